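test_that("generators are pure functions of their plans", {
  plan <- transcriptome_plan(seed = 81, n_transcripts = 3, lengths = 800)
  a <- make_transcriptome(plan)
  b <- make_transcriptome(plan)
  expect_identical(vapply(a$seqs, as.character, ""),
                   vapply(b$seqs, as.character, ""))

  tg1 <- make_target_gene(seed = 82, length = 1200, n_sites = 2)
  tg2 <- make_target_gene(seed = 82, length = 1200, n_sites = 2)
  expect_identical(as.character(tg1$target), as.character(tg2$target))

  plan_r <- recording_plan(seed = 83, duration_s = 2, units = list(
    list(ttp_us = 400, amp = 9, model = "poisson", rate_hz = 5)))
  expect_identical(make_recording(plan_r)$recording$samples,
                   make_recording(plan_r)$recording$samples)
})

test_that("planted transcriptome matches are exact, never longer", {
  g <- random_guides(1, 84)
  for (L in c(15L, 18L, 21L)) {
    tx <- make_transcriptome(transcriptome_plan(
      seed = 84 + L, n_transcripts = 2, lengths = 1200,
      plants = list(list(site = revcomp(g), match_len = L,
                         transcript = 1))))
    expect_equal(oracle_longest_match(g, tx$seqs), L)
    expect_equal(longest_match(g, tx$seqs)$max_len, L)
  }
  # without plants a random guide matches far below the scramble bound
  tx0 <- make_transcriptome(transcriptome_plan(
    seed = 85, n_transcripts = 3, lengths = 2000))
  m <- longest_match(g, tx0$seqs)$max_len
  expect_equal(m, oracle_longest_match(g, tx0$seqs))
  expect_lt(m, 15)
  expect_error(make_transcriptome(transcriptome_plan(
    seed = 86, n_transcripts = 1, lengths = 10,
    plants = list(list(site = revcomp(g), match_len = 21)))),
    "longer than")
})

test_that("target-gene plants are exactly recoverable by the scan", {
  tg <- make_target_gene(seed = 87, length = 2000, n_sites = 3)
  cands <- scan_candidates(tg$target)
  expect_equal(cands$window_start, tg$truth$window_start)
  # GC-poor background with no plants yields nothing
  tg0 <- make_target_gene(seed = 88, length = 1500, n_sites = 0, gc = 0.2)
  expect_equal(nrow(scan_candidates(tg0$target)), 0)
  expect_error(make_target_gene(seed = 89, length = 500, n_sites = 2,
                                positions = c(10, 20)),
               "overlap")
})

test_that("planted recordings are detectable at the designed SNR", {
  plan <- recording_plan(seed = 90, duration_s = 10, noise_sd = 1, units = list(
    list(ttp_us = 350, amp = 10, model = "poisson", rate_hz = 4)))
  sim <- make_recording(plan)
  det <- detect_spikes(bandpass_filter(sim$recording))
  n_match <- match_spikes(det, sim$truth$time_ms, tol = 0.5)
  expect_gte(n_match / nrow(sim$truth), 0.95)
})

test_that("bursty trains score higher burstiness than Poisson trains", {
  bi_of <- function(times) {
    as.numeric(burstiness(autocorrelogram(
      rasterize(times, 120000), 50)))
  }
  set.seed(91)
  bp <- bi_of(sim_poisson_train(5, 120, seed = 92))
  bb <- bi_of(sim_bursty_train(1.25, 120, spikes_per_burst = 4,
                               intra_isi_ms = 3, seed = 93))
  expect_gt(bb, bp)
  expect_error(sim_bursty_train(1, 10, intra_isi_ms = 0.5), "refractory")
})

test_that("spike templates respect their parameters", {
  t_us <- seq(-200, 800, by = 1)
  v <- spike_template(t_us, ttp_us = 500, amp = 2, peak_ratio = 0.5)
  expect_equal(t_us[which.min(v)], 0)
  expect_equal(t_us[which.max(v)], 500)
  expect_equal(min(v), -2)
  expect_equal(max(v), 1)
  expect_error(recording_plan(seed = 1, units = list(list(ttp_us = 300))),
               "positive amp")
  expect_error(recording_plan(seed = 1, rate = 10000), ">= 20000")
})
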
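test_that("band-pass keeps the band, rejects line noise and DC", {
  rate <- 20000
  t <- seq(0, 2, by = 1 / rate)[-1]
  inband <- recording(sin(2 * pi * 1000 * t), rate)
  out <- bandpass_filter(inband)
  mid <- seq(rate / 2, 3 * rate / 2)  # avoid filter edges
  expect_equal(max(abs(out$samples[mid])), 1, tolerance = 0.05)

  low <- bandpass_filter(recording(sin(2 * pi * 50 * t), rate))
  atten <- 20 * log10(max(abs(low$samples[mid])))
  expect_lt(atten, -20)

  dc <- bandpass_filter(recording(rep(3, 2 * rate), rate))
  expect_lt(max(abs(dc$samples[mid])), 1e-6)  # away from filter edges

  expect_error(bandpass_filter(recording(rnorm(100), rate = 20000),
                               ephys_config(band = c(300, 11000))),
               "Nyquist")
})

test_that("spikes planted in noise are all detected near their true times", {
  rate <- 20000
  set.seed(71)
  x <- rnorm(rate * 5)  # 5 s, sd 1
  truth_ms <- seq(200, 4800, length.out = 10)
  for (t in truth_ms) {
    i <- round(t * rate / 1000) + 1
    su <- (i - 4):(i + 4)
    x[su] <- x[su] + spike_template(((su - 1) * 1e6 / rate) - t * 1000,
                                    ttp_us = 400, amp = 10)
  }
  det <- detect_spikes(recording(x, rate))
  expect_equal(length(det), 10)
  expect_equal(match_spikes(det, truth_ms, tol = 0.2), 10L)
})

test_that("pure noise yields (almost) no detections and edge cases are safe", {
  set.seed(72)
  det <- detect_spikes(recording(rnorm(20000 * 10), 20000))
  expect_lte(length(det), 2)  # 5-sigma Gaussian tail over 10 s
  expect_warning(z <- detect_spikes(recording(rep(1, 1000), 20000)),
                 "zero-variance")
  expect_equal(length(z), 0)
  expect_equal(length(detect_spikes(recording(numeric(0), 20000))), 0)
})

test_that("detected events respect the refractory separation", {
  set.seed(73)
  rate <- 20000
  x <- rnorm(rate)
  x[2000:2002] <- -12
  x[2010:2012] <- -12  # 0.5 ms later: inside the 1-ms refractory window
  det <- detect_spikes(recording(x, rate))
  expect_true(all(diff(det) >= 1))
  expect_equal(length(det), 1)
})

test_that("two planted waveform shapes are clustered apart", {
  set.seed(74)
  wf1 <- make_waveform(300, amp = 10)
  wf2 <- make_waveform(550, amp = 8)
  wfs <- rbind(t(replicate(60, wf1 + rnorm(length(wf1), 0, 0.3))),
               t(replicate(60, wf2 + rnorm(length(wf2), 0, 0.3))))
  truth <- rep(1:2, each = 60)
  lab <- cluster_waveforms(wfs, k = 2, seed = 5)
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(agree, 0.95)
  expect_equal(cluster_waveforms(wfs, k = 2, seed = 5), lab)  # deterministic
  # degenerate: identical waveforms accept any split
  same <- matrix(rep(wf1, 10), nrow = 10, byrow = TRUE)
  expect_equal(length(cluster_waveforms(same, k = 2)), 10)
  expect_error(cluster_waveforms(wfs, k = 1), "k must")
  expect_error(cluster_waveforms(wfs, k = 1000), "k must")
})

test_that("trough-to-peak recovers planted durations to sub-sample accuracy", {
  wf <- make_waveform(400, rate = 20000, offset_us = 0)
  expect_equal(trough_to_peak(wf, 20000), 400)
  # sweep with sub-sample offsets: recovered within one sample period
  for (ttp in seq(300, 600, by = 50)) {
    wf <- make_waveform(ttp, rate = 20000, offset_us = 21.3)
    expect_equal(trough_to_peak(wf, 20000), ttp, tolerance = 1e-6)
    expect_lt(abs(trough_to_peak(wf, 20000, refine = FALSE) - ttp), 50)
  }
  expect_true(is.na(trough_to_peak(rep(0, 50), 20000)))       # flat
  expect_true(is.na(trough_to_peak(seq(1, 0, -0.1), 20000)))  # monotone
})

test_that("unit classification boundary is strict at 440 microseconds", {
  expect_equal(classify_unit(441), "pPYR")
  expect_equal(classify_unit(440), "pIN")
  expect_equal(classify_unit(200), "pIN")
  expect_true(is.na(classify_unit(NA_real_)))
  sweep <- classify_unit(seq(300, 600, by = 1))
  expect_equal(length(unique(rle(sweep)$values)), 2)  # exactly one boundary
})

test_that("rasters are binary, bin at 1 ms and validate their input", {
  r <- rasterize(c(0.4, 0.6), duration_ms = 5)
  expect_equal(r, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(sum(rasterize(numeric(0), 100)), 0)
  expect_equal(sum(rasterize(seq(0.5, 99.5, by = 5), 100)), 20)
  expect_error(rasterize(c(-1, 2), 100), "lie in")
  expect_error(rasterize(c(5, 100), 100), "lie in")
})

test_that("firing rate and ISI are elementary and guarded", {
  expect_equal(firing_rate(seq(0.5, 59999.5, by = 500), 60), 2)
  expect_equal(length(isi_ms(5)), 0)
  expect_equal(isi_ms(seq(0, 100, by = 10)), rep(10, 10))
  expect_error(firing_rate(1:3, 0), "> 0")
})

test_that("autocorrelogram matches the pair-counting oracle", {
  # regular 10-ms train: peaks exactly at lags 10..50
  r <- rasterize(seq(0.5, 999.5, by = 10), 1000)
  acg <- autocorrelogram(r, 50)
  expect_true(all(acg[c(10, 20, 30, 40, 50)] > 0))
  expect_true(all(acg[setdiff(1:50, c(10, 20, 30, 40, 50))] == 0))
  expect_equal(acg, oracle_acg(r, 50))
  # single spike: all zero
  expect_true(all(autocorrelogram(rasterize(3.2, 100), 50) == 0))
  # random rasters against the oracle
  set.seed(75)
  for (i in 1:5) {
    rr <- as.integer(runif(400) < 0.05)
    expect_equal(autocorrelogram(rr, 50), oracle_acg(rr, 50))
  }
  expect_warning(short <- autocorrelogram(rep(1L, 20), 50), "shorter")
  expect_equal(length(short), 19)
})

test_that("burstiness follows its closed form and flags undefined cases", {
  uni <- stats::setNames(rep(3L, 50), 1:50)
  expect_equal(as.numeric(burstiness(uni)), 0.5)
  expect_equal(attr(burstiness(uni), "delta_t"), 25L)
  lag1 <- stats::setNames(c(7L, rep(0L, 49)), 1:50)
  expect_equal(as.numeric(burstiness(lag1)), 0.98)
  expect_true(is.na(burstiness(stats::setNames(rep(0L, 50), 1:50))))
  # BI is non-increasing in delta_t by construction
  bis <- vapply(1:50, function(dt) {
    acg <- rep(0L, 50); acg[dt] <- 1L
    as.numeric(burstiness(acg))
  }, 0)
  expect_true(all(diff(bis) < 0))
})

test_that("recording I/O round-trips in both formats", {
  rec <- recording(round(rnorm(500), 4), 20000)
  bin <- withr::local_tempfile(fileext = ".dat")
  write_recording(rec, bin)
  back <- read_recording(bin)
  expect_equal(back$rate, 20000)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)  # float32
  csv <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, csv, format = "csv")
  expect_equal(read_recording(csv, rate = 20000)$samples, rec$samples,
               tolerance = 1e-6)
  expect_error(read_recording(csv), "rate")
})
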
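test_that("longest_match agrees with the brute-force oracle", {
  set.seed(41)
  for (trial in 1:60) {
    q <- random_guides(1, 4100 + trial)
    nsub <- sample(1:3, 1)
    seqs <- stats::setNames(
      replicate(nsub, paste(sample(c("A", "C", "G", "T"),
                                   sample(100:600, 1), replace = TRUE),
                            collapse = "")),
      paste0("tx", seq_len(nsub)))
    got <- longest_match(q, seqs)
    expect_equal(got$max_len, oracle_longest_match(q, seqs))
    expect_true(all(got$hits$match_len == got$max_len))
  }
})

test_that("planted matches are found at their exact length and orientation", {
  g <- random_guides(1, 42)
  # full-length plant: guide's target site appears verbatim
  tx <- make_transcriptome(transcriptome_plan(
    seed = 43, n_transcripts = 2, lengths = 1500,
    plants = list(list(site = revcomp(g), match_len = 21, transcript = 1))))
  got <- longest_match(g, tx$seqs)
  expect_equal(got$max_len, 21L)
  expect_true("guide_match" %in% got$hits$orientation)
  # 18-mer plant, flanks broken
  tx18 <- make_transcriptome(transcriptome_plan(
    seed = 44, n_transcripts = 2, lengths = 1500,
    plants = list(list(site = revcomp(g), match_len = 18, transcript = 2))))
  got18 <- longest_match(g, tx18$seqs)
  expect_equal(got18$max_len, 18L)
  expect_equal(got18$max_len, oracle_longest_match(g, tx18$seqs))
})

test_that("match coordinates point at the matching substrings", {
  g <- random_guides(1, 45)
  tx <- make_transcriptome(transcriptome_plan(
    seed = 46, n_transcripts = 2, lengths = 1000,
    plants = list(list(site = revcomp(g), match_len = 16, transcript = 1))))
  got <- longest_match(g, tx$seqs)
  h <- got$hits[1, ]
  subj <- as.character(tx$seqs[[h$subject_id]])
  searched <- if (h$orientation == "guide_match")
    as.character(revcomp(g)) else g
  expect_equal(substr(subj, h$subject_start + 1,
                      h$subject_start + h$match_len),
               substr(searched, h$query_start + 1,
                      h$query_start + h$match_len))
})

test_that("the discard threshold is strict: 18 discarded, 17 kept", {
  guides <- random_guides(2, 47)
  tx <- make_transcriptome(transcriptome_plan(
    seed = 48, n_transcripts = 2, lengths = 2000,
    plants = list(
      list(site = revcomp(guides[1]), match_len = 18, transcript = 1),
      list(site = revcomp(guides[2]), match_len = 17, transcript = 2))))
  cands <- data.frame(antisense21 = guides, stringsAsFactors = FALSE)
  ann <- offtarget_filter(cands, tx$seqs, keep_all = TRUE)
  expect_equal(ann$offtarget_max, c(18L, 17L))
  expect_equal(ann$offtarget_ok, c(FALSE, TRUE))
  kept <- offtarget_filter(cands, tx$seqs)
  expect_equal(kept$antisense21, guides[2])
})

test_that("excluding the intended target removes it from the screen", {
  g <- random_guides(1, 49)
  site <- as.character(revcomp(g))
  tx <- make_transcriptome(transcriptome_plan(
    seed = 50, n_transcripts = 3, lengths = 1200,
    plants = list(list(site = site, match_len = 21, transcript = 2))))
  cfg <- screen_config(exclude = "tx2")
  got <- longest_match(g, tx$seqs, cfg)
  expect_lt(got$max_len, 15)
  expect_equal(got$max_len, oracle_longest_match(g, tx$seqs,
                                                 exclude = "tx2"))
  # candidate matching only its own excluded target is kept
  kept <- offtarget_filter(data.frame(antisense21 = g), tx$seqs, cfg)
  expect_equal(nrow(kept), 1)
  expect_error(
    longest_match(g, tx$seqs,
                  screen_config(exclude = c("tx1", "tx2", "tx3"))),
    "excluded")
})

test_that("scrambles preserve composition, avoid matches and reproduce", {
  g <- random_guides(1, 51)
  tx <- make_transcriptome(transcriptome_plan(
    seed = 52, n_transcripts = 3, lengths = 2000,
    plants = list(list(site = revcomp(g), match_len = 21, transcript = 1))))
  scr <- make_scramble(g, tx$seqs, seed = 7)
  expect_equal(sort(strsplit(as.character(scr), "")[[1]]),
               sort(strsplit(g, "")[[1]]))
  expect_equal(gc_percent(scr), gc_percent(g))
  expect_lt(attr(scr, "match_len"), 15)
  expect_equal(attr(scr, "match_len"),
               oracle_longest_match(scr, tx$seqs))
  expect_lte(max_homopolymer_run(scr), 3)
  scr2 <- make_scramble(g, tx$seqs, seed = 7)
  expect_equal(as.character(scr2), as.character(scr))
  # exhaustion reports the best attempt
  expect_error(
    make_scramble(g, tx$seqs, screen_config(scr_max_match = 1),
                  seed = 7, max_attempts = 3),
    "best attempt")
})
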
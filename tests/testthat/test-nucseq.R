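test_that("normalization uppercases, strips noise and detects the alphabet", {
  x <- nuc_seq("accggtGTCGAC")
  expect_equal(x$seq, "ACCGGTGTCGAC")
  expect_equal(x$alphabet, "DNA")

  expect_equal(nuc_seq("ACGT")$seq, "ACGT")
  expect_equal(nuc_seq("ACGU")$alphabet, "RNA")
  expect_equal(nuc_seq(" ac\ngt 12")$seq, "ACGT")

  expect_error(nuc_seq("ACGN"), "illegal symbol 'N' at offset 4")
  expect_error(nuc_seq("   "), "empty")
  expect_error(nuc_seq("ACGTU"), "contains")
  expect_error(nuc_seq("ACGT", alphabet = "RNA"), "contains 'T'")
})

test_that("revcomp matches hand values and an independent implementation", {
  expect_equal(as.character(revcomp("TAATGAGCCACACTTGGAGGT")),
               "ACCTCCAAGTGTGGCTCATTA")
  expect_equal(as.character(revcomp("A")), "T")
  expect_equal(as.character(revcomp(nuc_seq("ACGU"))), "ACGU")

  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:80, 1),
                      replace = TRUE), collapse = "")
    expect_equal(as.character(revcomp(revcomp(s))), s)
    expect_equal(as.character(revcomp(s)),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(s))))
  }
})

test_that("GC percent is exact and permutation invariant", {
  expect_equal(gc_percent("TAATGAGCCACACTTGGAGGT"), 100 * 10 / 21)
  expect_equal(gc_percent("AATGCCTGCTTCTTCAGCTTT"), 100 * 9 / 21)
  expect_equal(gc_percent("GGCC"), 100)
  expect_error(gc_percent(""), "empty")

  set.seed(12)
  s <- strsplit("TAATGAGCCACACTTGGAGGT", "")[[1]]
  for (i in 1:10) {
    expect_equal(gc_percent(paste(sample(s), collapse = "")),
                 gc_percent(paste(s, collapse = "")))
  }
})

test_that("homopolymer runs are measured correctly", {
  expect_equal(max_homopolymer_run("AAAT"), 3)
  expect_equal(max_homopolymer_run("GTTTTGGCCACTGACTGAC"), 4)
  expect_equal(max_homopolymer_run("ACGT"), 1)
  set.seed(13)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C"), 30, replace = TRUE), collapse = "")
    expect_lte(max_homopolymer_run(s), nchar(s))
  }
})

test_that("FASTA roundtrip is the identity on normalized records", {
  set.seed(14)
  recs <- lapply(1:100, function(i) {
    nuc_seq(paste(sample(c("A", "C", "G", "T"), sample(10:120, 1),
                         replace = TRUE), collapse = ""),
            id = paste0("rec", i))
  })
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, path, width = 37)
  back <- read_fasta(path)
  expect_equal(length(back), 100)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$seq, recs[[i]]$seq)
  }
})

test_that("FASTA edge cases: single record, duplicates, malformed input", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT"), path)
  one <- read_fasta(path)
  expect_equal(one[[1]]$id, "x")
  expect_equal(one[[1]]$seq, "ACGT")

  writeLines(c(">a", "ACGT", ">a", "GGCC"), path)
  expect_warning(both <- read_fasta(path), "duplicate")
  expect_equal(length(both), 2)

  writeLines("ACGT", path)
  expect_error(read_fasta(path), "malformed")
  writeLines(character(0), path)
  expect_error(read_fasta(path), "empty")
})
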
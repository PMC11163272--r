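# Independent brute-force oracles used to check the fast implementations.

# longest common contiguous substring of q and s by sliding q over every
# alignment offset and taking the longest run of matches
oracle_lcs_pair <- function(q, s) {
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  nq <- length(qc)
  ns <- length(sc)
  best <- 0L
  for (off in (1L - nq):(ns - 1L)) {
    i <- max(1L, 1L - off):min(nq, ns - off)
    m <- qc[i] == sc[i + off]
    r <- rle(m)
    if (any(r$values)) best <- max(best, max(r$lengths[r$values]))
  }
  best
}

# transcriptome-wide oracle for longest_match()
oracle_longest_match <- function(query, seqs, both = TRUE,
                                 exclude = character()) {
  seqs <- tx_chr(seqs)
  seqs <- seqs[setdiff(names(seqs), exclude)]
  q <- chartr("U", "T", toupper(as.character(query)))
  rc <- as.character(revcomp(q))
  pats <- c(rc, if (both) q)
  max(vapply(seqs, function(s) {
    max(vapply(pats, oracle_lcs_pair, 0L, s = s))
  }, 0L))
}

# named character vector from any transcriptome representation
tx_chr <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("subject", seq_along(x))
    return(toupper(x))
  }
  stats::setNames(vapply(x, as.character, ""),
                  vapply(x, function(s) s$id, ""))
}

# autocorrelogram by explicit counting over ordered spike-bin pairs
oracle_acg <- function(raster, max_lag = 50L) {
  idx <- which(raster == 1L)
  counts <- integer(max_lag)
  for (i in idx) {
    for (j in idx[idx > i]) {
      l <- j - i
      if (l <= max_lag) counts[l] <- counts[l] + 1L
    }
  }
  stats::setNames(counts, seq_len(max_lag))
}

# terminal-window energy by an independent loop over the shipped table file
oracle_end_energy <- function(sense, end, w = 5L) {
  path <- system.file("extdata", "nn_stacks_dg37.tsv", package = "amirephys")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  s <- chartr("T", "U", toupper(as.character(sense)))
  if (end == "antisense5p") {
    s <- paste(rev(strsplit(chartr("ACGU", "UGCA", s), "",
                            fixed = TRUE)[[1]]), collapse = "")
  }
  e <- 0
  for (i in seq_len(w)) {
    e <- e + tab$dg37[tab$stack == substr(s, i, i + 1L)]
  }
  e
}

# number of truth spikes matched by a detection within tol ms (1-1 matching)
match_spikes <- function(detected, truth_ms, tol = 0.5) {
  used <- logical(length(detected))
  n <- 0L
  for (t in truth_ms) {
    j <- which(!used & abs(detected - t) <= tol)
    if (length(j)) {
      used[j[which.min(abs(detected[j] - t))]] <- TRUE
      n <- n + 1L
    }
  }
  n
}

# seeded random 21-mer guides
random_guides <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                     collapse = ""))
}
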
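#' Off-target screen configuration
#'
#' Candidates with a longest contiguous exact transcriptome match greater
#' than `discard_over` nt are discarded; scrambled controls must match less
#' than `scr_max_match` nt (strict). The intended target transcript(s) are
#' named in `exclude` and never count as off-targets. Both orientations are
#' searched by default: the target-site sequence `revcomp(query)` (where the
#' guide could pair, `guide_match`) and the query itself (`sense_match`).
#'
#' @param discard_over discard threshold in nt (kept iff match <= this).
#' @param scr_max_match strict upper bound for scramble matches, nt.
#' @param exclude character vector of subject ids to exclude.
#' @param both_orientations search both orientations?
#' @return A `screen_config` list.
#' @export
screen_config <- function(discard_over = 17L, scr_max_match = 15L,
                          exclude = character(), both_orientations = TRUE) {
  if (discard_over < 1L || scr_max_match < 1L) {
    stop("thresholds must be >= 1")
  }
  structure(list(discard_over = as.integer(discard_over),
                 scr_max_match = as.integer(scr_max_match),
                 exclude = as.character(exclude),
                 both_orientations = isTRUE(both_orientations)),
            class = "screen_config")
}

# normalize transcriptome input into list(ids=..., seqs=DNA-canonical strings)
tx_strings <- function(transcriptome) {
  if (inherits(transcriptome, "nuc_seq")) transcriptome <- list(transcriptome)
  if (is.character(transcriptome)) {
    ids <- if (is.null(names(transcriptome)))
      paste0("subject", seq_along(transcriptome)) else names(transcriptome)
    seqs <- vapply(transcriptome, function(s) canon_dna(s), "")
  } else {
    ids <- vapply(transcriptome, function(s) as_nuc_seq(s)$id, "")
    seqs <- vapply(transcriptome, canon_dna, "")
  }
  list(ids = ids, seqs = unname(seqs))
}

# longest substring of `pat` occurring in `big` (subjects joined by '#');
# returns NULL or data.frame(query_start0, big_start0, match_len)
longest_sub_hits <- function(pat, big, floor_len = 1L) {
  np <- nchar(pat)
  for (L in seq(min(np, nchar(big)), floor_len)) {
    rows <- list()
    for (a in 1:(np - L + 1L)) {
      m <- gregexpr(substr(pat, a, a + L - 1L), big, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        rows[[length(rows) + 1L]] <-
          data.frame(query_start = a - 1L, big_start = as.integer(m) - 1L,
                     match_len = L)
      }
    }
    if (length(rows)) return(do.call(rbind, rows))
  }
  NULL
}

#' Longest contiguous transcriptome match
#'
#' Desk-scale stand-in for a BLAST screen: the maximum, over all non-excluded
#' subjects, of the longest common contiguous substring between the subject
#' and (a) the target-site sequence `revcomp(query)` (`guide_match`) and (b)
#' the query itself (`sense_match`). All ties at the maximum are reported.
#' Deterministic; correctness is defined by a brute-force all-substrings
#' oracle. Mismatches and gaps are not modelled.
#'
#' @param query the 21-nt guide (`nuc_seq` or character; other lengths warn).
#' @param transcriptome list of `nuc_seq`, or (named) character vector.
#' @param cfg a [screen_config()].
#' @return list with `max_len` (integer) and `hits` (data.frame: `query_id`,
#'   `subject_id`, `match_len`, `query_start`, `subject_start` — both
#'   0-based, `query_start` on the searched orientation — and `orientation`).
#' @export
longest_match <- function(query, transcriptome, cfg = screen_config()) {
  qn <- as_nuc_seq(query, id = "query")
  q <- canon_dna(qn)
  if (nchar(q) != 21L) warning("query length is not 21 nt")
  tx <- tx_strings(transcriptome)
  keep <- !(tx$ids %in% cfg$exclude)
  if (!any(keep)) {
    stop("all subjects excluded: nothing to screen (no subjects left, ",
         "which is different from finding no match)")
  }
  ids <- tx$ids[keep]
  seqs <- tx$seqs[keep]
  big <- paste(seqs, collapse = "#")
  # map 0-based big offsets back to subject index / subject offset
  starts <- cumsum(c(0L, nchar(seqs) + 1L))[seq_along(seqs)]

  pats <- list(guide_match = revcomp_str(q))
  if (cfg$both_orientations) pats$sense_match <- q

  best <- 0L
  hits <- list()
  for (ori in names(pats)) {
    h <- longest_sub_hits(pats[[ori]], big)
    if (is.null(h)) next
    h$orientation <- ori
    hits[[ori]] <- h
    best <- max(best, h$match_len[1])
  }
  if (best == 0L) {
    return(list(max_len = 0L,
                hits = data.frame(query_id = character(),
                                  subject_id = character(),
                                  match_len = integer(),
                                  query_start = integer(),
                                  subject_start = integer(),
                                  orientation = character())))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[hits$match_len == best, , drop = FALSE]
  si <- findInterval(hits$big_start, starts)
  out <- data.frame(query_id = qn$id,
                    subject_id = ids[si],
                    match_len = hits$match_len,
                    query_start = hits$query_start,
                    subject_start = hits$big_start - starts[si],
                    orientation = hits$orientation,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(max_len = as.integer(best), hits = out)
}

#' Off-target filter
#'
#' Screens each candidate's guide (`antisense21`) against the transcriptome
#' and keeps candidates whose longest contiguous match is at most
#' `discard_over` nt (the boundary itself is kept: "greater than" discards).
#'
#' @param candidates data.frame with an `antisense21` column (e.g. from
#'   [scan_candidates()]).
#' @param transcriptome as in [longest_match()].
#' @param cfg a [screen_config()].
#' @param keep_all keep discarded rows (flagged) instead of dropping them?
#' @return Annotated data.frame with `offtarget_max`, `offtarget_subject`
#'   and `offtarget_ok` columns; by default only surviving rows.
#' @export
offtarget_filter <- function(candidates, transcriptome,
                             cfg = screen_config(), keep_all = FALSE) {
  stopifnot(is.data.frame(candidates), "antisense21" %in% names(candidates))
  n <- nrow(candidates)
  mx <- integer(n)
  subj <- character(n)
  for (i in seq_len(n)) {
    lm <- longest_match(candidates$antisense21[i], transcriptome, cfg)
    mx[i] <- lm$max_len
    subj[i] <- if (nrow(lm$hits)) lm$hits$subject_id[1] else NA_character_
  }
  candidates$offtarget_max <- mx
  candidates$offtarget_subject <- subj
  candidates$offtarget_ok <- mx <= cfg$discard_over
  if (!keep_all) {
    candidates <- candidates[candidates$offtarget_ok, , drop = FALSE]
    rownames(candidates) <- NULL
  }
  candidates
}

#' Composition-preserving scrambled control
#'
#' Draws seeded random permutations of the guide's bases (identical base
#' multiset, hence identical GC content) until one has a longest contiguous
#' transcriptome match strictly below `scr_max_match` and — by default — no
#' homopolymer run longer than 3. The first qualifying permutation is
#' returned; fixed seeds reproduce it exactly.
#'
#' @param guide 21-nt guide (`nuc_seq` or character).
#' @param transcriptome as in [longest_match()].
#' @param cfg a [screen_config()].
#' @param seed RNG seed for the permutation stream.
#' @param max_attempts attempts before giving up.
#' @param enforce_run also require max homopolymer run <= 3?
#' @return A `nuc_seq` with attributes `match_len` (its longest transcriptome
#'   match) and `attempts`. Errors if `max_attempts` is exhausted, reporting
#'   the best attempt and its match length.
#' @export
make_scramble <- function(guide, transcriptome, cfg = screen_config(),
                          seed = 1L, max_attempts = 1000L,
                          enforce_run = TRUE) {
  g <- as_nuc_seq(guide, id = "guide")
  if (nchar(g$seq) != 21L) stop("guide must be 21 nt")
  ch <- strsplit(canon_dna(g), "", fixed = TRUE)[[1]]
  best_seq <- NULL
  best_len <- Inf
  res <- with_seed(seed, {
    out <- NULL
    for (i in seq_len(max_attempts)) {
      s <- paste(sample(ch), collapse = "")
      if (enforce_run && max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths) > 3L) next
      ml <- longest_match(s, transcriptome, cfg)$max_len
      if (ml < best_len) {
        best_len <- ml
        best_seq <- s
      }
      if (ml < cfg$scr_max_match) {
        out <- structure(nuc_seq(s, id = paste0(g$id, "_scr")),
                         match_len = ml, attempts = i)
        break
      }
    }
    out
  })
  if (is.null(res)) {
    stop(sprintf(paste0("no scramble with match < %d nt found in %d ",
                        "attempts; best attempt %s had match %d nt"),
                 cfg$scr_max_match, max_attempts, best_seq, best_len))
  }
  res
}
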
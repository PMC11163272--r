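#' Duplex consensus specification
#'
#' The candidate scan slides a 23-nt window over the target. The consensus
#' `N2[CG]N8[AUT]N8[AUT]N2` fixes window positions 3, 12 and 21 (1-based):
#' position 3 must be C or G, positions 12 and 21 must be A or T/U. T and U
#' are treated as equivalent. The 21-nt sense duplex strand sits inside the
#' window at `sense_offset` (0-based; default 1, i.e. window positions 2-22,
#' a convention since the flanking assignment is not fixed by the rules
#' themselves).
#'
#' @param window_len window length in nt.
#' @param fixed_positions named list: 1-based window position -> allowed
#'   bases (string, T/U equivalent).
#' @param sense_offset 0-based start of the 21-nt sense strand in the window.
#' @return A `consensus_spec` list.
#' @export
consensus_spec <- function(window_len = 23L,
                           fixed_positions = list(`3` = "CG",
                                                  `12` = "AUT",
                                                  `21` = "AUT"),
                           sense_offset = 1L) {
  window_len <- as.integer(window_len)
  sense_offset <- as.integer(sense_offset)
  if (sense_offset < 0L || sense_offset + 21L > window_len) {
    stop("sense_offset + 21 must not exceed window_len")
  }
  pos <- as.integer(names(fixed_positions))
  if (any(is.na(pos)) || any(pos < 1L | pos > window_len)) {
    stop("fixed_positions names must be 1-based window positions")
  }
  structure(list(window_len = window_len,
                 fixed_positions = fixed_positions,
                 sense_offset = sense_offset),
            class = "consensus_spec")
}

#' Candidate filter configuration
#'
#' Bounds are inclusive. Each filter can be toggled independently so the
#' pipeline can also carry designs that violate one rule (useful when
#' specifying guides directly).
#'
#' @param gc_min,gc_max GC band in percent (default 45-50).
#' @param max_run longest allowed homopolymer run (default 3: runs of 4+ of
#'   the same base are rejected).
#' @param check_consensus,check_gc,check_run enable/disable each filter.
#' @param gc_on compute GC on the 21-nt `"sense"` strand (default) or the
#'   full 23-nt `"window"`.
#' @param regions optional list of 0-based half-open `c(start, end)` target
#'   intervals; only windows fully inside a region are scanned.
#' @return A `filter_config` list.
#' @export
filter_config <- function(gc_min = 45, gc_max = 50, max_run = 3L,
                          check_consensus = TRUE, check_gc = TRUE,
                          check_run = TRUE, gc_on = c("sense", "window"),
                          regions = NULL) {
  if (!(gc_min >= 0 && gc_min <= gc_max && gc_max <= 100)) {
    stop("need 0 <= gc_min <= gc_max <= 100")
  }
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_run = as.integer(max_run),
                 check_consensus = isTRUE(check_consensus),
                 check_gc = isTRUE(check_gc),
                 check_run = isTRUE(check_run),
                 gc_on = match.arg(gc_on),
                 regions = regions),
            class = "filter_config")
}

#' Scan a target transcript for duplex candidates
#'
#' Enumerates every 23-nt window on the target, applies the enabled filters
#' (positional consensus, homopolymer run, GC band) and returns one row per
#' passing window with per-filter diagnostics. Output is sorted by window
#' start and deterministic. A target shorter than the window yields an empty
#' frame with a warning.
#'
#' @param target a `nuc_seq` or character scalar.
#' @param consensus a [consensus_spec()].
#' @param filters a [filter_config()].
#' @return data.frame with columns `target_id`, `window_start` (0-based),
#'   `window`, `sense21`, `antisense21`, `gc_percent`, `max_run`,
#'   `consensus_ok`, `gc_ok`, `run_ok`. Diagnostics are reported for every
#'   emitted candidate; rows are kept only if all *enabled* filters pass.
#' @export
scan_candidates <- function(target, consensus = consensus_spec(),
                            filters = filter_config()) {
  target <- as_nuc_seq(target, id = "target")
  s <- canon_dna(target)
  n <- nchar(s)
  wl <- consensus$window_len
  empty <- data.frame(target_id = character(), window_start = integer(),
                      window = character(), sense21 = character(),
                      antisense21 = character(), gc_percent = double(),
                      max_run = integer(), consensus_ok = logical(),
                      gc_ok = logical(), run_ok = logical(),
                      stringsAsFactors = FALSE)
  if (n < wl) {
    warning("target shorter than the scan window; no candidates")
    return(empty)
  }
  starts0 <- 0:(n - wl)
  if (!is.null(filters$regions)) {
    keep <- rep(FALSE, length(starts0))
    for (r in filters$regions) {
      keep <- keep | (starts0 >= r[1] & starts0 + wl <= r[2])
    }
    starts0 <- starts0[keep]
    if (!length(starts0)) return(empty)
  }
  windows <- substring(s, starts0 + 1L, starts0 + wl)

  consensus_ok <- rep(TRUE, length(windows))
  for (p in names(consensus$fixed_positions)) {
    pos <- as.integer(p)
    allowed <- strsplit(chartr("U", "T",
                               consensus$fixed_positions[[p]]), "")[[1]]
    consensus_ok <- consensus_ok &
      substring(windows, pos, pos) %in% allowed
  }

  off <- consensus$sense_offset
  sense <- substring(windows, off + 1L, off + 21L)
  gcseq <- if (filters$gc_on == "window") windows else sense
  gc <- 100 * nchar(gsub("[^GC]", "", gcseq)) / nchar(gcseq)
  runs <- vapply(strsplit(sense, "", fixed = TRUE),
                 function(ch) max(rle(ch)$lengths), 1L)
  gc_ok <- gc >= filters$gc_min & gc <= filters$gc_max
  run_ok <- runs <= filters$max_run

  pass <- (!filters$check_consensus | consensus_ok) &
          (!filters$check_gc | gc_ok) &
          (!filters$check_run | run_ok)

  out <- data.frame(target_id = target$id,
                    window_start = starts0,
                    window = windows,
                    sense21 = sense,
                    antisense21 = unname(vapply(sense, revcomp_str, "")),
                    gc_percent = gc,
                    max_run = as.integer(runs),
                    consensus_ok = consensus_ok,
                    gc_ok = gc_ok,
                    run_ok = run_ok,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-validate a single candidate window rule by rule
#'
#' Independent scalar re-checker for one 23-nt window: the scan must emit
#' exactly the windows whose report here is all-true (under the same enabled
#' filters). Used as the scan's oracle.
#'
#' @param window a 23-nt window as `nuc_seq`/character, or a candidate row
#'   from [scan_candidates()] (its `window` column is used).
#' @param consensus a [consensus_spec()].
#' @param filters a [filter_config()].
#' @return list with `gc`, `max_run`, `consensus_ok`, `gc_ok`, `run_ok` and
#'   `pass` (all enabled rules true).
#' @export
validate_candidate <- function(window, consensus = consensus_spec(),
                               filters = filter_config()) {
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1L)
    window <- window$window
  }
  w <- canon_dna(window)
  if (nchar(w) != consensus$window_len) {
    stop("window length != ", consensus$window_len)
  }
  ch <- strsplit(w, "", fixed = TRUE)[[1]]
  consensus_ok <- TRUE
  for (p in names(consensus$fixed_positions)) {
    allowed <- strsplit(chartr("U", "T",
                               consensus$fixed_positions[[p]]), "")[[1]]
    if (!(ch[as.integer(p)] %in% allowed)) consensus_ok <- FALSE
  }
  off <- consensus$sense_offset
  sense_ch <- ch[(off + 1L):(off + 21L)]
  gc_ch <- if (filters$gc_on == "window") ch else sense_ch
  gc <- 100 * sum(gc_ch %in% c("G", "C")) / length(gc_ch)
  mrun <- max(rle(sense_ch)$lengths)
  gc_ok <- gc >= filters$gc_min && gc <= filters$gc_max
  run_ok <- mrun <= filters$max_run
  pass <- (!filters$check_consensus || consensus_ok) &&
          (!filters$check_gc || gc_ok) &&
          (!filters$check_run || run_ok)
  list(gc = gc, max_run = mrun, consensus_ok = consensus_ok,
       gc_ok = gc_ok, run_ok = run_ok, pass = pass)
}
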
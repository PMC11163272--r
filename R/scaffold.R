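#' miR-155 scaffold specification
#'
#' The amiRNA expression cassette is `arm5 + antisense(21 nt) + loop +
#' sense(19 nt) + arm3`: the miR-155 5' and 3' arms flank a hairpin whose
#' guide (antisense) strand is intact and whose passenger (sense) strand
#' carries a two-nucleotide central deletion (positions 10 and 11 of the
#' 21-nt sense, 1-based) that creates the bulge favouring guide loading into
#' RISC. The default arm and loop sequences are the ones shared by the
#' reference constructs shipped with the package (see
#' [reference_constructs()]); they are treated as opaque verbatim flanks.
#'
#' @param arm5,loop,arm3 scaffold segments (DNA, `nuc_seq` or character).
#' @param delete_positions 1-based positions removed from the 21-nt sense.
#' @return A `scaffold_spec` list.
#' @export
scaffold_spec <- function(arm5 = mir155_arm5, loop = mir155_loop,
                          arm3 = mir155_arm3,
                          delete_positions = c(10L, 11L)) {
  arm5 <- canon_dna(arm5)
  loop <- canon_dna(loop)
  arm3 <- canon_dna(arm3)
  if (!endsWith(arm5, "TGCTG")) stop("arm5 must end with 'TGCTG'")
  if (!startsWith(arm3, "CAGGA")) stop("arm3 must start with 'CAGGA'")
  if (nchar(loop) != 19L) stop("loop must be 19 nt")
  delete_positions <- sort(as.integer(delete_positions))
  if (any(delete_positions < 1L | delete_positions > 21L)) {
    stop("delete_positions must lie in 1..21")
  }
  structure(list(arm5 = arm5, loop = loop, arm3 = arm3,
                 delete_positions = delete_positions),
            class = "scaffold_spec")
}

# default scaffold segments: common prefix/suffix and loop of the shipped
# reference constructs (73-nt 5' arm, 19-nt loop, 90-nt 3' arm)
mir155_arm5 <- paste0("ACCGGTGTCGACTTTAAAGGGAGGTAGTGAGTGGACCAGTGGATCCTGGA",
                      "GGCTTGCTGAAGGCTGTATGCTG")
mir155_loop <- "GTTTTGGCCACTGACTGAC"
mir155_arm3 <- paste0("CAGGACACAAGGCCTGTTACTAGCACTCACATGGAACAAATGGCCCAGAT",
                      "CTGGCCGCACTCGAGATATCTAGAATTCACTAGTGAGCTC")

delete_at <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(ch[-pos], collapse = "")
}

#' Assemble an amiRNA scaffold construct
#'
#' Embeds a 21-nt guide (antisense) into the scaffold: the sense strand is
#' the guide's reverse complement with `spec$delete_positions` removed, and
#' the full construct is `arm5 + antisense + loop + sense + arm3`.
#'
#' @param antisense21 the 21-nt guide (DNA; `nuc_seq` or character).
#' @param name construct name.
#' @param spec a [scaffold_spec()].
#' @return An `amir_construct`: list with `name`, `antisense21`, `sense19`,
#'   `full` (all uppercase DNA strings) and `consistent = TRUE`.
#' @examples
#' b <- build_construct("TAATGAGCCACACTTGGAGGT", name = "tau724")
#' nchar(b$full)
#' @export
build_construct <- function(antisense21, name = "amiRNA",
                            spec = scaffold_spec()) {
  a <- as_nuc_seq(antisense21, id = name)
  if (a$alphabet != "DNA") stop("antisense must be DNA")
  if (nchar(a$seq) != 21L) stop("antisense must be 21 nt, got ",
                                nchar(a$seq))
  sense_full <- revcomp_str(a$seq)
  sense19 <- delete_at(sense_full, spec$delete_positions)
  full <- paste0(spec$arm5, a$seq, spec$loop, sense19, spec$arm3)
  structure(list(name = name, antisense21 = a$seq, sense19 = sense19,
                 full = full, consistent = TRUE),
            class = "amir_construct")
}

#' @export
print.amir_construct <- function(x, ...) {
  cat(sprintf("<amir_construct %s> %d nt\n", x$name, nchar(x$full)))
  cat("  antisense (guide):", x$antisense21, "\n")
  cat("  sense (deleted):  ", x$sense19, "\n")
  cat(sprintf("  segments consistent: %s\n", x$consistent))
  invisible(x)
}

#' Parse a scaffold construct into its segments
#'
#' Inverse of [build_construct()]: locates the 5' arm, loop and 3' arm (each
#' must occur exactly once, in order) and extracts the antisense and sense
#' segments between them. The parse reports whether the sense segment is
#' consistent with the antisense under some adjacent two-nt deletion
#' ([infer_deletion()]). `parse_construct(build_construct(x)$full)`
#' round-trips to `x`.
#'
#' @param full the full construct (`nuc_seq` or character; case-insensitive).
#' @param spec a [scaffold_spec()].
#' @return An `amir_construct` with an extra `deletion` element (the inferred
#'   deletion positions, `integer(0)` if inconsistent).
#' @export
parse_construct <- function(full, spec = scaffold_spec()) {
  fn <- as_nuc_seq(full, id = "construct")
  s <- fn$seq
  find_once <- function(landmark, what) {
    m <- gregexpr(landmark, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) stop(sprintf("landmark '%s' not found", what))
    if (length(m) > 1L) stop(sprintf("landmark '%s' found %d times",
                                     what, length(m)))
    as.integer(m)
  }
  p5 <- find_once(spec$arm5, "arm5")
  pl <- find_once(spec$loop, "loop")
  p3 <- find_once(spec$arm3, "arm3")
  e5 <- p5 + nchar(spec$arm5)
  el <- pl + nchar(spec$loop)
  if (!(p5 < pl && e5 <= pl && el <= p3)) {
    stop("landmarks not in arm5 < loop < arm3 order")
  }
  antisense <- substr(s, e5, pl - 1L)
  sense <- substr(s, el, p3 - 1L)
  del <- if (nchar(sense) == nchar(antisense) - 2L) {
    infer_deletion(sense, antisense)
  } else integer(0)
  structure(list(name = fn$id, antisense21 = antisense, sense19 = sense,
                 full = s, consistent = length(del) > 0L, deletion = del),
            class = "amir_construct")
}

#' Infer the deleted sense positions
#'
#' Finds the adjacent position pairs whose removal from
#' `revcomp(antisense21)` yields `sense19`. Repeats in the sense strand can
#' make several pairs consistent; the canonical answer is the pair whose
#' midpoint is closest to the centre of the full-length sense strand (ties
#' broken toward the 5' end), reflecting the central-bulge design of the
#' scaffold. All consistent pairs are available via the `all_pairs`
#' attribute (first positions). Returns `integer(0)` when no adjacent pair
#' reproduces `sense19`.
#'
#' @param sense19 the deleted sense strand (length `n - 2`).
#' @param antisense21 the guide strand (length `n`, conventionally 21).
#' @return Integer vector of the two 1-based deleted positions (or empty).
#' @examples
#' infer_deletion("ACCTCCAAGTGGCTCATTA", "TAATGAGCCACACTTGGAGGT")  # 10 11
#' @export
infer_deletion <- function(sense19, antisense21) {
  sn <- seq_str(sense19)
  an <- seq_str(antisense21)
  n <- nchar(an)
  if (nchar(sn) != n - 2L) {
    stop("sense must be exactly 2 nt shorter than the antisense")
  }
  full <- revcomp_str(canon_dna(an))
  ok <- vapply(seq_len(n - 1L), function(i) {
    paste0(substr(full, 1L, i - 1L), substr(full, i + 2L, n)) == sn
  }, NA)
  cand <- which(ok)
  if (!length(cand)) return(integer(0))
  centre <- (n + 1) / 2
  d <- abs(cand + 0.5 - centre)
  i <- cand[order(d, cand)][1]
  structure(c(i, i + 1L), all_pairs = cand)
}

#' Reference amiRNA constructs
#'
#' Reads the packaged FASTA of the three reference constructs — two
#' tau-targeting amiRNAs (`TauMiRNA166`, against the MAPT exon 2/3 junction;
#' `TauMiRNA724`, against exon 11) and the scrambled control (`ScrMiRNA`) —
#' and returns them parsed into scaffold segments.
#'
#' @return Named list of `amir_construct` objects.
#' @export
reference_constructs <- function() {
  path <- system.file("extdata", "reference_constructs.fa",
                      package = "amirephys", mustWork = TRUE)
  recs <- read_fasta(path)
  out <- lapply(recs, function(r) {
    p <- parse_construct(r)
    p$name <- r$id
    p
  })
  stats::setNames(out, vapply(recs, function(r) r$id, ""))
}
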
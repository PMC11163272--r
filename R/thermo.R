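# cache for the shipped nearest-neighbor table
.thermo_env <- new.env(parent = emptyenv())

#' Nearest-neighbor stack free-energy table
#'
#' Returns the shipped RNA Watson-Crick stack free energies (dG at 37 C,
#' kcal/mol; Xia et al. 1998 set) as a named numeric vector keyed by the
#' 5'->3' dinucleotide step. Sequences are canonicalized to RNA (T -> U)
#' before lookup.
#'
#' @return Named numeric vector of length 16.
#' @export
nn_stack_table <- function() {
  if (is.null(.thermo_env$xia1998)) {
    path <- system.file("extdata", "nn_stacks_dg37.tsv",
                        package = "amirephys", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .thermo_env$xia1998 <- stats::setNames(tab$dg37, tab$stack)
  }
  .thermo_env$xia1998
}

#' Thermodynamic asymmetry configuration
#'
#' Terminal duplex energies are stack-only sums over `terminal_window_bp`
#' nearest-neighbor steps at each 5' end (dangling ends and terminal AU
#' penalties are omitted). The asymmetry `delta = Eas - Es` is accepted when
#' the antisense 5' end is the more stable one (`Eas < Es`) and `delta` lies
#' in `[delta_lo, delta_hi]` (defaults -5 to -3, in the units of the table,
#' kcal/mol by default).
#'
#' @param terminal_window_bp number of stack steps summed at each end (2-10).
#' @param delta_lo,delta_hi inclusive acceptance band for `delta`.
#' @param nn_table named numeric stack table; `NULL` uses [nn_stack_table()].
#' @return A `thermo_config` list.
#' @export
thermo_config <- function(terminal_window_bp = 5L, delta_lo = -5,
                          delta_hi = -3, nn_table = NULL) {
  terminal_window_bp <- as.integer(terminal_window_bp)
  if (terminal_window_bp < 2L || terminal_window_bp > 10L) {
    stop("terminal_window_bp must be in 2..10")
  }
  if (delta_lo > delta_hi) stop("delta_lo must be <= delta_hi")
  structure(list(terminal_window_bp = terminal_window_bp,
                 delta_lo = delta_lo, delta_hi = delta_hi,
                 nn_table = nn_table),
            class = "thermo_config")
}

thermo_table <- function(cfg) {
  if (is.null(cfg$nn_table)) nn_stack_table() else cfg$nn_table
}

#' 5' terminal duplex energy
#'
#' Free energy of the terminal window at one 5' end of the duplex implied by
#' `sense` and its reverse complement: the sum of nearest-neighbor stack
#' energies over the first `terminal_window_bp` base-pair steps reading from
#' that end. `end = "sense5p"` gives Es; `end = "antisense5p"` gives Eas
#' (equivalently, the window at the sense strand's 3' end, read on the
#' antisense strand).
#'
#' @param sense the 21-nt sense strand (`nuc_seq` or character).
#' @param end `"sense5p"` or `"antisense5p"`.
#' @param cfg a [thermo_config()].
#' @return Energy in the table's units (kcal/mol for the shipped set).
#' @export
end_energy <- function(sense, end = c("sense5p", "antisense5p"),
                       cfg = thermo_config()) {
  end <- match.arg(end)
  s <- chartr("T", "U", seq_str(sense))
  w <- cfg$terminal_window_bp
  if (nchar(s) < w + 1L) {
    stop("sequence shorter than terminal_window_bp + 1")
  }
  if (end == "antisense5p") {
    s <- paste(rev(strsplit(chartr("ACGU", "UGCA", s), "",
                            fixed = TRUE)[[1]]), collapse = "")
  }
  tab <- thermo_table(cfg)
  steps <- substring(s, 1:w, 2:(w + 1L))
  miss <- setdiff(steps, names(tab))
  if (length(miss)) stop("no stack parameter for: ",
                         paste(miss, collapse = ", "))
  sum(tab[steps])
}

#' Duplex asymmetry energies
#'
#' Es, Eas and `delta = Eas - Es` for one duplex, plus the acceptance verdict
#' `Eas < Es` and `delta_lo <= delta <= delta_hi`.
#'
#' @inheritParams end_energy
#' @return list with `Es`, `Eas`, `delta`, `accepted`.
#' @export
duplex_energy <- function(sense, cfg = thermo_config()) {
  Es <- end_energy(sense, "sense5p", cfg)
  Eas <- end_energy(sense, "antisense5p", cfg)
  delta <- Eas - Es
  list(Es = Es, Eas = Eas, delta = delta,
       accepted = (Eas < Es) && delta >= cfg$delta_lo &&
                  delta <= cfg$delta_hi)
}

#' Annotate candidates with 5' asymmetry energies
#'
#' Appends `Es`, `Eas`, `delta` and `thermo_accepted` to a candidate frame
#' (as produced by [scan_candidates()], or any frame with a `sense21`
#' column). The accepted subset satisfies `Eas < Es` and
#' `delta in [delta_lo, delta_hi]` exactly.
#'
#' @param candidates data.frame with a `sense21` column.
#' @param cfg a [thermo_config()].
#' @param accepted_only drop non-accepted rows?
#' @return The annotated (optionally filtered) data.frame.
#' @export
asymmetry_filter <- function(candidates, cfg = thermo_config(),
                             accepted_only = FALSE) {
  stopifnot(is.data.frame(candidates), "sense21" %in% names(candidates))
  if (nrow(candidates)) {
    en <- lapply(candidates$sense21, duplex_energy, cfg = cfg)
    candidates$Es <- vapply(en, `[[`, 0, "Es")
    candidates$Eas <- vapply(en, `[[`, 0, "Eas")
    candidates$delta <- vapply(en, `[[`, 0, "delta")
    candidates$thermo_accepted <- vapply(en, `[[`, NA, "accepted")
  } else {
    candidates$Es <- double()
    candidates$Eas <- double()
    candidates$delta <- double()
    candidates$thermo_accepted <- logical()
  }
  if (accepted_only) {
    candidates <- candidates[candidates$thermo_accepted, , drop = FALSE]
    rownames(candidates) <- NULL
  }
  candidates
}
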
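#' Identified nucleotide sequence
#'
#' `nuc_seq()` normalizes raw text into a nucleotide sequence object:
#' whitespace and digits are stripped, letters are uppercased, and the
#' alphabet is auto-detected (any `U` forces RNA, otherwise DNA). Symbols
#' outside `A`, `C`, `G`, `T`, `U` are rejected with the offending symbol and
#' its 1-based offset; IUPAC ambiguity codes are not expanded. A DNA sequence
#' may never contain `U` and an RNA sequence may never contain `T`.
#'
#' @param raw character scalar (or an existing `nuc_seq`, returned relabelled).
#' @param id sequence identifier.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to auto-detect.
#' @return An object of class `nuc_seq`: a list with elements `id`, `seq`
#'   (uppercase string) and `alphabet`.
#' @examples
#' nuc_seq("accggtGTCGAC")   # DNA, uppercased
#' nuc_seq("ACGU")           # U forces RNA
#' @export
nuc_seq <- function(raw, id = "seq", alphabet = NULL) {
  if (inherits(raw, "nuc_seq")) {
    raw <- raw$seq
  }
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("'raw' must be a single character string")
  }
  s <- toupper(gsub("[[:space:][:digit:]]", "", raw))
  if (!nzchar(s)) stop("empty sequence after whitespace/digit removal")
  bad <- regexpr("[^ACGTU]", s)
  if (bad > 0L) {
    stop(sprintf("illegal symbol '%s' at offset %d", substr(s, bad, bad), bad))
  }
  has_t <- grepl("T", s, fixed = TRUE)
  has_u <- grepl("U", s, fixed = TRUE)
  if (is.null(alphabet)) {
    alphabet <- if (has_u) "RNA" else "DNA"
  }
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  if (alphabet == "DNA" && has_u) stop("DNA sequence contains 'U'")
  if (alphabet == "RNA" && has_t) stop("RNA sequence contains 'T'")
  structure(list(id = as.character(id), seq = s, alphabet = alphabet),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  s <- x$seq
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("<nuc_seq %s> %s (%d nt, %s)\n", x$alphabet, s,
              nchar(x$seq), x$id))
  invisible(x)
}

#' @export
as.character.nuc_seq <- function(x, ...) x$seq

# Coerce character or nuc_seq input; returns a nuc_seq.
as_nuc_seq <- function(x, id = "seq") {
  if (inherits(x, "nuc_seq")) x else nuc_seq(x, id = id)
}

# Plain uppercase string from character or nuc_seq input.
seq_str <- function(x) {
  if (inherits(x, "nuc_seq")) x$seq else as_nuc_seq(x)$seq
}

# DNA-canonical string (U -> T) used wherever T and U compare as equal.
canon_dna <- function(x) chartr("U", "T", seq_str(x))

#' Reverse complement
#'
#' Watson-Crick reverse complement in the same alphabet as the input.
#' `revcomp(revcomp(x))` is the identity.
#'
#' @param x a `nuc_seq` or character scalar.
#' @return A `nuc_seq` in the input's alphabet (id suffixed with `_rc`).
#' @examples
#' as.character(revcomp("TAATGAGCCACACTTGGAGGT"))
#' @export
revcomp <- function(x) {
  x <- as_nuc_seq(x)
  comp <- if (x$alphabet == "RNA") chartr("ACGU", "UGCA", x$seq)
          else chartr("ACGT", "TGCA", x$seq)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  nuc_seq(rc, id = paste0(x$id, "_rc"), alphabet = x$alphabet)
}

# reverse-complement on a plain DNA-canonical string (fast path, no checks)
revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

#' GC content in percent
#'
#' @param x a `nuc_seq` or character scalar (length >= 1).
#' @return `100 * (#G + #C) / length` as a double.
#' @examples
#' gc_percent("TAATGAGCCACACTTGGAGGT")  # 47.619
#' @export
gc_percent <- function(x) {
  s <- seq_str(x)
  n <- nchar(s)
  if (n < 1L) stop("empty sequence")
  100 * nchar(gsub("[^GC]", "", s)) / n
}

#' Longest homopolymer run
#'
#' Length of the longest run of one identical base; used by the candidate
#' filter that rejects runs of four or more.
#'
#' @param x a `nuc_seq` or character scalar.
#' @return Integer run length (<= sequence length).
#' @examples
#' max_homopolymer_run("GTTTTGGCCACTGACTGAC")  # 4
#' @export
max_homopolymer_run <- function(x) {
  ch <- strsplit(seq_str(x), "", fixed = TRUE)[[1]]
  if (!length(ch)) stop("empty sequence")
  max(rle(ch)$lengths)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O that return/accept lists of
#' [nuc_seq()] records (normalized: uppercase, alphabet auto-detected).
#' Duplicate record identifiers raise a warning; both records are kept.
#' `read_fasta(write_fasta(x))` is the identity on normalized records.
#'
#' @param path file path.
#' @param seqs list of `nuc_seq` (or character vector, possibly named).
#' @param width line-wrap width on write.
#' @return `read_fasta`: a list of `nuc_seq`. `write_fasta`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  if (!startsWith(lines[1], ">")) {
    stop("malformed FASTA: first record lacks a '>' header")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            " (all records kept)")
  }
  mapply(function(s, id) nuc_seq(s, id = id),
         as.character(set), ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ids <- if (is.null(names(seqs))) paste0("seq", seq_along(seqs))
           else names(seqs)
    seqs <- mapply(nuc_seq, seqs, ids, SIMPLIFY = FALSE)
  }
  x <- Biostrings::BStringSet(vapply(seqs, function(s) s$seq, ""))
  names(x) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(x, path, width = as.integer(width))
  invisible(path)
}
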
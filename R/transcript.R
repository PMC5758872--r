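#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U (so DNA-form FASTA as served by Ensembl is
#' accepted), and validates that only A, C, G, U remain.
#'
#' @param x character scalar, nucleotide sequence.
#' @return character scalar over \{A,C,G,U\}.
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- which(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "U"))
  if (length(bad) > 0L) {
    stop("non-ACGU characters after normalization at positions: ",
         paste(utils::head(bad, 20L), collapse = ", "))
  }
  s
}

#' Construct a transcript record
#'
#' A transcript is a named RNA sequence with an annotated 3'UTR start.
#' `utr_start` is the 0-based offset where the 3'UTR begins within `seq`;
#' everything before it is trailing CDS context (so `cds_end_context ==
#' utr_start` by construction). All coordinates in the package are 0-based
#' half-open on the sense strand.
#'
#' @param id character scalar identifier.
#' @param seq nucleotide string (T accepted, normalized to U).
#' @param utr_start integer >= 0, 0-based offset of the 3'UTR start.
#' @param source free-text provenance (e.g. an Ensembl transcript ID).
#' @param gene optional gene/group label used by [select_longest_utr()].
#' @return object of class `transcript`.
#' @export
transcript <- function(id, seq, utr_start = 0L, source = "", gene = NA_character_) {
  seq <- normalize_rna(seq)
  utr_start <- as.integer(utr_start)
  if (is.na(utr_start) || utr_start < 0L || utr_start > nchar(seq)) {
    stop("utr_start must be in [0, nchar(seq)] for transcript '", id, "'")
  }
  structure(list(id = as.character(id), seq = seq, utr_start = utr_start,
                 cds_end_context = utr_start, source = as.character(source),
                 gene = as.character(gene)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript>", x$id, " (", nchar(x$seq), " nt, utr_start=",
      x$utr_start, ")\n", sep = "")
  invisible(x)
}

#' 3'UTR length of a transcript
#' @param t a `transcript`.
#' @return integer, number of UTR nucleotides.
#' @export
utr_length <- function(t) nchar(t$seq) - t$utr_start

#' Construct a 0-based half-open interval
#'
#' @param start 0-based inclusive start.
#' @param end exclusive end, `end >= start`.
#' @return integer vector `c(start, end)` of class `interval`.
#' @export
iv <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end < start) {
    stop("invalid interval [", start, ",", end, ")")
  }
  structure(c(start = start, end = end), class = "interval")
}

iv_len <- function(x) unname(x[2L] - x[1L])

check_iv_in <- function(x, n, what = "interval") {
  if (x[1L] < 0L || x[2L] > n) {
    stop(what, " [", x[1L], ",", x[2L], ") out of bounds for length ", n)
  }
  invisible(x)
}

#' Extract the subsequence covered by an interval
#' @param seq character scalar sequence.
#' @param x interval from [iv()].
#' @return character scalar.
#' @export
iv_seq <- function(seq, x) {
  check_iv_in(x, nchar(seq))
  if (iv_len(x) == 0L) return("")
  substr(seq, x[1L] + 1L, x[2L])
}
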
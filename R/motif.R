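#' Canonical motif class of an SSR repeat unit
#'
#' Collapses a repeat unit to its strand- and phase-independent motif class,
#' the convention used when reporting microsatellite composition (e.g. a
#' dinucleotide tract read as \code{TC}, \code{CT}, \code{GA} or \code{AG} is
#' always reported as class \code{"AG/CT"}). The class label is \code{"X/Y"}
#' where \code{X} is the lexicographically smallest string among all cyclic
#' rotations of the motif and of its reverse complement, and \code{Y} is the
#' reverse complement of \code{X}. Palindromic classes such as \code{"AT/AT"}
#' are legal.
#'
#' @param motif Character scalar, repeat unit of length 1--6 over
#'   \code{A,C,G,T}. Must be primitive, i.e. not itself a repetition of a
#'   shorter unit (\code{"ATAT"} is rejected; its tract belongs to the
#'   \code{"AT/AT"} dinucleotide class).
#' @return Character scalar, the \code{"X/Y"} motif class label.
#' @examples
#' canonical_motif("TC")   # "AG/CT"
#' canonical_motif("A")    # "A/T"
#' canonical_motif("CCT")  # "AGG/CCT"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L)
  motif <- toupper(motif)
  u <- nchar(motif)
  if (u < 1L || u > 6L)
    stop("invalid motif: unit length must be 1-6, got ", u)
  bases <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("invalid motif: non-ACGT character in '", motif, "'")
  if (!is_primitive_unit(motif))
    stop("invalid motif: '", motif, "' is a repetition of a shorter unit")
  x <- min(c(cyclic_rotations(motif), cyclic_rotations(revcomp(motif))))
  paste(x, revcomp(x), sep = "/")
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character scalar over \code{A,C,G,T,N} (case preserved as upper).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

cyclic_rotations <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(x)
  xx <- paste0(x, x)
  vapply(seq_len(n), function(i) substr(xx, i, i + n - 1L), character(1))
}

# A unit is primitive iff no proper divisor d of its length tiles it.
is_primitive_unit <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        x == paste(rep(substr(x, 1L, d), n %/% d), collapse = ""))
      return(FALSE)
  }
  TRUE
}
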
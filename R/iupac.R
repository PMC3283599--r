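# IUPAC nucleotide codes as bitmasks (A=1, C=2, G=4, T=8) so that set
# intersection/union are single bitwAnd/bitwOr calls.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.BITS_CODE <- character(15L)
.BITS_CODE[.IUPAC_BITS] <- names(.IUPAC_BITS)

.BASES <- c("A", "C", "G", "T")

#' Convert an IUPAC nucleotide code to its base set
#'
#' @param code Single IUPAC letter (case-insensitive).
#' @return Character vector of the unambiguous bases the code stands for.
#' @examples
#' iupac_to_set("R") # A, G
#' @export
iupac_to_set <- function(code) {
  bits <- .iupac_bits(code)
  .BASES[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Convert a set of bases to the IUPAC code
#'
#' @param bases Character vector drawn from A, C, G, T (duplicates allowed).
#' @return A single IUPAC letter.
#' @examples
#' set_to_iupac(c("A", "G")) # "R"
#' @export
set_to_iupac <- function(bases) {
  bases <- toupper(bases)
  bad <- setdiff(unique(bases), .BASES)
  if (length(bad)) stop("not nucleotide bases: ", paste(bad, collapse = ","))
  .BITS_CODE[Reduce(bitwOr, .IUPAC_BITS[bases])]
}

.iupac_bits <- function(codes) {
  bits <- .IUPAC_BITS[toupper(codes)]
  if (anyNA(bits)) {
    stop("invalid IUPAC code(s): ",
         paste(unique(codes[is.na(bits)]), collapse = ","))
  }
  unname(bits)
}

#' Test, intersect and union IUPAC codes
#'
#' `iupac_compatible()` is TRUE where the base sets of two codes intersect;
#' `iupac_intersect()` returns the code of the intersection (NA where empty);
#' `iupac_union()` the code of the union. All three are vectorised.
#'
#' @param a,b IUPAC letters (vectors recycled to common length).
#' @return Logical vector, or character vector of IUPAC codes.
#' @export
iupac_compatible <- function(a, b) {
  bitwAnd(.iupac_bits(a), .iupac_bits(b)) > 0L
}

#' @rdname iupac_compatible
#' @export
iupac_intersect <- function(a, b) {
  bits <- bitwAnd(.iupac_bits(a), .iupac_bits(b))
  out <- rep(NA_character_, length(bits))
  out[bits > 0L] <- .BITS_CODE[bits[bits > 0L]]
  out
}

#' @rdname iupac_compatible
#' @export
iupac_union <- function(a, b) {
  .BITS_CODE[bitwOr(.iupac_bits(a), .iupac_bits(b))]
}

.is_ambiguous <- function(codes) !(toupper(codes) %in% .BASES)

.char_split <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Pairwise p-distance between two aligned sequences
#'
#' Uncorrected proportion of differing sites. Sites where either sequence has
#' a gap (`-`) are skipped. Sites where either sequence carries an IUPAC
#' ambiguity code are skipped when the two base sets intersect (an ambiguity
#' produced by damage must not inflate distance) and counted as differences
#' when they do not.
#'
#' @param x,y Equal-length sequence strings (or character vectors of single
#'   letters).
#' @return Distance in `[0, 1]`, with attributes `n_compared` and `n_diff`.
#'   `NaN` when no site is comparable.
#' @export
p_distance <- function(x, y) {
  if (length(x) == 1L) x <- .char_split(x)
  if (length(y) == 1L) y <- .char_split(y)
  if (length(x) != length(y)) stop("sequences have different lengths")
  keep <- x != "-" & y != "-"
  x <- toupper(x[keep]); y <- toupper(y[keep])
  amb <- .is_ambiguous(x) | .is_ambiguous(y)
  compat <- iupac_compatible(x, y)
  use <- !amb | !compat              # plain sites, plus incompatible ambiguous
  diff <- !compat & use
  d <- sum(diff) / sum(use)
  structure(d, n_compared = sum(use), n_diff = sum(diff))
}
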
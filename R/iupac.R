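#' @useDynLib cnescan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide code -> set of unambiguous bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# 4-bit encoding (A=1, C=2, G=4, T=8); a code's bits are the union of its set.
.iupac_bits <- local({
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(IUPAC_SETS, function(s) sum(base_bit[s]), integer(1))
})

.seq_chars <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) x <- as.character(x)
  if (is.list(x) && !is.null(x$residues)) x <- x$residues
  stopifnot(is.character(x), length(x) == 1L)
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

.check_iupac <- function(chars, what = "sequence") {
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' in %s at position %d",
                 chars[bad[1]], what, bad[1]), call. = FALSE)
  }
  invisible(chars)
}

#' Reverse complement of a nucleotide string
#'
#' Complements all 15 IUPAC codes (e.g. W -> W, H -> D) and reverses the
#' string, so degenerate motifs such as the terminal dyad core \code{WTTWTG}
#' can be flipped as patterns, not just concrete sequences.
#'
#' @param x A character string, \code{Biostrings} XString, or a list with a
#'   \code{residues} field. Case-insensitive; returned uppercase.
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("TTTTTG")   # "CAAAAA"
#' reverse_complement("WTTWTG")   # "CAWAAW"
#' @export
reverse_complement <- function(x) {
  chars <- .seq_chars(x)
  if (length(chars) == 0L) return("")
  .check_iupac(chars)
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Match a degenerate IUPAC pattern against one window
#'
#' @param pattern IUPAC pattern string (all 15 codes allowed).
#' @param window Concrete sequence window of the same length. Ambiguity codes
#'   in the window only match pattern positions whose base set contains them
#'   (an \code{N} in genomic input never satisfies e.g. a \code{W}).
#' @return \code{TRUE} iff every window base is a member of the corresponding
#'   pattern code's base set.
#' @examples
#' iupac_match("WTTWTG", "TTTTTG")  # TRUE
#' iupac_match("WTTWTG", "CTTTTG")  # FALSE
#' @export
iupac_match <- function(pattern, window) {
  p <- .check_iupac(.seq_chars(pattern), "pattern")
  w <- .check_iupac(.seq_chars(window), "window")
  if (length(p) != length(w)) {
    stop("pattern and window lengths differ (", length(p), " vs ", length(w), ")",
         call. = FALSE)
  }
  if (length(p) == 0L) return(TRUE)
  pb <- .iupac_bits[p]
  wb <- .iupac_bits[w]
  all(bitwAnd(pb, wb) == wb)
}

#' All start positions where a pattern matches a sequence
#'
#' Vectorised subset-matching over every offset: position i is reported when
#' for each k, the subject base set at i+k-1 is contained in the pattern code
#' set at k. Used by the dyad detector and the genome scanner.
#'
#' @param pattern IUPAC pattern string.
#' @param subject Subject sequence (IUPAC alphabet).
#' @return Sorted integer vector of 1-based start positions (possibly empty).
#' @export
iupac_match_positions <- function(pattern, subject) {
  p <- .check_iupac(.seq_chars(pattern), "pattern")
  s <- .check_iupac(.seq_chars(subject), "subject")
  m <- length(p); L <- length(s)
  if (m == 0L || L < m) return(integer(0))
  pb <- unname(.iupac_bits[p])
  sb <- unname(.iupac_bits[s])
  n_off <- L - m + 1L
  ok <- rep(TRUE, n_off)
  for (k in seq_len(m)) {
    wk <- sb[k:(k + n_off - 1L)]
    ok <- ok & (bitwAnd(pb[k], wk) == wk)
  }
  which(ok)
}

# Smallest IUPAC code covering a set of unambiguous bases.
iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  stopifnot(all(bases %in% c("A", "C", "G", "T")), length(bases) >= 1L)
  for (code in names(IUPAC_SETS)) {
    if (setequal(IUPAC_SETS[[code]], bases)) return(code)
  }
  stop("unreachable")
}

# Normalise raw residues for analysis input: uppercase, restricted alphabet.
normalize_residues <- function(x, allow = c("A", "C", "G", "T", "N")) {
  chars <- .seq_chars(x)
  if (length(chars) == 0L) stop("empty sequence", call. = FALSE)
  bad <- which(!chars %in% allow)
  if (length(bad)) {
    stop(sprintf("disallowed character '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)
  }
  paste(chars, collapse = "")
}
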
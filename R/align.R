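# Progressive multiple alignment for CNE-scale families.
#
# The guide tree is UPGMA (average-linkage hclust) over pairwise k-mer
# distances; profiles are merged bottom-up with an affine-gap profile
# Needleman-Wunsch (Gotoh) implemented in C++. Scoring is deliberately
# simple -- match +1 / mismatch -1, gap of length k costs open + k*extend --
# which is adequate and fully reproducible for 150-200 bp families.

.profile_counts <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  counts <- matrix(0, nrow = 4L, ncol = ncol(mat),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in c("A", "C", "G", "T")) counts[b, ] <- colSums(mat == b)
  counts
}

.apply_path <- function(seqs, path) {
  # path: per alignment column, source column (1-based) or 0 for gap
  chars <- strsplit(seqs, "", fixed = TRUE)
  out <- vapply(chars, function(ch) {
    res <- rep("-", length(path))
    res[path > 0L] <- ch[path[path > 0L]]
    paste(res, collapse = "")
  }, character(1))
  names(out) <- names(seqs)
  out
}

.align_two_profiles <- function(seqs1, seqs2, match, mismatch, gap_open, gap_extend) {
  res <- profile_align_cpp(.profile_counts(seqs1), .profile_counts(seqs2),
                           length(seqs1), length(seqs2),
                           match, mismatch, gap_open, gap_extend)
  c(.apply_path(seqs1, res$path1), .apply_path(seqs2, res$path2))
}

#' Pairwise k-mer distances between sequences
#'
#' Distance is 1 minus the fraction of shared k-mers (multiset intersection
#' over the smaller k-mer count). Only used to build the guide tree, so a
#' coarse measure is fine.
#'
#' @param seqs Named character vector of ungapped sequences.
#' @param k Word size; shrunk automatically for very short inputs.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
kmer_distance <- function(seqs, k = 4L) {
  n <- length(seqs)
  k <- max(1L, min(as.integer(k), min(nchar(seqs))))
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    words <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
    table(words)
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- counts[[i]]; cj <- counts[[j]]
      shared <- intersect(names(ci), names(cj))
      ov <- sum(pmin(ci[shared], cj[shared]))
      denom <- min(sum(ci), sum(cj))
      d[i, j] <- d[j, i] <- 1 - ov / denom
    }
  }
  d
}

#' Progressive global alignment of a sequence family
#'
#' Aligns a family of homologous sequences (e.g. the CNE repertoire of a
#' virus genus) by progressive profile merging along a UPGMA guide tree built
#' from k-mer distances. Deterministic for fixed inputs and parameters:
#' DP tie-breaks prefer diagonal, then up, then left, and guide-tree ties
#' follow input order.
#'
#' @param seqs Named character vector (>= 2 sequences) or the value of
#'   \code{\link{read_fasta}}.
#' After the progressive stage, \code{refine_rounds} rounds of leave-one-out
#' refinement realign each sequence against the profile of the others, which
#' repairs gaps frozen in a suboptimal position by an early pairwise merge.
#'
#' @param gap_open,gap_extend Affine gap penalties (a gap of length k costs
#'   \code{gap_open + k * gap_extend}).
#' @param match,mismatch Substitution scores.
#' @param k Guide-tree word size.
#' @param refine_rounds Leave-one-out refinement rounds (default 2; 0
#'   disables refinement).
#' @return A \code{\link{new_alignment}} object; records keep input order.
#' @examples
#' aln <- align_family(c(s1 = "ACGTACGTACGT", s2 = "ACGTAGTACGT"))
#' aln$n_cols
#' @export
align_family <- function(seqs, gap_open = 5, gap_extend = 1,
                         match = 1, mismatch = -1, k = 4L, refine_rounds = 2L) {
  seqs <- unclass(seqs)
  attr(seqs, "descriptions") <- NULL
  if (length(seqs) < 2L) stop("need at least 2 sequences to align", call. = FALSE)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  seqs <- vapply(seqs, normalize_residues, character(1))

  if (length(seqs) == 2L) {
    merged <- .align_two_profiles(seqs[1], seqs[2], match, mismatch,
                                  gap_open, gap_extend)
    return(new_alignment(merged[names(seqs)]))
  }

  d <- kmer_distance(seqs, k = k)
  tree <- stats::hclust(stats::as.dist(d), method = "average")  # UPGMA
  profiles <- lapply(seq_along(seqs), function(i) seqs[i])
  merged_nodes <- vector("list", nrow(tree$merge))
  node <- function(idx) if (idx < 0) profiles[[-idx]] else merged_nodes[[idx]]
  for (r in seq_len(nrow(tree$merge))) {
    left <- node(tree$merge[r, 1]); right <- node(tree$merge[r, 2])
    merged_nodes[[r]] <- .align_two_profiles(left, right, match, mismatch,
                                             gap_open, gap_extend)
  }
  final <- merged_nodes[[nrow(tree$merge)]][names(seqs)]
  final <- .refine_alignment(final, match, mismatch, gap_open, gap_extend,
                             rounds = refine_rounds)
  new_alignment(final)
}

# drop columns that are gaps in every record
.drop_allgap_cols <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  keep <- colSums(mat != "-") > 0L
  stats::setNames(apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""),
                  names(seqs))
}

# Leave-one-out refinement: realign each sequence, ungapped, against the
# profile of the remaining records. Deterministic fixed sweep order.
.refine_alignment <- function(seqs, match, mismatch, gap_open, gap_extend,
                              rounds = 2L) {
  if (rounds <= 0L || length(seqs) < 3L) return(seqs)
  for (r in seq_len(rounds)) {
    for (i in seq_along(seqs)) {
      others <- .drop_allgap_cols(seqs[-i])
      single <- stats::setNames(gsub("-", "", seqs[i], fixed = TRUE),
                                names(seqs)[i])
      merged <- .align_two_profiles(others, single, match, mismatch,
                                    gap_open, gap_extend)
      seqs <- merged[names(seqs)]
    }
  }
  seqs
}

#' Score a pair of gapped sequences under the aligner's objective
#'
#' Columns where both records have a gap are dropped; remaining columns score
#' match/mismatch, and each maximal gap run of length k in either record costs
#' \code{gap_open + k * gap_extend} (terminal gaps included).
#'
#' @param s1,s2 Gapped strings of equal length.
#' @inheritParams align_family
#' @return Numeric alignment score.
#' @export
pairwise_alignment_score <- function(s1, s2, gap_open = 5, gap_extend = 1,
                                     match = 1, mismatch = -1) {
  a <- .seq_chars(s1); b <- .seq_chars(s2)
  stopifnot(length(a) == length(b))
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  both <- a != "-" & b != "-"
  score <- sum(ifelse(a[both] == b[both], match, mismatch))
  for (g in list(rle(a == "-"), rle(b == "-"))) {
    runs <- g$lengths[g$values]
    if (length(runs)) score <- score - sum(gap_open + runs * gap_extend)
  }
  score
}

#' Percent-identity matrix of an alignment
#'
#' Identity of a pair is 100 x (columns where both records are non-gap and
#' equal) / (columns where both are non-gap); a pair with no co-aligned
#' columns is reported as \code{NA}, not 0. This is the co-aligned-column
#' denominator (not total alignment length); with it, published CNE families
#' span roughly 66-100\% identity.
#'
#' @param aln A \code{cne_alignment}.
#' @return List with \code{ids}, \code{values} (symmetric percent matrix,
#'   diagonal 100), and off-diagonal \code{min}/\code{max} summaries.
#' @export
pairwise_identity <- function(aln) {
  stopifnot(inherits(aln, "cne_alignment"))
  mat <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  n <- nrow(mat)
  values <- matrix(100, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      values[i, j] <- values[j, i] <-
        if (!any(both)) NA_real_ else 100 * mean(mat[i, both] == mat[j, both])
    }
  }
  off <- values[upper.tri(values)]
  structure(list(ids = aln$ids, values = values,
                 min = if (all(is.na(off))) NA_real_ else min(off, na.rm = TRUE),
                 max = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)),
            class = "identity_matrix")
}

#' @export
print.identity_matrix <- function(x, ...) {
  cat(sprintf("<identity_matrix> %d ids, off-diagonal %.1f-%.1f%%\n",
              length(x$ids), x$min, x$max))
  invisible(x)
}
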
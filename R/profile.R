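# Per-column conservation statistics of a family alignment, the consensus
# string with the uppercase / lowercase / 'n' / '.' convention used for CNE
# consensus figures, and segmentation of absolutely conserved columns into
# discrete clusters (c1..ck).

#' Per-column profile of an alignment
#'
#' For every column: base counts, gap count, non-gap coverage, modal base and
#' frequency (over unambiguous non-gap residues), information content, and a
#' flag for absolute conservation. Information content is R = 2 - H bits,
#' where H is the Shannon entropy of the base frequencies; \code{ic_display}
#' scales R by the coverage fraction the way sequence-logo stacks are drawn.
#' No small-sample correction is applied (negligible at family sizes near 38).
#'
#' A column is "absolutely conserved" when every record has the same
#' unambiguous residue: modal frequency exactly 1 with zero gaps and zero Ns.
#'
#' @param aln A \code{cne_alignment}.
#' @return Data frame of class \code{cne_profile}, one row per column, with
#'   attribute \code{n_records}.
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "cne_alignment"))
  mat <- do.call(rbind, strsplit(unname(aln$seqs), "", fixed = TRUE))
  n <- nrow(mat)
  counts <- sapply(c("A", "C", "G", "T", "N", "-"), function(b) colSums(mat == b))
  counts <- matrix(counts, ncol = 6, dimnames = list(NULL, c("A", "C", "G", "T", "N", "gap")))
  base_counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  tot <- rowSums(base_counts)
  coverage <- (n - counts[, "gap"]) / n

  modal_idx <- max.col(base_counts, ties.method = "first")
  modal_count <- base_counts[cbind(seq_len(nrow(counts)), modal_idx)]
  modal_tie <- rowSums(base_counts == modal_count & base_counts > 0) > 1L
  modal_base <- c("A", "C", "G", "T")[modal_idx]
  modal_base[tot == 0] <- NA_character_
  modal_freq <- ifelse(tot > 0, modal_count / tot, NA_real_)

  ic <- apply(base_counts, 1L, function(cnt) {
    s <- sum(cnt)
    if (s == 0) return(0)
    p <- cnt[cnt > 0] / s
    2 + sum(p * log2(p))
  })
  ic[tot == 0] <- 0

  conserved <- tot == n & modal_count == n

  prof <- data.frame(
    col = seq_len(aln$n_cols),
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"],
    N = counts[, "N"], gap = counts[, "gap"],
    coverage = coverage, modal_base = modal_base, modal_freq = modal_freq,
    modal_tie = modal_tie, ic = ic, ic_display = ic * coverage,
    conserved = conserved, stringsAsFactors = FALSE
  )
  attr(prof, "n_records") <- n
  class(prof) <- c("cne_profile", "data.frame")
  prof
}

#' Consensus string from a column profile
#'
#' Per column: \code{'.'} when the gap fraction exceeds \code{gap_threshold}
#' (the majority of records carry a gap); else the uppercase modal base when
#' the modal frequency reaches \code{upper_threshold} (complete conservation
#' by default); else the lowercase modal base when it reaches
#' \code{lower_threshold} (50\% or greater); else \code{'n'}. A tie between
#' two modal bases at or above the lower threshold yields \code{'n'}.
#'
#' @param profile A \code{cne_profile}.
#' @param upper_threshold,lower_threshold,gap_threshold Fractions in (0, 1].
#' @return Consensus string, one character per alignment column.
#' @export
consensus_string <- function(profile, upper_threshold = 1.0,
                             lower_threshold = 0.5, gap_threshold = 0.5) {
  stopifnot(inherits(profile, "cne_profile"),
            upper_threshold > 0, upper_threshold <= 1,
            lower_threshold > 0, lower_threshold <= upper_threshold,
            gap_threshold > 0, gap_threshold <= 1)
  n <- attr(profile, "n_records")
  gap_frac <- profile$gap / n
  out <- character(nrow(profile))
  for (i in seq_len(nrow(profile))) {
    if (gap_frac[i] > gap_threshold || is.na(profile$modal_freq[i])) {
      out[i] <- "."
    } else if (!profile$modal_tie[i] && profile$modal_freq[i] >= upper_threshold) {
      out[i] <- profile$modal_base[i]
    } else if (!profile$modal_tie[i] && profile$modal_freq[i] >= lower_threshold) {
      out[i] <- tolower(profile$modal_base[i])
    } else {
      out[i] <- "n"
    }
  }
  paste(out, collapse = "")
}

#' Segment absolutely conserved columns into discrete clusters
#'
#' Clusters are maximal chains of absolutely conserved columns in which
#' consecutive conserved columns are separated by at most
#' \code{max_intervening} non-conserved columns; chains carrying fewer than
#' \code{min_conserved} conserved columns are discarded. Labels run left to
#' right (c1, c2, ...). When dyad elements (in consensus coordinates) are
#' supplied, clusters overlapping an arm are categorised \code{dyad-arm};
#' otherwise clusters whose modal-base sequence contains the TAT triplet are
#' \code{TAT-containing}; the rest are \code{other}.
#'
#' @param profile A \code{cne_profile}.
#' @param max_intervening Maximum non-conserved columns bridged within a
#'   cluster (default 2).
#' @param min_conserved Minimum conserved columns per reported cluster
#'   (default 3).
#' @param dyads Optional list of \code{dyad_element}s located on the
#'   ungapped consensus/template, used only for categorisation.
#' @return Data frame: \code{label,start_col,end_col,n_conserved,category}.
#' @export
segment_clusters <- function(profile, max_intervening = 2L, min_conserved = 3L,
                             dyads = NULL) {
  stopifnot(inherits(profile, "cne_profile"))
  pos <- profile$col[profile$conserved]
  if (length(pos) == 0L) {
    return(data.frame(label = character(), start_col = integer(),
                      end_col = integer(), n_conserved = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  breaks <- which(diff(pos) - 1L > max_intervening)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pos))
  spans <- data.frame(start_col = pos[starts], end_col = pos[ends],
                      n_conserved = ends - starts + 1L)
  spans <- spans[spans$n_conserved >= min_conserved, , drop = FALSE]
  if (nrow(spans) == 0L) {
    return(data.frame(label = character(), start_col = integer(),
                      end_col = integer(), n_conserved = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  spans$label <- paste0("c", seq_len(nrow(spans)))

  arm_spans <- NULL
  if (!is.null(dyads)) {
    arm_spans <- do.call(rbind, lapply(dyads, function(d) {
      if (is.null(d)) return(NULL)
      rbind(c(d$left_start, d$left_end), c(d$right_start, d$right_end))
    }))
  }
  spans$category <- vapply(seq_len(nrow(spans)), function(i) {
    s <- spans$start_col[i]; e <- spans$end_col[i]
    if (!is.null(arm_spans) &&
        any(arm_spans[, 1] <= e & s <= arm_spans[, 2])) return("dyad-arm")
    modal <- profile$modal_base[s:e]
    modal[is.na(modal)] <- "n"
    if (grepl("TAT", paste(modal, collapse = ""), fixed = TRUE)) return("TAT-containing")
    "other"
  }, character(1))
  rownames(spans) <- NULL
  spans[, c("label", "start_col", "end_col", "n_conserved", "category")]
}

# cumulative ungapped position of each alignment column for one gapped record
.ungapped_index <- function(gapped) {
  ch <- strsplit(gapped, "", fixed = TRUE)[[1]]
  cumsum(ch != "-")
}

#' Inter-cluster spacing per sequence
#'
#' For each record, the ungapped distance (bp) between consecutive cluster
#' spans: start of the next cluster minus end of the previous one, minus 1.
#' A cluster whose span is fully deleted in a record gives missing distances
#' for its adjacent pairs.
#'
#' @param clusters Output of \code{\link{segment_clusters}} (>= 2 rows).
#' @param aln The \code{cne_alignment} the profile came from.
#' @return List with \code{distances} (records x adjacent pairs matrix) and
#'   \code{summary} (per pair: min, max, width of the observed range).
#' @export
cluster_spacings <- function(clusters, aln) {
  stopifnot(inherits(aln, "cne_alignment"), nrow(clusters) >= 2L)
  n_pair <- nrow(clusters) - 1L
  pair_names <- paste(clusters$label[-nrow(clusters)], clusters$label[-1], sep = "-")
  dist_mat <- matrix(NA_real_, nrow = length(aln$ids), ncol = n_pair,
                     dimnames = list(aln$ids, pair_names))
  for (s in seq_along(aln$ids)) {
    gapped <- aln$seqs[[s]]
    ch <- strsplit(gapped, "", fixed = TRUE)[[1]]
    upos <- cumsum(ch != "-")
    span_bounds <- lapply(seq_len(nrow(clusters)), function(i) {
      cols <- clusters$start_col[i]:clusters$end_col[i]
      nong <- cols[ch[cols] != "-"]
      if (!length(nong)) return(NULL)
      c(start = upos[nong[1]], end = upos[nong[length(nong)]])
    })
    for (p in seq_len(n_pair)) {
      a <- span_bounds[[p]]; b <- span_bounds[[p + 1L]]
      if (is.null(a) || is.null(b)) next
      dist_mat[s, p] <- b["start"] - a["end"] - 1
    }
  }
  summary <- data.frame(
    pair = pair_names,
    min = apply(dist_mat, 2, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)),
    max = apply(dist_mat, 2, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
  summary$width <- summary$max - summary$min
  rownames(summary) <- NULL
  list(distances = dist_mat, summary = summary)
}

#' AT share of the absolutely conserved columns
#'
#' @param profile A \code{cne_profile}.
#' @return Percent of absolutely conserved columns whose residue is A or T;
#'   \code{NA} when no column is absolutely conserved.
#' @export
at_fraction_of_conserved <- function(profile) {
  stopifnot(inherits(profile, "cne_profile"))
  cons <- profile[profile$conserved, , drop = FALSE]
  if (nrow(cons) == 0L) return(NA_real_)
  100 * mean(cons$modal_base %in% c("A", "T"))
}

#' Write a profile as TSV (one row per column)
#' @param profile A \code{cne_profile}.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
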
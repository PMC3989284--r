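#' AT content of a sequence
#'
#' Percent A+T among the unambiguous bases; ambiguity codes (N etc.) are
#' excluded from both numerator and denominator.
#'
#' @param seq Sequence string (or XString).
#' @return Percent in [0, 100]; \code{NA} when no unambiguous base exists.
#' @examples
#' at_content("ATAT")  # 100
#' at_content("ACGT")  # 50
#' @export
at_content <- function(seq) {
  chars <- .seq_chars(if (is.character(seq)) seq else as.character(seq))
  n_at <- sum(chars %in% c("A", "T"))
  n_tot <- sum(chars %in% c("A", "C", "G", "T"))
  if (n_tot == 0L) return(NA_real_)
  100 * n_at / n_tot
}

#' AT enrichment of a region over its background genome
#'
#' A region is called AT-rich under the two-part criterion used for the CNE:
#' its AT content must exceed 50\% and exceed the background (whole-genome)
#' AT content.
#'
#' @param region_seq Region sequence.
#' @param background_seq Background (e.g. whole genome) sequence.
#' @return Object of class \code{at_stats}: \code{region_at},
#'   \code{background_at}, \code{enrichment} (percentage points),
#'   \code{is_at_rich}.
#' @export
at_enrichment <- function(region_seq, background_seq) {
  region_at <- at_content(region_seq)
  background_at <- at_content(background_seq)
  structure(list(
    region_at = region_at,
    background_at = background_at,
    enrichment = region_at - background_at,
    is_at_rich = !is.na(region_at) && !is.na(background_at) &&
      region_at > 50 && region_at > background_at
  ), class = "at_stats")
}

#' @export
print.at_stats <- function(x, ...) {
  cat(sprintf("<at_stats> region %.1f%%, background %.1f%%, enrichment %+.1f pp, AT-rich: %s\n",
              x$region_at, x$background_at, x$enrichment, x$is_at_rich))
  invisible(x)
}

#' Compare AT content of listed regions against their parent sequences
#'
#' One row per region: region AT, background AT, enrichment, AT-rich flag;
#' a final \code{mean} row averages the numeric columns. Out-of-bounds
#' regions are reported with an error message and skipped.
#'
#' @param seqs Named character vector (e.g. from \code{\link{read_fasta}}).
#' @param regions List of \code{genomic_interval}s whose \code{seq_id}s name
#'   entries of \code{seqs}.
#' @return Data frame; attribute \code{errors} collects per-region failures.
#' @export
at_compare_table <- function(seqs, regions) {
  rows <- list(); errs <- character(0)
  for (iv in regions) {
    if (!iv$seq_id %in% names(seqs)) {
      errs <- c(errs, sprintf("%s:%d-%d: unknown sequence id", iv$seq_id, iv$start, iv$end))
      next
    }
    parent <- seqs[[iv$seq_id]]
    if (iv$end > nchar(parent)) {
      errs <- c(errs, sprintf("%s:%d-%d: region out of bounds (length %d)",
                              iv$seq_id, iv$start, iv$end, nchar(parent)))
      next
    }
    st <- at_enrichment(substr(parent, iv$start, iv$end), parent)
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = iv$seq_id, start = iv$start, end = iv$end,
      region_at = st$region_at, background_at = st$background_at,
      enrichment = st$enrichment, is_at_rich = st$is_at_rich,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               region_at = numeric(), background_at = numeric(),
               enrichment = numeric(), is_at_rich = logical(),
               stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- rbind(tab, data.frame(
      seq_id = "mean", start = NA_integer_, end = NA_integer_,
      region_at = mean(tab$region_at), background_at = mean(tab$background_at),
      enrichment = mean(tab$enrichment), is_at_rich = NA, stringsAsFactors = FALSE))
  }
  attr(tab, "errors") <- errs
  tab
}
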
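#' Genomic interval in GenBank convention
#'
#' Coordinates are 1-based and inclusive on both ends, matching how element
#' locations are printed in GenBank records and in comparative tables of
#' baculovirus genomes. Internal arithmetic that needs 0-based half-open
#' coordinates (BED emission) converts only at that boundary.
#'
#' @param seq_id Sequence identifier.
#' @param start,end 1-based inclusive bounds, \code{1 <= start <= end}.
#' @param strand \code{"+"} or \code{"-"}.
#' @return An object of class \code{genomic_interval}.
#' @examples
#' iv <- genomic_interval("NC_001623", 132228, 132383)
#' interval_length(iv)  # 156
#' @export
genomic_interval <- function(seq_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(is.character(seq_id), length(seq_id) == 1L, nzchar(seq_id))
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]",
         call. = FALSE)
  }
  strand <- match.arg(strand, c("+", "-"))
  structure(list(seq_id = seq_id, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d(%s) [%d bp]\n",
              x$seq_id, x$start, x$end, x$strand, interval_length(x)))
  invisible(x)
}

#' Length of an interval in bp
#'
#' @param iv A \code{genomic_interval}.
#' @return Integer length \code{end - start + 1}.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  iv$end - iv$start + 1L
}

#' Expand an interval by flanking sequence
#'
#' Upstream/downstream are taken in transcriptional orientation: on the plus
#' strand \code{up} extends the start leftwards; on the minus strand the roles
#' are mirrored. Used for the CNE construct arithmetic (156-bp element with
#' 5/10-bp flanks -> 171 bp; 19/25-bp flanks -> 200 bp).
#'
#' @param iv A \code{genomic_interval}.
#' @param up,down Non-negative flank widths in bp.
#' @param seq_length Optional length of the parent sequence; expansion past it
#'   errors when supplied.
#' @return The expanded \code{genomic_interval}.
#' @export
expand_flanks <- function(iv, up, down, seq_length = NULL) {
  stopifnot(inherits(iv, "genomic_interval"))
  up <- as.integer(up); down <- as.integer(down)
  stopifnot(up >= 0L, down >= 0L)
  if (iv$strand == "+") {
    new_start <- iv$start - up; new_end <- iv$end + down
  } else {
    new_start <- iv$start - down; new_end <- iv$end + up
  }
  if (new_start < 1L) stop("flank expansion extends past position 1", call. = FALSE)
  if (!is.null(seq_length) && new_end > seq_length) {
    stop("flank expansion extends past sequence end (", seq_length, ")", call. = FALSE)
  }
  genomic_interval(iv$seq_id, new_start, new_end, iv$strand)
}

#' Does one interval contain another?
#'
#' @param outer,inner \code{genomic_interval}s on the same sequence.
#' @return \code{TRUE} iff \code{outer} spans \code{inner} (strand ignored).
#' @export
interval_contains <- function(outer, inner) {
  stopifnot(inherits(outer, "genomic_interval"), inherits(inner, "genomic_interval"))
  if (outer$seq_id != inner$seq_id) {
    stop("intervals are on different sequences: ", outer$seq_id, " vs ",
         inner$seq_id, call. = FALSE)
  }
  outer$start <= inner$start && inner$end <= outer$end
}

# 1-based inclusive -> BED 0-based half-open, and back.
interval_to_bed_row <- function(iv, name = ".", score = 0) {
  data.frame(chrom = iv$seq_id, chromStart = iv$start - 1L, chromEnd = iv$end,
             name = name, score = score, strand = iv$strand,
             stringsAsFactors = FALSE)
}

bed_row_to_interval <- function(row) {
  genomic_interval(as.character(row$chrom), as.integer(row$chromStart) + 1L,
                   as.integer(row$chromEnd), as.character(row$strand))
}
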
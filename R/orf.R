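# Six-frame ORF finding and interval-overlap classification, used to ask
# whether a conserved element is or is not protein-coding territory.

.STOPS <- c("TAA", "TAG", "TGA")

# ORFs on the forward strand of `s`: per frame, the 5'-most ATG after the
# previous in-frame stop, through the next in-frame stop (inclusive).
.orfs_one_strand <- function(s, min_len) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    if (frame + 1L > L - 2L) next
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% .STOPS
    is_atg <- codons == "ATG"
    open_from <- 1L  # codon index from which an ATG may open an ORF
    for (ci in seq_along(codons)) {
      if (!is_stop[ci]) next
      atg_idx <- which(is_atg[open_from:ci])
      if (length(atg_idx)) {
        a <- open_from + atg_idx[1L] - 1L
        orf_start <- starts[a]
        orf_end <- starts[ci] + 2L
        len <- orf_end - orf_start + 1L
        if (len >= min_len) {
          out[[length(out) + 1L]] <- c(start = orf_start, end = orf_end,
                                       frame = frame, length = len)
        }
      }
      open_from <- ci + 1L
    }
  }
  out
}

#' Find ORFs in all six reading frames
#'
#' An ORF runs from an ATG to the next in-frame stop codon; its length in bp
#' includes the stop codon (so a 279-bp ORF is 92 sense codons plus the
#' stop). Per frame and stop, the 5'-most ATG is reported. ORFs truncated by
#' the sequence end (no in-frame stop) are omitted unless
#' \code{include_truncated} is set, in which case they are reported running
#' to the last full codon with \code{truncated = TRUE}.
#'
#' @param seq Sequence string.
#' @param min_len Minimum ORF length in bp (default 150, the conventional
#'   gene-length cutoff used when annotating short baculovirus ORFs).
#' @param include_truncated Report stop-less ORFs at the sequence end.
#' @return Data frame \code{start,end,strand,frame,length,truncated} in
#'   forward-strand 1-based inclusive coordinates; \code{frame} (0/1/2) is
#'   the frame on the ORF's own strand.
#' @export
find_orfs <- function(seq, min_len = 150L, include_truncated = FALSE) {
  s <- if (is.character(seq)) toupper(seq) else toupper(as.character(seq))
  L <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), length = integer(), truncated = logical(),
                      stringsAsFactors = FALSE)
  if (L < 6L) return(empty)

  collect <- function(str, strand) {
    res <- .orfs_one_strand(str, min_len)
    if (include_truncated) {
      res <- c(res, .truncated_orfs(str, min_len))
    }
    if (!length(res)) return(NULL)
    df <- as.data.frame(do.call(rbind, res))
    df$truncated <- if (is.null(df$truncated)) 0 else df$truncated
    if (strand == "-") {
      new_start <- L - df$end + 1L
      new_end <- L - df$start + 1L
      df$start <- new_start; df$end <- new_end
    }
    df$strand <- strand
    df
  }
  fwd <- collect(s, "+")
  rev <- collect(reverse_complement(s), "-")
  res <- rbind(fwd, rev)
  if (is.null(res) || !nrow(res)) return(empty)
  res$truncated <- as.logical(res$truncated)
  res <- res[order(res$start, res$end, res$strand), c("start", "end", "strand",
                                                      "frame", "length", "truncated")]
  rownames(res) <- NULL
  res
}

# stop-less ORFs running off the sequence end (flag-gated)
.truncated_orfs <- function(s, min_len) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    if (frame + 1L > L - 2L) next
    starts <- seq.int(frame + 1L, L - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% .STOPS
    is_atg <- codons == "ATG"
    last_stop <- if (any(is_stop)) max(which(is_stop)) else 0L
    tail_atg <- which(is_atg & seq_along(codons) > last_stop)
    if (length(tail_atg)) {
      a <- tail_atg[1L]
      orf_start <- starts[a]
      orf_end <- starts[length(starts)] + 2L
      len <- orf_end - orf_start + 1L
      if (len >= min_len) {
        out[[length(out) + 1L]] <- c(start = orf_start, end = orf_end,
                                     frame = frame, length = len, truncated = 1)
      }
    }
  }
  out
}

#' Classify the overlap between an ORF and a region
#'
#' Strandless interval-relation classification on a shared sequence.
#'
#' @param orf A \code{genomic_interval} or a one-row slice of
#'   \code{\link{find_orfs}} output (with a \code{seq_id} column or taken to
#'   share the region's sequence).
#' @param region A \code{genomic_interval}.
#' @return One of \code{"none"}, \code{"partial"},
#'   \code{"region_contains_orf"}, \code{"orf_contains_region"}. Identical
#'   intervals classify as \code{"orf_contains_region"} (ORF containment is
#'   checked first).
#' @export
overlap_classify <- function(orf, region) {
  stopifnot(inherits(region, "genomic_interval"))
  if (inherits(orf, "genomic_interval")) {
    if (orf$seq_id != region$seq_id) {
      stop("ORF and region are on different sequences: ", orf$seq_id, " vs ",
           region$seq_id, call. = FALSE)
    }
    os <- orf$start; oe <- orf$end
  } else {
    if (!is.null(orf$seq_id) && length(orf$seq_id) == 1L &&
        orf$seq_id != region$seq_id) {
      stop("ORF and region are on different sequences", call. = FALSE)
    }
    os <- as.integer(orf$start); oe <- as.integer(orf$end)
  }
  if (oe < region$start || os > region$end) return("none")
  if (os <= region$start && region$end <= oe) return("orf_contains_region")
  if (region$start <= os && oe <= region$end) return("region_contains_orf")
  "partial"
}
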
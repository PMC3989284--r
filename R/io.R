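#' Read a FASTA file of nucleotide sequences
#'
#' Thin wrapper around \code{Biostrings::readDNAStringSet} that enforces the
#' package's ingest rules: identifiers are the token before the first
#' whitespace, duplicates are rejected, residues are uppercased and restricted
#' to A/C/G/T/N, and empty files or empty records error.
#'
#' @param path Path to a plain (ungapped) FASTA file.
#' @return Named character vector of sequences; names are record ids, the
#'   \code{"descriptions"} attribute keeps the full header lines.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) stop("empty record '", ids[i], "'", call. = FALSE)
    seqs[i] <- normalize_residues(seqs[i])
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (or list with \code{residues} fields).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, function(s) s$id, character(1))
    seqs <- stats::setNames(vapply(seqs, function(s) s$residues, character(1)), nm)
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)  # BString keeps gap characters intact
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an alignment object
#'
#' @param seqs Named character vector of equal-length gapped sequences over
#'   \{A,C,G,T,N,-\}.
#' @return Object of class \code{cne_alignment}: list with \code{ids},
#'   \code{seqs}, \code{n_cols}.
#' @export
new_alignment <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: record lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(seqs)
  for (i in seq_along(seqs)) {
    normalize_residues(seqs[i], allow = c("A", "C", "G", "T", "N", "-"))
  }
  structure(list(ids = names(seqs), seqs = seqs, n_cols = unname(lens[1])),
            class = "cne_alignment")
}

#' @export
print.cne_alignment <- function(x, ...) {
  cat(sprintf("<cne_alignment> %d records x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' Read a pre-aligned (gapped) FASTA
#'
#' Accepts an externally produced multiple alignment (e.g. ClustalW output
#' exported as FASTA) as an alternative entry point to \code{align_family}.
#'
#' @param path Path to gapped FASTA ('-' gaps).
#' @return A \code{cne_alignment}.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- stats::setNames(toupper(as.character(set)), ids)
  new_alignment(seqs)
}

#' Remove gaps from an alignment record
#' @param aln A \code{cne_alignment}.
#' @param id Record identifier.
#' @return Ungapped sequence string.
#' @export
ungap <- function(aln, id) {
  stopifnot(inherits(aln, "cne_alignment"), id %in% aln$ids)
  gsub("-", "", aln$seqs[[id]], fixed = TRUE)
}

#' Write scan hits (or any interval table) as BED6
#'
#' Converts from the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param hits Data frame with columns \code{seq_id,start,end,strand} and
#'   optionally \code{name} and \code{score}.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  stopifnot(all(c("seq_id", "start", "end", "strand") %in% names(hits)))
  bed <- data.frame(
    chrom = hits$seq_id,
    chromStart = as.integer(hits$start) - 1L,
    chromEnd = as.integer(hits$end),
    name = if ("name" %in% names(hits)) hits$name else ".",
    score = if ("score" %in% names(hits)) hits$score else 0,
    strand = hits$strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file back into 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return Data frame with \code{seq_id,start,end,name,score,strand}
#'   (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "chromStart", "chromEnd",
                                         "name", "score", "strand"))
  data.frame(seq_id = bed$chrom, start = bed$chromStart + 1L, end = bed$chromEnd,
             name = bed$name, score = bed$score, strand = bed$strand,
             stringsAsFactors = FALSE)
}

#' Read an interval fixture TSV (seq_id, start, end, strand)
#'
#' Coordinates are 1-based inclusive, as printed in GenBank-style tables.
#'
#' @param path TSV path with a header row.
#' @return List of \code{genomic_interval}s.
#' @export
read_intervals_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("seq_id", "start", "end", "strand") %in% names(tab)))
  lapply(seq_len(nrow(tab)), function(i) {
    genomic_interval(tab$seq_id[i], tab$start[i], tab$end[i], tab$strand[i])
  })
}
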
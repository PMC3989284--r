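#!/usr/bin/env Rscript

# Stage 3: AT enrichment of planted elements over their genomes, and the
# ORF content overlapping them.
#
# For each simulated genome from stage 1: compares the planted CNE's AT
# content against the genome background (the element should satisfy the
# two-part AT-rich criterion), finds ORFs longer than 150 bp around the
# planted locus, and classifies their overlap with the element. Writes
# results/atcompare.tsv and results/orfs.tsv.

suppressPackageStartupMessages(library(cnescan))

data_dir <- file.path("results", "data")
if (!file.exists(file.path(data_dir, "genome_plus.fasta"))) {
  stop("run analysis/01_simulate.R first")
}

at_rows <- list(); orf_rows <- list()
for (tag in c("plus", "minus")) {
  genome <- read_fasta(file.path(data_dir, sprintf("genome_%s.fasta", tag)))
  gid <- names(genome)[1]
  truth <- read_bed(file.path(data_dir, sprintf("genome_%s_truth.bed", tag)))
  plant <- truth[truth$name == "plant1", ]

  regions <- list(genomic_interval(gid, plant$start, plant$end, plant$strand))
  tab <- at_compare_table(genome, regions)
  tab$genome <- gid
  at_rows[[tag]] <- tab
  cat(sprintf("%s: element AT %.1f%% vs genome %.1f%% (enrichment %+.1f pp, AT-rich: %s)\n",
              gid, tab$region_at[1], tab$background_at[1], tab$enrichment[1],
              tab$is_at_rich[1]))

  # ORFs in a 2-kb window around the planted element
  win_start <- max(1L, plant$start - 1000L)
  win_end <- min(nchar(genome[[1]]), plant$end + 1000L)
  window <- substr(genome[[1]], win_start, win_end)
  orfs <- find_orfs(window, min_len = 150)
  if (nrow(orfs)) {
    orfs$start <- orfs$start + win_start - 1L
    orfs$end <- orfs$end + win_start - 1L
    region <- genomic_interval(gid, plant$start, plant$end)
    orfs$overlap <- vapply(seq_len(nrow(orfs)), function(i) {
      overlap_classify(genomic_interval(gid, orfs$start[i], orfs$end[i]), region)
    }, character(1))
    orfs$genome <- gid
    orf_rows[[tag]] <- orfs
  }
  cat(sprintf("%s: %d ORF(s) >= 150 bp within +/-1 kb of the planted element\n",
              gid, nrow(orfs)))
}

dir.create("results", showWarnings = FALSE)
write.table(do.call(rbind, at_rows), file.path("results", "atcompare.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
orf_tab <- if (length(orf_rows)) do.call(rbind, orf_rows) else
  data.frame(start = integer(), end = integer(), strand = character(),
             frame = integer(), length = integer(), truncated = logical(),
             overlap = character(), genome = character())
write.table(orf_tab, file.path("results", "orfs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("tables written to results/atcompare.tsv and results/orfs.tsv\n")
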
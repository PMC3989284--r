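#!/usr/bin/env Rscript

# Stage 1: generate the study datasets with known truth.
#
# Produces, under results/data/:
#   family.fasta          38-member synthetic CNE family (default divergence)
#   family_truth.fasta    the truth alignment (template columns, '-' gaps)
#   family_truth.tsv      per-sequence element coordinates
#   genome_plus.fasta / genome_minus.fasta
#                         40-kb host genomes with one planted CNE each
#                         (forward / reverse strand) plus all three decoys
#   genome_*_truth.bed    truth intervals for the plants and decoys
#   spec.txt              the generator settings used (provenance echo)

suppressPackageStartupMessages(library(cnescan))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed")) && i < length(args)) {
  as.integer(args[i + 1])
} else 1L

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- family_spec(seed = seed)
fam <- simulate_family(spec)
write_fasta(fam$sequences, file.path(out, "family.fasta"))
write_fasta(fam$truth_alignment$seqs, file.path(out, "family_truth.fasta"))
write.table(fam$truth_elements, file.path(out, "family_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("family: %d sequences, lengths %d-%d bp\n",
            length(fam$sequences), min(nchar(fam$sequences)),
            max(nchar(fam$sequences))))

for (cfg in list(list(tag = "plus", strand = "+", member = 1L),
                 list(tag = "minus", strand = "-", member = 2L))) {
  gs <- genome_spec(length = 40000L, gc = 0.43,
                    plants = list(list(seq = fam$sequences[[cfg$member]],
                                       pos = 15000L, strand = cfg$strand)),
                    decoys = c("lone_DS", "shuffled_CNE", "tandem_TAT"),
                    seed = seed + 10L + cfg$member)
  sim <- simulate_genome(gs)
  write_fasta(stats::setNames(sim$genome, paste0("genome_", cfg$tag)),
              file.path(out, sprintf("genome_%s.fasta", cfg$tag)))
  truth <- sim$truth
  truth$seq_id <- paste0("genome_", cfg$tag)
  write_bed(truth, file.path(out, sprintf("genome_%s_truth.bed", cfg$tag)))
  cat(sprintf("genome_%s: %d bp, AT %.1f%%, planted CNE at %d (%s), %d decoys\n",
              cfg$tag, nchar(sim$genome), at_content(sim$genome),
              truth$start[truth$kind == "plant"], cfg$strand,
              sum(startsWith(truth$kind, "decoy"))))
}

writeLines(c(
  sprintf("seed\t%d", seed),
  sprintf("n_sequences\t%d", spec$n_sequences),
  sprintf("divergence\t%g", spec$divergence),
  sprintf("at_bias\t%g", spec$at_bias),
  sprintf("indel_max\t%d", spec$indel_max),
  sprintf("indel_prob\t%g", spec$indel_prob),
  "genome_length\t40000",
  "genome_gc\t0.43"
), file.path(out, "spec.txt"))
cat("settings echoed to", file.path(out, "spec.txt"), "\n")
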
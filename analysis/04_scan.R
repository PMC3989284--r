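#!/usr/bin/env Rscript

# Stage 4: build the architecture model from the profiled family and scan
# the simulated genomes on both strands.
#
# Writes results/model.tsv (the serialized architecture), and per genome a
# BED6 of hits plus a detailed TSV (per-element positions, score, AT).
# Reports sensitivity against the planted truth and checks that no decoy
# is called.

suppressPackageStartupMessages(library(cnescan))

data_dir <- file.path("results", "data")
fam_path <- file.path(data_dir, "family.fasta")
if (!file.exists(fam_path)) stop("run analysis/01_simulate.R first")

rep <- profile_family(read_fasta(fam_path))
model <- build_model(rep$profile, rep$clusters, rep$dyads, rep$alignment)
print(model)
write_model(model, file.path("results", "model.tsv"))

for (tag in c("plus", "minus")) {
  genome <- read_fasta(file.path(data_dir, sprintf("genome_%s.fasta", tag)))
  gid <- names(genome)[1]
  truth <- read_bed(file.path(data_dir, sprintf("genome_%s_truth.bed", tag)))
  plant <- truth[truth$name == "plant1", ]
  decoys <- truth[grepl("decoy", truth$name), ]

  hits <- scan_genome(genome[[1]], model, seq_id = gid)
  write_bed(hits, file.path("results", sprintf("hits_%s.bed", tag)))
  write.table(hits, file.path("results", sprintf("hits_%s.tsv", tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  hit_ok <- any(abs(hits$start - plant$start) <= 3 & hits$strand == plant$strand)
  decoy_hit <- any(vapply(seq_len(nrow(decoys)), function(j) {
    any(hits$start <= decoys$end[j] & decoys$start[j] <= hits$end)
  }, logical(1)))
  cat(sprintf("%s: %d hit(s); planted CNE (%s strand) %s; decoys %s\n",
              gid, nrow(hits), plant$strand,
              if (hit_ok) "recovered" else "MISSED",
              if (decoy_hit) "CALLED (unexpected)" else "silent"))
}
cat("hits written to results/hits_{plus,minus}.{bed,tsv}; model to results/model.tsv\n")
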
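# One-call drivers used by the analysis scripts: family profiling (align ->
# profile -> consensus -> clusters -> dyads -> spacings -> AT stats) and the
# report writers. These are thin compositions of the exported stage
# functions; every number they report is computed by those stages.

#' Profile a CNE family end to end
#'
#' Aligns the family (unless an alignment is supplied), computes the column
#' profile, consensus string, conserved clusters, the three dyad elements
#' (located on the modal-base consensus, so coordinates are alignment
#' columns), inter-cluster spacings and identity summary.
#'
#' @param seqs Named character vector of ungapped sequences, or a
#'   \code{cne_alignment} to skip the alignment step.
#' @param max_intervening,min_conserved Cluster segmentation parameters.
#' @param ... Passed to \code{\link{align_family}}.
#' @return List of class \code{cne_family_report}: \code{alignment},
#'   \code{profile}, \code{consensus}, \code{clusters}, \code{dyads},
#'   \code{spacings}, \code{identity}, and a \code{summary} list (conserved
#'   base count, cluster count, dyad spans, AT fraction of conserved bases,
#'   mean family AT content).
#' @export
profile_family <- function(seqs, max_intervening = 2L, min_conserved = 3L, ...) {
  aln <- if (inherits(seqs, "cne_alignment")) seqs else align_family(seqs, ...)
  prof <- column_profiles(aln)
  cons <- consensus_string(prof)

  modal <- prof$modal_base
  modal[is.na(modal)] <- "N"
  modal_str <- paste(modal, collapse = "")
  dyads <- classify_cne_dyads(modal_str)

  clusters <- segment_clusters(prof, max_intervening = max_intervening,
                               min_conserved = min_conserved, dyads = dyads)
  spacings <- if (nrow(clusters) >= 2L) cluster_spacings(clusters, aln) else NULL
  ident <- pairwise_identity(aln)

  ungapped <- vapply(aln$ids, function(id) ungap(aln, id), character(1))
  summary <- list(
    n_records = length(aln$ids),
    n_cols = aln$n_cols,
    n_conserved = sum(prof$conserved),
    n_clusters = nrow(clusters),
    dyads_found = names(Filter(Negate(is.null), dyads)),
    at_of_conserved = at_fraction_of_conserved(prof),
    mean_at = mean(vapply(ungapped, at_content, numeric(1))),
    identity_min = ident$min, identity_max = ident$max
  )
  structure(list(alignment = aln, profile = prof, consensus = cons,
                 clusters = clusters, dyads = dyads, spacings = spacings,
                 identity = ident, summary = summary),
            class = "cne_family_report")
}

#' @export
print.cne_family_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cne_family_report> %d records, %d columns\n", s$n_records, s$n_cols))
  cat(sprintf("  absolutely conserved columns: %d in %d clusters\n",
              s$n_conserved, s$n_clusters))
  cat(sprintf("  dyads found: %s\n", paste(s$dyads_found, collapse = ", ")))
  cat(sprintf("  AT among conserved: %.1f%%; mean family AT: %.1f%%\n",
              s$at_of_conserved, s$mean_at))
  cat(sprintf("  pairwise identity: %.1f-%.1f%%\n", s$identity_min, s$identity_max))
  invisible(x)
}

#' Write the report bundle of a profiled family
#'
#' Emits the gapped alignment and consensus as FASTA, the column profile,
#' cluster, dyad, spacing and identity tables as TSV, and a plain-text
#' summary, into \code{dir}.
#'
#' @param report A \code{cne_family_report}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_family_report <- function(report, dir) {
  stopifnot(inherits(report, "cne_family_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(report$alignment$seqs, file.path(dir, "alignment.fasta"))
  write_fasta(c(consensus = report$consensus), file.path(dir, "consensus.fasta"))
  write_profile_tsv(report$profile, file.path(dir, "profile.tsv"))
  utils::write.table(report$clusters, file.path(dir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dyads_to_table(report$dyads), file.path(dir, "dyads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$spacings)) {
    utils::write.table(report$spacings$summary, file.path(dir, "spacings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(round(report$identity$values, 2),
                     file.path(dir, "identity.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  s <- report$summary
  writeLines(c(
    sprintf("records\t%d", s$n_records),
    sprintf("columns\t%d", s$n_cols),
    sprintf("conserved_bases\t%d", s$n_conserved),
    sprintf("clusters\t%d", s$n_clusters),
    sprintf("dyads\t%s", paste(s$dyads_found, collapse = ",")),
    sprintf("at_of_conserved\t%.2f", s$at_of_conserved),
    sprintf("mean_at\t%.2f", s$mean_at),
    sprintf("identity_min\t%.2f", s$identity_min),
    sprintf("identity_max\t%.2f", s$identity_max)
  ), file.path(dir, "summary.txt"))
  invisible(dir)
}
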
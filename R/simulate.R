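# Synthetic CNE families and host genomes with known truth, so alignment,
# profiling, dyad detection and scanning can all be benchmarked without any
# downloaded genome. The default template reproduces the published element
# grammar: terminal dyads with WTTWTG cores and 5-nt spacers, a central dyad
# with GWAGACTWT/AHAGTCTWC cores and a 9-nt spacer, TAT clusters between
# them, 154-157 bp overall, elevated AT content.

#' The built-in CNE template and its element annotations
#'
#' A deterministic 157-bp template laid out as DSl | v1 | c2(TAT) | v2 |
#' c3 | v3 | DSc | v4 | c6(TAT) | v5 | DSr, where the v regions (and the
#' asymmetric dyad spacers) are the variable columns a simulated family
#' mutates, and everything else is absolutely conserved by construction.
#'
#' @return List with \code{template} (concrete 157-bp instance),
#'   \code{degenerate} (same string with \code{N} at variable columns),
#'   \code{elements} (data frame: \code{element_id,kind,start,end}),
#'   \code{variable_cols} (integer vector), and \code{spacer_regions}
#'   (inter-element regions where indels are permitted).
#' @export
default_cne_template <- function() {
  parts <- c(
    DSl_arm1   = "TTTTTG",
    DSl_spacer = "ATCAA",
    DSl_arm2   = "CAAAAA",
    v1         = "AACCATTAAACCAATACA",
    c2         = "TAT",
    v2         = "CAACCATAACCAAAC",
    c3         = "CATTAT",
    v3         = "ACCAAATACCAAATCC",
    DSc_left   = "GAAGACTAT",
    DSc_spacer = "CCACAATCA",
    DSc_right  = "ATAGTCTTC",
    v4         = "CACCAATTCACAAACCA",
    c6         = "TAT",
    v5         = "CCAAACATACCAATACCA",
    DSr_arm1   = "TTTTTG",
    DSr_spacer = "ATCAA",
    DSr_arm2   = "CAAAAA"
  )
  template <- paste(parts, collapse = "")
  ends <- cumsum(nchar(parts))
  starts <- ends - nchar(parts) + 1L
  names(starts) <- names(ends) <- names(parts)

  span <- function(from, to) c(starts[[from]], ends[[to]])
  el <- rbind(
    data.frame(element_id = "DSl", kind = "dyad",
               start = span("DSl_arm1", "DSl_arm2")[1], end = span("DSl_arm1", "DSl_arm2")[2]),
    data.frame(element_id = "c2", kind = "tat_cluster",
               start = starts[["c2"]], end = ends[["c2"]]),
    data.frame(element_id = "c3", kind = "conserved_cluster",
               start = starts[["c3"]], end = ends[["c3"]]),
    data.frame(element_id = "DSc", kind = "dyad",
               start = span("DSc_left", "DSc_right")[1], end = span("DSc_left", "DSc_right")[2]),
    data.frame(element_id = "c6", kind = "tat_cluster",
               start = starts[["c6"]], end = ends[["c6"]]),
    data.frame(element_id = "DSr", kind = "dyad",
               start = span("DSr_arm1", "DSr_arm2")[1], end = span("DSr_arm1", "DSr_arm2")[2])
  )
  rownames(el) <- NULL

  spacer_regions <- data.frame(
    region = c("v1", "v2", "v3", "v4", "v5"),
    start = starts[c("v1", "v2", "v3", "v4", "v5")],
    end = ends[c("v1", "v2", "v3", "v4", "v5")],
    row.names = NULL, stringsAsFactors = FALSE
  )

  # variable columns: the five inter-element regions plus the asymmetric
  # spacers inside the dyads (two positions in each terminal spacer, the
  # whole central spacer)
  variable_cols <- sort(c(
    unlist(lapply(seq_len(nrow(spacer_regions)), function(i) {
      spacer_regions$start[i]:spacer_regions$end[i]
    })),
    starts[["DSl_spacer"]] + c(1L, 3L),
    starts[["DSc_spacer"]]:ends[["DSc_spacer"]],
    starts[["DSr_spacer"]] + c(1L, 3L)
  ))
  names(variable_cols) <- NULL

  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  degen <- chars
  degen[variable_cols] <- "N"

  list(template = template, degenerate = paste(degen, collapse = ""),
       elements = el, variable_cols = variable_cols,
       spacer_regions = spacer_regions)
}

#' Specification for a simulated CNE family
#'
#' @param n_sequences Family size (default 38, the size of the published
#'   genus-wide repertoire).
#' @param divergence Per-column substitution probability applied to variable
#'   columns (conserved columns never mutate). The default 0.2 yields
#'   pairwise identities roughly from the mid-60s to the high 80s percent,
#'   echoing the 66\% floor of the published family; 0 gives identical
#'   copies.
#' @param at_bias Probability that a substituted base is A or T (default
#'   0.63, keeping synthetic CNEs AT-rich like the real ones).
#' @param indel_max Maximum deletion (bp) per inter-element spacer region per
#'   sequence, 0-3; spacing jitter is realised as deletions confined to the
#'   spacer regions so the truth alignment stays well defined.
#' @param indel_prob Probability that a given spacer region of a given
#'   sequence carries any deletion.
#' @param seed Integer seed; the single source of randomness.
#' @param template Template list from \code{\link{default_cne_template}}.
#' @return Object of class \code{family_spec}.
#' @export
family_spec <- function(n_sequences = 38L, divergence = 0.2, at_bias = 0.63,
                        indel_max = 3L, indel_prob = 0.3, seed = 1L,
                        template = default_cne_template()) {
  stopifnot(n_sequences >= 2L, divergence >= 0, divergence <= 1,
            at_bias >= 0, at_bias <= 1, indel_max >= 0L, indel_max <= 3L,
            indel_prob >= 0, indel_prob <= 1)
  sub_prob <- rep(0, nchar(template$template))
  sub_prob[template$variable_cols] <- divergence
  structure(list(n_sequences = as.integer(n_sequences), divergence = divergence,
                 sub_prob = sub_prob, at_bias = at_bias,
                 indel_max = as.integer(indel_max), indel_prob = indel_prob,
                 seed = as.integer(seed), template = template),
            class = "family_spec")
}

.draw_substitution <- function(ref, at_bias) {
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  w <- ifelse(alts %in% c("A", "T"), at_bias / 2, (1 - at_bias) / 2)
  sample(alts, 1L, prob = w / sum(w))
}

#' Simulate a CNE family with known truth
#'
#' Sequences are drawn column-wise from the template: conserved columns are
#' copied verbatim, variable columns substitute with the spec's per-column
#' probability (AT-biased replacement), and 0-\code{indel_max} bp deletions
#' are applied to the inter-element spacer regions only. Identical spec and
#' seed give byte-identical output.
#'
#' @param spec A \code{\link{family_spec}}.
#' @return List: \code{sequences} (named ungapped strings),
#'   \code{truth_alignment} (a \code{cne_alignment} over template columns),
#'   \code{truth_elements} (per-sequence element coordinates, ungapped), and
#'   \code{spec}.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  tpl <- spec$template
  chars <- strsplit(tpl$template, "", fixed = TRUE)[[1]]
  L <- length(chars)
  ids <- sprintf("seq%02d", seq_len(spec$n_sequences))

  gapped <- character(spec$n_sequences)
  truth_rows <- list()
  for (i in seq_len(spec$n_sequences)) {
    s <- chars
    mut <- which(stats::runif(L) < spec$sub_prob)
    for (m in mut) s[m] <- .draw_substitution(chars[m], spec$at_bias)
    deleted <- logical(L)
    if (spec$indel_max > 0L) {
      for (r in seq_len(nrow(tpl$spacer_regions))) {
        if (stats::runif(1) >= spec$indel_prob) next
        d <- sample.int(spec$indel_max, 1L)
        re <- tpl$spacer_regions$end[r]
        deleted[(re - d + 1L):re] <- TRUE  # trailing columns of the region
      }
    }
    s[deleted] <- "-"
    gapped[i] <- paste(s, collapse = "")

    # deletions never touch element columns, so ungapped element coordinates
    # follow directly from the cumulative non-deleted count
    upos <- cumsum(!deleted)
    for (e in seq_len(nrow(tpl$elements))) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        seq = ids[i], element_id = tpl$elements$element_id[e],
        kind = tpl$elements$kind[e],
        start = upos[tpl$elements$start[e]],
        end = upos[tpl$elements$end[e]],
        stringsAsFactors = FALSE)
    }
  }
  names(gapped) <- ids
  sequences <- stats::setNames(gsub("-", "", gapped, fixed = TRUE), ids)
  truth_elements <- do.call(rbind, truth_rows)
  rownames(truth_elements) <- NULL
  list(sequences = sequences, truth_alignment = new_alignment(gapped),
       truth_elements = truth_elements, spec = spec)
}

#' Specification for a simulated host genome
#'
#' @param length Genome length in bp.
#' @param gc Background GC fraction (i.i.d. background; published
#'   alphabaculovirus genomes have AT contents between roughly 42.5 and
#'   66.6\%, i.e. GC 0.33-0.58).
#' @param plants List of planted elements, each a list with \code{seq},
#'   optional \code{pos} (1-based start; \code{NA} = random) and
#'   \code{strand} (\code{"+"}/\code{"-"}; minus-strand plants are spliced in
#'   as their reverse complement).
#' @param decoys Character vector drawn from \code{"lone_DS"},
#'   \code{"shuffled_CNE"}, \code{"tandem_TAT"}; a shuffled-CNE decoy
#'   permutes the template's residues, preserving composition.
#' @param circular Mark the genome as covalently closed circular.
#' @param seed Integer seed.
#' @return Object of class \code{genome_spec}.
#' @export
genome_spec <- function(length = 50000L, gc = 0.43, plants = list(),
                        decoys = character(0), circular = FALSE, seed = 1L) {
  stopifnot(length >= 1000L, gc > 0, gc < 1)
  known <- c("lone_DS", "shuffled_CNE", "tandem_TAT")
  if (!all(decoys %in% known)) {
    stop("unknown decoy kind: ", paste(setdiff(decoys, known), collapse = ", "),
         call. = FALSE)
  }
  structure(list(length = as.integer(length), gc = gc, plants = plants,
                 decoys = decoys, circular = circular, seed = as.integer(seed)),
            class = "genome_spec")
}

#' Simulate a host genome with planted elements and decoys
#'
#' Draws an i.i.d. background at the requested GC, splices planted sequences
#' (reverse-complemented for minus-strand plants) and decoys at non-overlapping
#' positions, and returns the truth table. Overlapping placements error.
#'
#' @param spec A \code{\link{genome_spec}}.
#' @return List: \code{genome} (string), \code{truth} (data frame
#'   \code{name,start,end,strand,kind}), \code{circular}.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  p <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2, T = (1 - spec$gc) / 2)
  bg <- sample(names(p), spec$length, replace = TRUE, prob = p)

  tpl <- default_cne_template()
  decoy_seq <- function(kind) {
    switch(kind,
      lone_DS = paste0("TTTTTG", "ACGTA", "CAAAAA"),
      shuffled_CNE = paste(sample(strsplit(tpl$template, "", fixed = TRUE)[[1]]),
                           collapse = ""),
      tandem_TAT = strrep("TAT", 6L))
  }

  items <- list()
  for (i in seq_along(spec$plants)) {
    pl <- spec$plants[[i]]
    items[[length(items) + 1L]] <- list(
      name = if (!is.null(pl$name)) pl$name else sprintf("plant%d", i),
      seq = toupper(pl$seq),
      pos = if (is.null(pl$pos)) NA_integer_ else as.integer(pl$pos),
      strand = if (is.null(pl$strand)) "+" else pl$strand,
      kind = "plant")
  }
  for (i in seq_along(spec$decoys)) {
    items[[length(items) + 1L]] <- list(
      name = sprintf("decoy_%s", spec$decoys[i]),
      seq = decoy_seq(spec$decoys[i]), pos = NA_integer_, strand = "+",
      kind = paste0("decoy:", spec$decoys[i]))
  }

  placed <- data.frame(start = integer(), end = integer())
  truth_rows <- list()
  for (it in items) {
    w <- nchar(it$seq)
    if (w > spec$length) stop("planted element longer than genome", call. = FALSE)
    if (is.na(it$pos)) {
      ok <- FALSE
      for (try in 1:1000) {
        pos <- sample.int(spec$length - w + 1L, 1L)
        if (!any(pos <= placed$end + 50L & placed$start - 50L <= pos + w - 1L)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place element without overlap", call. = FALSE)
    } else {
      pos <- it$pos
      if (pos < 1L || pos + w - 1L > spec$length) {
        stop("planted element does not fit at requested position", call. = FALSE)
      }
      if (any(pos <= placed$end & placed$start <= pos + w - 1L)) {
        stop("planted elements overlap", call. = FALSE)
      }
    }
    placed <- rbind(placed, data.frame(start = pos, end = pos + w - 1L))
    ins <- if (it$strand == "-") reverse_complement(it$seq) else it$seq
    bg[pos:(pos + w - 1L)] <- strsplit(ins, "", fixed = TRUE)[[1]]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      name = it$name, start = pos, end = pos + w - 1L, strand = it$strand,
      kind = it$kind, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(name = character(), start = integer(), end = integer(),
               strand = character(), kind = character(), stringsAsFactors = FALSE)
  list(genome = paste(bg, collapse = ""), truth = truth, circular = spec$circular)
}
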
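# The CNE architecture model: the ordered element template (clusters plus
# the three dyad elements with their spacing windows) learned from a profiled
# family, a per-window scorer, and the both-strand genome scanner. Scoring is
# this package's operationalization of the observation that element order and
# spacing are tightly conserved: each element found near its expected offset
# contributes one point, with a linear penalty for offset violations.

#' Assemble a CNE architecture model from a profiled family
#'
#' Elements are the family's dyad-symmetry elements plus every conserved
#' cluster not housed inside a dyad span. Cluster patterns are the column
#' consensus with sub-maximal columns degenerated to the IUPAC code of the
#' observed bases; dyads keep their search specs. Element offset windows
#' (start position relative to the element start of the sequence) and
#' spacing windows are the per-sequence observed min/max widened by
#' \code{tolerance} on each side.
#'
#' @param profile A \code{cne_profile} of the family alignment.
#' @param clusters Output of \code{\link{segment_clusters}}.
#' @param dyads Output of \code{\link{classify_cne_dyads}} run on the
#'   family's modal-base consensus (coordinates in alignment columns).
#' @param aln The \code{cne_alignment} itself (for per-sequence offsets).
#' @param tolerance Widening of every observed window, bp (default 1).
#' @return Object of class \code{cne_model}.
#' @export
build_model <- function(profile, clusters, dyads, aln, tolerance = 1L) {
  stopifnot(inherits(profile, "cne_profile"), inherits(aln, "cne_alignment"))
  tolerance <- as.integer(tolerance)

  specs <- list(DSl = ds_terminal_spec("DS_terminal"),
                DSc = ds_central_spec("DS_central"),
                DSr = ds_terminal_spec("DS_terminal"))
  elements <- list()
  for (nm in c("DSl", "DSc", "DSr")) {
    d <- dyads[[nm]]
    if (is.null(d)) next
    elements[[length(elements) + 1L]] <- list(
      id = nm, kind = "dyad", spec = specs[[nm]],
      col_start = d$left_start, col_end = d$right_end,
      width = d$right_end - d$left_start + 1L)
  }
  dyad_spans <- do.call(rbind, lapply(elements, function(e) c(e$col_start, e$col_end)))

  if (!is.null(clusters) && nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      s <- clusters$start_col[i]; e <- clusters$end_col[i]
      if (!is.null(dyad_spans) &&
          any(dyad_spans[, 1] <= e & s <= dyad_spans[, 2])) next
      pat <- vapply(s:e, function(cc) {
        cnt <- c(A = profile$A[cc], C = profile$C[cc], G = profile$G[cc],
                 T = profile$T[cc])
        seen <- names(cnt)[cnt > 0]
        if (!length(seen)) "N" else iupac_code_for(seen)
      }, character(1))
      elements[[length(elements) + 1L]] <- list(
        id = clusters$label[i], kind = clusters$category[i],
        pattern = paste(pat, collapse = ""),
        col_start = s, col_end = e, width = e - s + 1L)
    }
  }
  if (length(elements) < 2L) {
    stop("a model needs at least two elements", call. = FALSE)
  }
  ord <- order(vapply(elements, `[[`, integer(1), "col_start"))
  elements <- elements[ord]

  # per-sequence ungapped offsets of each element start, relative to each
  # sequence's own element-region start (offset of the first element = 1)
  n_el <- length(elements)
  starts <- matrix(NA_real_, nrow = length(aln$ids), ncol = n_el)
  lens <- numeric(length(aln$ids))
  for (si in seq_along(aln$ids)) {
    ch <- strsplit(aln$seqs[[si]], "", fixed = TRUE)[[1]]
    upos <- cumsum(ch != "-")
    for (ei in seq_len(n_el)) {
      cols <- elements[[ei]]$col_start:elements[[ei]]$col_end
      nong <- cols[ch[cols] != "-"]
      if (length(nong)) starts[si, ei] <- upos[nong[1]]
    }
    lens[si] <- upos[length(upos)]
  }
  anchor <- starts[, 1]
  rel <- starts - anchor + 1

  for (ei in seq_len(n_el)) {
    obs <- rel[, ei]
    obs <- obs[!is.na(obs)]
    if (!length(obs)) obs <- elements[[ei]]$col_start
    elements[[ei]]$offset_min <- as.integer(max(1, min(obs) - tolerance))
    elements[[ei]]$offset_max <- as.integer(max(obs) + tolerance)
  }
  # spacing windows between consecutive elements (end of one to start of next)
  spacing <- NULL
  if (n_el >= 2L) {
    widths <- vapply(elements, `[[`, integer(1), "width")
    gaps <- rel[, -1, drop = FALSE] - (rel[, -n_el, drop = FALSE] +
                                         rep(widths[-n_el], each = nrow(rel)))
    spacing <- data.frame(
      from = vapply(elements[-n_el], `[[`, character(1), "id"),
      to = vapply(elements[-1], `[[`, character(1), "id"),
      min = apply(gaps, 2, min, na.rm = TRUE) - tolerance,
      max = apply(gaps, 2, max, na.rm = TRUE) + tolerance,
      stringsAsFactors = FALSE)
    rownames(spacing) <- NULL
  }

  structure(list(
    elements = elements, spacing = spacing,
    length_min = as.integer(min(lens) - tolerance),
    length_max = as.integer(max(lens) + tolerance),
    tolerance = tolerance
  ), class = "cne_model")
}

#' @export
print.cne_model <- function(x, ...) {
  cat(sprintf("<cne_model> %d elements, length window [%d, %d] bp\n",
              length(x$elements), x$length_min, x$length_max))
  for (e in x$elements) {
    what <- if (e$kind == "dyad") {
      sprintf("dyad %s..%s spacer %d-%d", e$spec$core_left, e$spec$core_right,
              e$spec$spacer_min, e$spec$spacer_max)
    } else e$pattern
    cat(sprintf("  %-4s %-18s offsets [%d, %d]  %s\n", e$id, e$kind,
                e$offset_min, e$offset_max, what))
  }
  invisible(x)
}

# match positions (start, end) of one model element within a sequence string
.element_matches <- function(el, s) {
  if (el$kind == "dyad") {
    hits <- find_core_hits(s, el$spec)
    if (!nrow(hits)) return(cbind(start = integer(0), end = integer(0)))
    m2 <- nchar(el$spec$core_right)
    cbind(start = hits$left_pos, end = hits$right_pos + m2 - 1L)
  } else {
    pos <- iupac_match_positions(el$pattern, s)
    cbind(start = pos, end = pos + nchar(el$pattern) - 1L)
  }
}

#' Score one window against a CNE architecture model
#'
#' Each model element contributes 1 when its pattern (or dyad spec) is found
#' with its start inside the element's cumulative offset window widened by
#' \code{slack}; the total spacing violation (bp by which found elements sit
#' outside their strict windows) is penalised linearly with weight
#' \code{lambda}. The maximal score equals the number of model elements.
#'
#' @param window_seq Window sequence (length near the model's length window).
#' @param model A \code{cne_model}.
#' @param lambda Spacing-violation weight per bp (default 0.1).
#' @param slack Extra bp allowed around the strict offset window (default 5).
#' @return List: \code{score}, \code{max_score}, \code{elements} (per-element
#'   found flag, matched position, violation).
#' @export
score_window <- function(window_seq, model, lambda = 0.1, slack = 5L) {
  stopifnot(inherits(model, "cne_model"))
  s <- if (is.character(window_seq)) toupper(window_seq) else as.character(window_seq)
  rows <- list()
  score <- 0
  for (el in model$elements) {
    m <- .element_matches(el, s)
    pos <- m[, "start"]
    inside <- pos >= el$offset_min - slack & pos <= el$offset_max + slack
    if (any(inside)) {
      cand <- pos[inside]
      viol <- pmax(0, el$offset_min - cand, cand - el$offset_max)
      k <- which.min(viol)
      score <- score + 1 - lambda * viol[k]
      rows[[length(rows) + 1L]] <- data.frame(
        id = el$id, found = TRUE, position = cand[k], violation = viol[k],
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        id = el$id, found = FALSE, position = NA_integer_, violation = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  list(score = score, max_score = length(model$elements),
       elements = do.call(rbind, rows))
}

#' Scan a genome on both strands for CNE-like loci
#'
#' Candidate window starts are derived from genome-wide matches of the
#' model's rarest elements (any window reaching \code{threshold} must contain
#' at least \code{ceiling(threshold)} elements, so it must contain one of the
#' \code{n - ceiling(threshold) + 1} rarest); each candidate is scored with
#' \code{\link{score_window}} semantics against precomputed match tables.
#' Hits with score >= \code{threshold} are selected greedily by score, ties
#' to the leftmost, and never overlap on forward coordinates. For circular
#' genomes the scan runs over an end-wrapped copy extended by one window
#' less one base; origin-spanning hits are reported with \code{end} greater
#' than the genome length.
#'
#' The default threshold 5 with the default six-element model requires all
#' three dyads plus at least two of the three clusters.
#'
#' @param genome Genome sequence string (or \code{\link{read_fasta}} entry).
#' @param model A \code{cne_model}.
#' @param threshold Minimum reported score (default 5).
#' @param lambda,slack Passed to the scoring semantics.
#' @param circular Treat the genome as circular (end-wrapped scan).
#' @param seq_id Name used in the output table.
#' @return Data frame of hits: \code{seq_id,start,end,strand,score,n_found,}
#'   \code{at_content} (1-based inclusive, forward-strand coordinates), with
#'   per-hit element details in the \code{"details"} attribute.
#' @export
scan_genome <- function(genome, model, threshold = 5, lambda = 0.1, slack = 5L,
                        circular = FALSE, seq_id = "genome") {
  stopifnot(inherits(model, "cne_model"))
  g <- if (is.character(genome)) toupper(genome) else toupper(as.character(genome))
  G <- nchar(g)
  if (G < model$length_max) stop("genome shorter than the model window", call. = FALSE)
  wrap <- if (circular) model$length_max - 1L else 0L

  strand_seqs <- list(
    "+" = if (wrap) paste0(g, substr(g, 1L, wrap)) else g,
    "-" = local({
      rc <- reverse_complement(g)
      if (wrap) paste0(rc, substr(rc, 1L, wrap)) else rc
    })
  )

  n_el <- length(model$elements)
  need <- min(n_el, max(1L, ceiling(threshold)))
  hits <- list()
  for (strand in c("+", "-")) {
    s <- strand_seqs[[strand]]
    matches <- lapply(model$elements, .element_matches, s = s)
    n_match <- vapply(matches, nrow, integer(1))
    rare <- order(n_match)[seq_len(n_el - need + 1L)]

    cand <- integer(0)
    for (ei in rare) {
      el <- model$elements[[ei]]
      pos <- matches[[ei]][, "start"]
      if (!length(pos)) next
      lo <- el$offset_min - slack; hi <- el$offset_max + slack
      cand <- c(cand, unlist(lapply(pos, function(p) (p - hi):(p - lo))))
    }
    cand <- sort(unique(cand))
    cand <- cand[cand >= 1L & cand <= nchar(s) - model$length_min + 1L]
    if (circular) cand <- cand[cand <= G]  # each origin window scanned once
    if (!length(cand)) next

    sorted_pos <- lapply(matches, function(m) m[, "start"])
    for (w0 in cand) {
      score <- 0; n_found <- 0L; last_end <- w0
      det <- list()
      for (ei in seq_len(n_el)) {
        el <- model$elements[[ei]]
        pos <- sorted_pos[[ei]]
        off <- pos - w0 + 1L
        inside <- off >= el$offset_min - slack & off <= el$offset_max + slack
        if (any(inside)) {
          offs <- off[inside]
          viol <- pmax(0, el$offset_min - offs, offs - el$offset_max)
          k <- which.min(viol)
          score <- score + 1 - lambda * viol[k]
          n_found <- n_found + 1L
          last_end <- max(last_end, matches[[ei]][inside, "end"][k])
          det[[length(det) + 1L]] <- data.frame(
            id = el$id, found = TRUE, position = offs[k], violation = viol[k],
            stringsAsFactors = FALSE)
        } else {
          det[[length(det) + 1L]] <- data.frame(
            id = el$id, found = FALSE, position = NA_integer_,
            violation = NA_real_, stringsAsFactors = FALSE)
        }
      }
      if (score < threshold) next
      w_len <- min(max(last_end - w0 + 1L, model$length_min), model$length_max)
      w_end <- w0 + w_len - 1L
      if (strand == "+") {
        fs <- w0; fe <- w_end
      } else {
        Ls <- nchar(s)
        fs <- Ls - wrap - w_end + 1L  # rev coords -> forward coords
        fe <- Ls - wrap - w0 + 1L
        if (fs < 1L) { fs <- fs + G; fe <- fe + G }  # origin-spanning
      }
      win <- substr(s, w0, w_end)
      hits[[length(hits) + 1L]] <- list(
        row = data.frame(seq_id = seq_id, start = fs, end = fe, strand = strand,
                         score = score, n_found = n_found,
                         at_content = at_content(win), stringsAsFactors = FALSE),
        details = do.call(rbind, det))
    }
  }

  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(), n_found = integer(),
                      at_content = numeric(), stringsAsFactors = FALSE)
  if (!length(hits)) {
    attr(empty, "details") <- list()
    return(empty)
  }
  tab <- do.call(rbind, lapply(hits, `[[`, "row"))
  ord <- order(-tab$score, tab$start)
  keep <- integer(0)
  for (i in ord) {
    clash <- any(vapply(keep, function(j) {
      tab$start[i] <= tab$end[j] && tab$start[j] <= tab$end[i]
    }, logical(1)))
    if (!clash) keep <- c(keep, i)
  }
  keep <- keep[order(tab$start[keep])]
  out <- tab[keep, , drop = FALSE]
  out$name <- sprintf("cne_hit_%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  attr(out, "details") <- lapply(hits[keep], `[[`, "details")
  out
}

#' Serialize a model to a human-readable config file
#'
#' Plain text: global key=value lines followed by one tab-separated line per
#' element. Round-trips through \code{\link{read_model}}.
#'
#' @param model A \code{cne_model}.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cne_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("length_min=%d", model$length_min),
    sprintf("length_max=%d", model$length_max),
    sprintf("tolerance=%d", model$tolerance),
    paste("#id", "kind", "pattern", "core_left", "core_right",
          "spacer_min", "spacer_max", "offset_min", "offset_max", "width",
          sep = "\t")), con)
  for (e in model$elements) {
    if (e$kind == "dyad") {
      line <- paste(e$id, e$kind, ".", e$spec$core_left, e$spec$core_right,
                    e$spec$spacer_min, e$spec$spacer_max,
                    e$offset_min, e$offset_max, e$width, sep = "\t")
    } else {
      line <- paste(e$id, e$kind, e$pattern, ".", ".", ".", ".",
                    e$offset_min, e$offset_max, e$width, sep = "\t")
    }
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a model config written by \code{\link{write_model}}
#' @param path Config path.
#' @return A \code{cne_model}.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- grep("^[a-z_]+=", lines, value = TRUE)
  vals <- stats::setNames(
    as.integer(sub("^[a-z_]+=", "", kv)),
    sub("=.*$", "", kv))
  el_lines <- lines[!grepl("^[a-z_]+=", lines) & !startsWith(lines, "#")]
  elements <- lapply(el_lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[2] == "dyad") {
      list(id = f[1], kind = "dyad",
           spec = dyad_spec(paste0("DS_", f[1]), f[4], f[5],
                            as.integer(f[6]), as.integer(f[7])),
           offset_min = as.integer(f[8]), offset_max = as.integer(f[9]),
           width = as.integer(f[10]))
    } else {
      list(id = f[1], kind = f[2], pattern = f[3],
           offset_min = as.integer(f[8]), offset_max = as.integer(f[9]),
           width = as.integer(f[10]))
    }
  })
  structure(list(elements = elements, spacing = NULL,
                 length_min = vals[["length_min"]],
                 length_max = vals[["length_max"]],
                 tolerance = vals[["tolerance"]]),
            class = "cne_model")
}
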
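# Dyad-symmetry element (DS) detection. A DS is a pair of inverted-repeat
# arms around a non-symmetric spacer. The CNE carries three: terminal DSl and
# DSr (degenerate WTTWTG cores, 5-nt spacer; minimal "core DS" = 17 bp) and a
# central DSc (GWAGACTWT / AHAGTCTWC cores, 9-10-nt spacer; core DSc = 27 bp).
# Arms extend outward beyond the cores through strictly Watson-Crick
# complementary base pairs.

#' Define a dyad-symmetry element search specification
#'
#' @param name Label (e.g. \code{"DS_terminal"}, \code{"DS_central"}).
#' @param core_left IUPAC pattern of the left core arm.
#' @param core_right IUPAC pattern of the right core arm; must be
#'   positionwise compatible with the reverse complement of \code{core_left}
#'   (their base sets must intersect at every position).
#' @param spacer_min,spacer_max Allowed spacer lengths in nt.
#' @return Object of class \code{dyad_spec}.
#' @export
dyad_spec <- function(name, core_left, core_right = reverse_complement(core_left),
                      spacer_min, spacer_max = spacer_min) {
  core_left <- toupper(core_left); core_right <- toupper(core_right)
  spacer_min <- as.integer(spacer_min); spacer_max <- as.integer(spacer_max)
  stopifnot(nzchar(core_left), nzchar(core_right),
            spacer_min >= 0L, spacer_min <= spacer_max)
  rc <- .seq_chars(reverse_complement(core_left))
  cr <- .check_iupac(.seq_chars(core_right), "core_right")
  if (length(rc) != length(cr)) {
    stop("core_right length must equal core_left length", call. = FALSE)
  }
  compat <- bitwAnd(.iupac_bits[rc], .iupac_bits[cr]) != 0L
  if (!all(compat)) {
    stop("core_right is not reverse-complement-compatible with core_left ",
         "at position ", which(!compat)[1], call. = FALSE)
  }
  structure(list(name = name, core_left = core_left, core_right = core_right,
                 spacer_min = spacer_min, spacer_max = spacer_max),
            class = "dyad_spec")
}

#' Terminal-DS specification (DSl / DSr)
#'
#' WTTWTG core arm in forward and reverse orientation around a 5-nt spacer.
#' @param name Spec label.
#' @return A \code{dyad_spec}.
#' @export
ds_terminal_spec <- function(name = "DS_terminal") {
  dyad_spec(name, "WTTWTG", "CAWAAW", 5L, 5L)
}

#' Central-DS specification (DSc)
#'
#' GWAGACTWT and its reverse complement written degenerately as AHAGTCTWC,
#' around a 9-10-nt spacer.
#' @param name Spec label.
#' @return A \code{dyad_spec}.
#' @export
ds_central_spec <- function(name = "DS_central") {
  dyad_spec(name, "GWAGACTWT", "AHAGTCTWC", 9L, 10L)
}

#' Fallback terminal-core variants
#'
#' Degenerate core hexamers seen in a handful of species whose terminal arms
#' drifted off the WTTWTG consensus: the TTATTG/CAATAA variant and the
#' CAAAAT/ATTTTG variant. Tried by \code{\link{classify_cne_dyads}} only when
#' the primary terminal spec finds nothing.
#' @return List of \code{dyad_spec}s.
#' @export
ds_terminal_fallbacks <- function() {
  list(dyad_spec("DS_terminal_TTATTG", "TTATTG", "CAATAA", 5L, 5L),
       dyad_spec("DS_terminal_CAAAAT", "CAAAAT", "ATTTTG", 5L, 5L))
}

#' Find core dyad candidates in a sequence
#'
#' Reports every position where the left core pattern matches the forward
#' strand and the right core pattern matches downstream at a spacer within
#' the spec's window. Minus-strand search is the scanner's job (it reverse
#' complements the query window).
#'
#' @param seq Sequence string (IUPAC alphabet).
#' @param spec A \code{dyad_spec}.
#' @return Data frame \code{left_pos,right_pos,spacer} in deterministic
#'   left-to-right (then increasing spacer) order; possibly empty.
#' @export
find_core_hits <- function(seq, spec) {
  stopifnot(inherits(spec, "dyad_spec"))
  s <- if (is.character(seq)) toupper(seq) else as.character(seq)
  m <- nchar(spec$core_left)
  left <- iupac_match_positions(spec$core_left, s)
  right <- iupac_match_positions(spec$core_right, s)
  out <- list()
  for (l in left) {
    for (sp in spec$spacer_min:spec$spacer_max) {
      r <- l + m + sp
      if (r %in% right) out[[length(out) + 1L]] <- c(l, r, sp)
    }
  }
  if (!length(out)) {
    return(data.frame(left_pos = integer(), right_pos = integer(),
                      spacer = integer()))
  }
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("left_pos", "right_pos", "spacer")
  res[order(res$left_pos, res$spacer), , drop = FALSE]
}

.WC_PAIR <- c(A = "T", C = "G", G = "C", T = "A")

#' Extend a core dyad candidate to its maximal arms
#'
#' Arms grow symmetrically outward from the cores one base pair at a time
#' while the outer left base is the strict Watson-Crick complement of the
#' outer right base, stopping at the first failure or the sequence boundary.
#' With the default zero mismatch allowance the extended regions (outside the
#' cores) reverse-complement each other exactly; a nonzero allowance tolerates
#' isolated non-complementary pairs (for the degenerate-species variants) but
#' arms always end on a complementary pair.
#'
#' @param seq Sequence string.
#' @param candidate One row of \code{\link{find_core_hits}} (or a list with
#'   \code{left_pos,right_pos,spacer}).
#' @param spec The \code{dyad_spec} the candidate came from.
#' @param max_mismatch Mismatches tolerated inside the extension (default 0).
#' @return Object of class \code{dyad_element}: arm intervals, spacer length,
#'   \code{arm_length} (core + extension), \code{total_span}, spec name, and
#'   mismatch offsets within the extension.
#' @export
extend_arms <- function(seq, candidate, spec, max_mismatch = 0L) {
  stopifnot(inherits(spec, "dyad_spec"))
  s <- .seq_chars(if (is.character(seq)) seq else as.character(seq))
  L <- length(s)
  lp <- as.integer(candidate$left_pos)
  rp <- as.integer(candidate$right_pos)
  m <- nchar(spec$core_left)
  m2 <- nchar(spec$core_right)
  ext <- 0L; mism <- 0L; mismatch_at <- integer(0)
  last_good <- 0L
  repeat {
    li <- lp - ext - 1L
    ri <- rp + m2 + ext
    if (li < 1L || ri > L) break
    a <- s[li]; b <- s[ri]
    ok <- a %in% names(.WC_PAIR) && identical(unname(.WC_PAIR[a]), b)
    if (ok) {
      ext <- ext + 1L
      last_good <- ext
    } else {
      if (mism + 1L > max_mismatch) break
      mism <- mism + 1L
      mismatch_at <- c(mismatch_at, ext + 1L)
      ext <- ext + 1L
    }
  }
  ext <- last_good  # arms end on a complementary pair
  mismatch_at <- mismatch_at[mismatch_at <= ext]
  arm <- m + ext
  structure(list(
    left_start = lp - ext, left_end = lp + m - 1L,
    right_start = rp, right_end = rp + m2 - 1L + ext,
    spacer_length = rp - (lp + m - 1L) - 1L,
    arm_length = arm, core_length = m,
    total_span = (rp + m2 - 1L + ext) - (lp - ext) + 1L,
    spec_name = spec$name, mismatch_at = mismatch_at
  ), class = "dyad_element")
}

#' @export
print.dyad_element <- function(x, ...) {
  cat(sprintf("<dyad_element %s> arms %d-%d / %d-%d, arm %d bp, spacer %d nt, span %d bp\n",
              x$spec_name, x$left_start, x$left_end, x$right_start, x$right_end,
              x$arm_length, x$spacer_length, x$total_span))
  invisible(x)
}

#' Exhaustively enumerate inverted repeats (testing oracle)
#'
#' Full enumeration over every (inner left-arm end, spacer) pair: the arm at
#' a pair is the maximal run of strictly Watson-Crick complementary bases
#' growing outward from the innermost positions. Quadratic and intended as an
#' independent oracle on small instances, not for genome-scale use.
#'
#' @param seq Sequence string (<= 10 kb).
#' @param min_arm Minimum arm length to report.
#' @param spacer_min,spacer_max Spacer range.
#' @return List of \code{dyad_element}s (spec name \code{"enumerated"}),
#'   ordered by left arm start then spacer.
#' @export
enumerate_inverted_repeats <- function(seq, min_arm, spacer_min, spacer_max = spacer_min) {
  s <- .seq_chars(if (is.character(seq)) seq else as.character(seq))
  L <- length(s)
  if (L > 10000L) stop("enumeration oracle capped at 10 kb", call. = FALSE)
  out <- list()
  for (i in seq_len(L)) {
    for (sp in spacer_min:spacer_max) {
      j0 <- i + sp + 1L
      if (j0 > L) next
      k <- 0L
      while (i - k >= 1L && j0 + k <= L) {
        a <- s[i - k]; b <- s[j0 + k]
        if (!(a %in% names(.WC_PAIR)) || !identical(unname(.WC_PAIR[a]), b)) break
        k <- k + 1L
      }
      if (k >= min_arm) {
        out[[length(out) + 1L]] <- structure(list(
          left_start = i - k + 1L, left_end = i,
          right_start = j0, right_end = j0 + k - 1L,
          spacer_length = sp, arm_length = k, core_length = NA_integer_,
          total_span = 2L * k + sp, spec_name = "enumerated",
          mismatch_at = integer(0)), class = "dyad_element")
      }
    }
  }
  ord <- order(vapply(out, `[[`, integer(1), "left_start"),
               vapply(out, `[[`, integer(1), "spacer_length"))
  out[ord]
}

# Greedy overlap resolution: longest arm wins, ties to the leftmost element.
.dedupe_dyads <- function(elements) {
  if (length(elements) <= 1L) return(elements)
  arm <- vapply(elements, `[[`, integer(1), "arm_length")
  left <- vapply(elements, `[[`, integer(1), "left_start")
  ord <- order(-arm, left)
  kept <- list()
  for (i in ord) {
    e <- elements[[i]]
    clash <- any(vapply(kept, function(k) {
      e$left_start <= k$right_end && k$left_start <= e$right_end
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- e
  }
  kept[order(vapply(kept, `[[`, integer(1), "left_start"))]
}

#' Locate the three CNE dyad elements in a CNE-scale sequence
#'
#' Runs the terminal spec (falling back to the degenerate-core variants when
#' it finds nothing) and the central spec, extends arms, resolves overlaps
#' (longest arm, ties leftmost), and assigns: leftmost terminal hit to DSl,
#' rightmost to DSr (a single terminal hit is assigned by which half of the
#' sequence it sits in), and the best central hit (longest arm, ties nearest
#' the sequence midpoint) to DSc. Absence of an element is a legal result
#' reported as \code{NULL}.
#'
#' @param seq CNE-scale sequence string (roughly 120-250 bp).
#' @param terminal_spec,central_spec Dyad specs (defaults as published).
#' @param fallbacks Fallback terminal specs tried when the primary finds
#'   nothing.
#' @param max_mismatch Extension mismatch allowance passed through.
#' @return List with elements \code{DSl}, \code{DSc}, \code{DSr} (each a
#'   \code{dyad_element} or \code{NULL}); attribute \code{fallback_used}
#'   names any fallback spec that produced the terminal calls.
#' @export
classify_cne_dyads <- function(seq, terminal_spec = ds_terminal_spec(),
                               central_spec = ds_central_spec(),
                               fallbacks = ds_terminal_fallbacks(),
                               max_mismatch = 0L) {
  s <- if (is.character(seq)) toupper(seq) else as.character(seq)
  L <- nchar(s)

  term_from <- function(spec) {
    hits <- find_core_hits(s, spec)
    lapply(seq_len(nrow(hits)), function(i) extend_arms(s, hits[i, ], spec, max_mismatch))
  }
  fallback_used <- character(0)
  terminals <- term_from(terminal_spec)
  if (!length(terminals)) {
    for (fb in fallbacks) {
      terminals <- c(terminals, term_from(fb))
    }
    if (length(terminals)) {
      fallback_used <- unique(vapply(terminals, `[[`, character(1), "spec_name"))
    }
  }
  terminals <- .dedupe_dyads(terminals)

  dsl <- dsr <- NULL
  if (length(terminals) >= 2L) {
    dsl <- terminals[[1L]]
    dsr <- terminals[[length(terminals)]]
  } else if (length(terminals) == 1L) {
    e <- terminals[[1L]]
    center <- (e$left_start + e$right_end) / 2
    if (center <= L / 2) dsl <- e else dsr <- e
  }

  centrals <- term_from(central_spec)
  centrals <- .dedupe_dyads(centrals)
  dsc <- NULL
  if (length(centrals)) {
    arm <- vapply(centrals, `[[`, integer(1), "arm_length")
    mid_dist <- vapply(centrals, function(e) abs((e$left_start + e$right_end) / 2 - (L + 1) / 2),
                       numeric(1))
    left <- vapply(centrals, `[[`, integer(1), "left_start")
    dsc <- centrals[[order(-arm, mid_dist, left)[1L]]]
  }

  structure(list(DSl = dsl, DSc = dsc, DSr = dsr), fallback_used = fallback_used)
}

#' Dyad elements as a data frame (for TSV/BED export)
#' @param dyads Named list of \code{dyad_element}s (NULLs dropped).
#' @return Data frame with one row per element.
#' @export
dyads_to_table <- function(dyads) {
  dyads <- Filter(Negate(is.null), dyads)
  if (!length(dyads)) {
    return(data.frame(name = character(), left_start = integer(),
                      left_end = integer(), right_start = integer(),
                      right_end = integer(), spacer = integer(),
                      arm_length = integer(), total_span = integer(),
                      spec = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    name = names(dyads),
    left_start = vapply(dyads, `[[`, integer(1), "left_start"),
    left_end = vapply(dyads, `[[`, integer(1), "left_end"),
    right_start = vapply(dyads, `[[`, integer(1), "right_start"),
    right_end = vapply(dyads, `[[`, integer(1), "right_end"),
    spacer = vapply(dyads, `[[`, integer(1), "spacer_length"),
    arm_length = vapply(dyads, `[[`, integer(1), "arm_length"),
    total_span = vapply(dyads, `[[`, integer(1), "total_span"),
    spec = vapply(dyads, `[[`, character(1), "spec_name"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
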
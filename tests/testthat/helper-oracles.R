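# Independent oracles used by the tests. These deliberately share no code
# with the package: alignment scoring by exhaustive recursion, IUPAC matching
# by explicit set expansion, segmentation by a direct mask walk, ORFs by a
# codon walk from every ATG.

# Optimal affine-gap global alignment score by memoised recursion over
# (i, j, previous-move) states; terminal gaps are charged. Only for tiny
# strings.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 5, ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == b[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "d"))
    }
    if (i <= length(a)) {
      cost <- ext + if (prev != "u") open else 0
      best <- max(best, -cost + rec(i + 1, j, "u"))
    }
    if (j <= length(b)) {
      cost <- ext + if (prev != "l") open else 0
      best <- max(best, -cost + rec(i, j + 1, "l"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "d")
}

# IUPAC sets written out independently of the package's table.
oracle_iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_iupac_match <- function(pattern, window) {
  p <- strsplit(pattern, "")[[1]]; w <- strsplit(window, "")[[1]]
  stopifnot(length(p) == length(w))
  all(mapply(function(pc, wc) wc %in% oracle_iupac_sets[[pc]], p, w))
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Segmentation by a direct walk over a logical conserved mask.
oracle_segment <- function(mask, max_intervening, min_conserved) {
  pos <- which(mask)
  if (!length(pos)) return(data.frame(start = integer(), end = integer(),
                                      n = integer()))
  groups <- list(); cur <- pos[1]
  for (p in pos[-1]) {
    if (p - cur[length(cur)] - 1 <= max_intervening) cur <- c(cur, p)
    else { groups[[length(groups) + 1]] <- cur; cur <- p }
  }
  groups[[length(groups) + 1]] <- cur
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(start = g[1], end = g[length(g)], n = length(g))
  }))
  out[out$n >= min_conserved, , drop = FALSE]
}

# Forward-strand ORFs by walking codons from every ATG, then keeping the
# 5'-most ATG per (frame, stop).
oracle_orfs_fwd <- function(s, min_len) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  stops <- c("TAA", "TAG", "TGA")
  cands <- list()
  for (i in seq_len(L - 2)) {
    if (paste(ch[i:(i + 2)], collapse = "") != "ATG") next
    j <- i
    repeat {
      if (j + 2 > L) break
      cod <- paste(ch[j:(j + 2)], collapse = "")
      if (j > i && cod %in% stops) {
        len <- j + 2 - i + 1
        if (len >= min_len) {
          cands[[length(cands) + 1]] <- data.frame(
            start = i, end = j + 2, frame = (i - 1) %% 3, length = len)
        }
        break
      }
      j <- j + 3
    }
  }
  if (!length(cands)) return(data.frame(start = integer(), end = integer(),
                                        frame = integer(), length = integer()))
  df <- do.call(rbind, cands)
  df <- df[order(df$end, df$start), ]
  df[!duplicated(df[, c("frame", "end")]), ]
}

# Random concrete sequence with a given AT fraction.
random_seq <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}
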
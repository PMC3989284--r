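make_aln_from_cols <- function(cols) {
  # cols: list of character vectors, one per column, all the same length
  n <- length(cols[[1]])
  seqs <- vapply(seq_len(n), function(i) {
    paste(vapply(cols, `[`, character(1), i), collapse = "")
  }, character(1))
  new_alignment(stats::setNames(seqs, sprintf("s%02d", seq_len(n))))
}

test_that("information content matches the entropy arithmetic", {
  aln <- make_aln_from_cols(list(rep("T", 38), rep("T", 38)))
  prof <- column_profiles(aln)
  expect_equal(prof$ic, c(2, 2))

  aln2 <- make_aln_from_cols(list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  prof2 <- column_profiles(aln2)
  expect_equal(prof2$ic, c(0, 0))

  aln3 <- make_aln_from_cols(list(c("A", "A", "A", "T"), c("A", "A", "A", "T")))
  prof3 <- column_profiles(aln3)
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(prof3$ic[1], 2 - h, tolerance = 1e-12)
  expect_equal(prof3$modal_freq[1], 0.75)
  expect_equal(round(prof3$ic[1], 3), 1.189)
})

test_that("consensus characters follow the uppercase/lowercase/n/. policy", {
  cols <- list(
    rep("T", 38),                                    # complete conservation
    c(rep("A", 19), rep("C", 10), rep("G", 9)),      # modal 0.5 -> lowercase
    c(rep("-", 30), rep("A", 8)),                    # gap majority -> '.'
    c(rep("A", 10), rep("C", 10), rep("G", 9), rep("T", 9)),  # weak -> 'n'
    c(rep("A", 19), rep("T", 19))                    # tie at threshold -> 'n'
  )
  aln <- make_aln_from_cols(cols)
  prof <- column_profiles(aln)
  expect_identical(consensus_string(prof), "Ta.nn")
  expect_equal(nchar(consensus_string(prof)), aln$n_cols)

  # small worked case: 2 A, 1 C, 1 G -> 'a'
  aln2 <- make_aln_from_cols(list(c("A", "A", "C", "G"), rep("A", 4)))
  expect_identical(consensus_string(column_profiles(aln2)), "aA")

  # all-gap column -> coverage 0, IC 0, '.'
  aln3 <- new_alignment(c(a = "A-G", b = "A-G"))
  prof3 <- column_profiles(aln3)
  expect_equal(prof3$coverage[2], 0)
  expect_equal(prof3$ic[2], 0)
  expect_identical(consensus_string(prof3), "A.G")
})

test_that("uppercase consensus positions are completely conserved non-gap columns", {
  fam <- simulate_family(family_spec(n_sequences = 15, divergence = 0.3, seed = 23))
  prof <- column_profiles(fam$truth_alignment)
  cons <- strsplit(consensus_string(prof), "")[[1]]
  upper <- which(cons %in% c("A", "C", "G", "T"))
  n <- attr(prof, "n_records")
  expect_true(all(prof$modal_freq[upper] == 1))
  expect_true(all(prof$gap[upper] / n <= 0.5))
})

test_that("cluster segmentation matches the brute-force mask oracle", {
  aln_ident <- new_alignment(c(a = strrep("ACGT", 10), b = strrep("ACGT", 10)))
  prof <- column_profiles(aln_ident)
  cl <- segment_clusters(prof)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start_col, 1L)
  expect_equal(cl$end_col, 40L)

  # conserved at {1,2,3, 10,11,12}, six intervening -> two clusters
  cols <- lapply(1:12, function(i) {
    if (i <= 3 || i >= 10) rep("A", 4) else c("A", "C", "G", "T")
  })
  cl2 <- segment_clusters(column_profiles(make_aln_from_cols(cols)),
                          max_intervening = 2, min_conserved = 3)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$start_col, c(1L, 10L))

  set.seed(41)
  for (i in 1:40) {
    mask <- runif(60) < 0.35
    cols <- lapply(seq_along(mask), function(k) {
      if (mask[k]) rep("T", 6) else c("A", "A", "C", "C", "G", "T")
    })
    prof <- column_profiles(make_aln_from_cols(cols))
    mi <- sample(0:3, 1); mc <- sample(1:4, 1)
    got <- segment_clusters(prof, max_intervening = mi, min_conserved = mc)
    want <- oracle_segment(mask, mi, mc)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start_col, want$start)
    expect_equal(got$end_col, want$end)
    expect_equal(got$n_conserved, want$n)
    expect_true(sum(got$n_conserved) <= sum(mask))
  }
})

test_that("cluster spacing ranges track the planted jitter", {
  fam0 <- simulate_family(family_spec(divergence = 0, indel_max = 0, seed = 3))
  prof0 <- column_profiles(fam0$truth_alignment)
  # zero divergence, concrete template: every column conserved, one cluster
  expect_true(all(prof0$conserved))
  cl0 <- segment_clusters(prof0)
  expect_equal(nrow(cl0), 1L)

  # jittered family, truth alignment: every adjacent-pair range width <= 3
  fam <- simulate_family(family_spec(divergence = 0.15, indel_max = 3, seed = 13))
  prof <- column_profiles(fam$truth_alignment)
  cl <- segment_clusters(prof)
  expect_true(nrow(cl) >= 2L)
  sp <- cluster_spacings(cl, fam$truth_alignment)
  expect_true(all(sp$summary$width <= 3))

  # no-jitter family at positive divergence: spacing widths all zero
  fam2 <- simulate_family(family_spec(divergence = 0.15, indel_max = 0, seed = 13))
  prof2 <- column_profiles(fam2$truth_alignment)
  cl2 <- segment_clusters(prof2)
  sp2 <- cluster_spacings(cl2, fam2$truth_alignment)
  expect_true(all(sp2$summary$width == 0))
})

test_that("AT fraction of conserved bases follows its definition", {
  aln <- new_alignment(c(a = "AAAA", b = "AAAA"))
  expect_equal(at_fraction_of_conserved(column_profiles(aln)), 100)

  aln2 <- new_alignment(c(a = "ATGC", b = "ATGC"))
  expect_equal(at_fraction_of_conserved(column_profiles(aln2)), 50)

  aln3 <- new_alignment(c(a = "AC", b = "CA"))
  expect_true(is.na(at_fraction_of_conserved(column_profiles(aln3))))
})
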
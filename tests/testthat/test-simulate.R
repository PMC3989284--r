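test_that("the built-in template satisfies its own grammar", {
  tpl <- default_cne_template()
  expect_gte(nchar(tpl$template), 154)
  expect_lte(nchar(tpl$template), 157)
  expect_equal(sum(tpl$elements$kind == "dyad"), 3L)
  expect_gte(sum(tpl$elements$kind == "tat_cluster"), 2L)
  # TAT clusters really are TAT; c3 ends in TAT
  for (i in which(tpl$elements$kind == "tat_cluster")) {
    expect_identical(substr(tpl$template, tpl$elements$start[i],
                            tpl$elements$end[i]), "TAT")
  }
  # degenerate view masks exactly the variable columns
  ch <- strsplit(tpl$degenerate, "")[[1]]
  expect_identical(which(ch == "N"), tpl$variable_cols)
  # self-consistency with the dyad detector
  d <- classify_cne_dyads(tpl$template)
  expect_false(any(vapply(d, is.null, logical(1))))
})

test_that("family simulation is deterministic and honours its bounds", {
  spec <- family_spec(seed = 33)
  f1 <- simulate_family(spec)
  f2 <- simulate_family(spec)
  expect_identical(f1$sequences, f2$sequences)
  expect_identical(f1$truth_alignment$seqs, f2$truth_alignment$seqs)

  tpl_len <- nchar(default_cne_template()$template)
  lens <- nchar(f1$sequences)
  expect_true(all(lens <= tpl_len))
  expect_true(all(lens >= tpl_len - 5 * 3))  # five regions, <= 3 bp each
  # length equals template minus deletions, per sequence
  gaps <- vapply(f1$truth_alignment$seqs, function(s) {
    sum(strsplit(s, "")[[1]] == "-")
  }, integer(1))
  expect_equal(unname(nchar(f1$sequences)), unname(tpl_len - gaps))
})

test_that("zero-divergence families are identical copies of the template", {
  f <- simulate_family(family_spec(divergence = 0, indel_max = 0,
                                   n_sequences = 5, seed = 2))
  tpl <- default_cne_template()$template
  expect_true(all(f$sequences == tpl))
  # round trip: align -> profile -> segment gives one cluster over everything
  rep <- profile_family(f$sequences)
  expect_equal(rep$summary$n_clusters, 1L)
  expect_equal(rep$clusters$start_col, 1L)
  expect_equal(rep$clusters$end_col, nchar(tpl))
  expect_setequal(rep$summary$dyads_found, c("DSl", "DSc", "DSr"))
})

test_that("truth alignment conserved set equals the template's fixed columns", {
  f <- simulate_family(family_spec(divergence = 0.35, seed = 44))
  tpl <- default_cne_template()
  prof <- column_profiles(f$truth_alignment)
  fixed <- setdiff(seq_len(nchar(tpl$template)), tpl$variable_cols)
  # every fixed column is absolutely conserved by construction
  expect_true(all(prof$conserved[fixed]))
  # a column carrying any gap is never absolutely conserved
  expect_true(all(!prof$conserved[prof$gap > 0]))
})

test_that("moderate-divergence identities live in the published band", {
  f <- simulate_family(family_spec(divergence = 0.2, seed = 55))
  rep <- profile_family(f$sequences)
  off <- rep$identity$values[upper.tri(rep$identity$values)]
  expect_true(all(off >= 60 & off <= 100))
})

test_that("genome simulation is deterministic, placed, and at the right AT", {
  tpl <- default_cne_template()$template
  gs <- genome_spec(length = 50000, gc = 0.43,
                    plants = list(list(seq = tpl, pos = 1234, strand = "+")),
                    seed = 6)
  g1 <- simulate_genome(gs)
  g2 <- simulate_genome(gs)
  expect_identical(g1$genome, g2$genome)

  expect_equal(nrow(g1$truth), 1L)
  expect_equal(g1$truth$start, 1234L)
  expect_identical(substr(g1$genome, 1234, 1234 + nchar(tpl) - 1L), tpl)

  expect_equal(at_content(g1$genome), 57, tolerance = 0.04)

  # minus-strand plants are spliced as reverse complement
  gsm <- genome_spec(length = 20000, gc = 0.43,
                     plants = list(list(seq = tpl, pos = 500, strand = "-")),
                     seed = 6)
  gm <- simulate_genome(gsm)
  expect_identical(substr(gm$genome, 500, 500 + nchar(tpl) - 1L),
                   reverse_complement(tpl))

  # overlapping placements error
  expect_error(simulate_genome(genome_spec(
    length = 20000, plants = list(list(seq = tpl, pos = 100, strand = "+"),
                                  list(seq = tpl, pos = 150, strand = "+")),
    seed = 1)), "overlap")
})

test_that("an empty plant list gives pure background with no truth rows", {
  sim <- simulate_genome(genome_spec(length = 10000, gc = 0.5, seed = 12))
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nchar(sim$genome), 10000L)
})
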
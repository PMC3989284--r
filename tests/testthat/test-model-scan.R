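tpl <- default_cne_template()

# a model learned from a modestly diverged family, reused across tests
fam_for_model <- simulate_family(family_spec(divergence = 0.12, seed = 77))
rep_for_model <- profile_family(fam_for_model$sequences)
model <- build_model(rep_for_model$profile, rep_for_model$clusters,
                     rep_for_model$dyads, rep_for_model$alignment)

test_that("a zero-divergence family gives a degenerate-width model", {
  fam0 <- simulate_family(family_spec(divergence = 0, indel_max = 0, seed = 1))
  rep0 <- profile_family(fam0$sequences)
  m0 <- build_model(rep0$profile, rep0$clusters, rep0$dyads, rep0$alignment,
                    tolerance = 0)
  expect_true(all(m0$spacing$max - m0$spacing$min == 0))
  widths <- vapply(m0$elements, function(e) e$offset_max - e$offset_min, integer(1))
  expect_true(all(widths == 0))
  expect_equal(m0$length_min, nchar(tpl$template))
  expect_equal(m0$length_max, nchar(tpl$template))
})

test_that("model learned from a jittered family has narrow windows in the CNE range", {
  fam <- simulate_family(family_spec(divergence = 0.1, indel_max = 3, seed = 7))
  rep <- profile_family(fam$sequences)
  m <- build_model(rep$profile, rep$clusters, rep$dyads, rep$alignment,
                   tolerance = 0)
  # spacing window widths bounded by the planted jitter
  expect_true(all(m$spacing$max - m$spacing$min <= 3))
  # total length window within the template size band
  expect_gte(m$length_min, 154 - 3 * 5)
  expect_lte(m$length_max, 157)
})

test_that("window scoring is maximal on the template and drops by one per ablated element", {
  sc <- score_window(tpl$template, model)
  expect_equal(sc$score, sc$max_score)
  expect_equal(sc$max_score, 6)

  s <- tpl$template
  dsc_start <- tpl$elements$start[tpl$elements$element_id == "DSc"]
  substr(s, dsc_start, dsc_start + 8) <- "GGGGGGGGG"
  sc2 <- score_window(s, model)
  expect_equal(sc2$score, sc$score - 1)
  expect_false(sc2$elements$found[sc2$elements$id == "DSc"])
})

test_that("shuffled CNEs score below the calling threshold almost always", {
  set.seed(91)
  chars <- strsplit(tpl$template, "")[[1]]
  scores <- vapply(1:200, function(i) {
    score_window(paste(sample(chars), collapse = ""), model)$score
  }, numeric(1))
  expect_gte(mean(scores < 5), 0.95)
})

test_that("the scanner recovers plants on both strands and ignores decoys", {
  gs <- genome_spec(length = 50000, gc = 0.43,
                    plants = list(
                      list(seq = fam_for_model$sequences[[1]], pos = 10000, strand = "+"),
                      list(seq = fam_for_model$sequences[[2]], pos = 30000, strand = "-")),
                    decoys = c("lone_DS", "shuffled_CNE", "tandem_TAT"),
                    seed = 42)
  sim <- simulate_genome(gs)
  hits <- scan_genome(sim$genome, model)
  expect_equal(nrow(hits), 2L)
  truth <- sim$truth[sim$truth$kind == "plant", ]
  for (k in 1:2) {
    d <- abs(hits$start - truth$start[k]) <= 3 & hits$strand == truth$strand[k]
    expect_true(any(d))
  }
  # no hit overlaps any decoy
  decoys <- sim$truth[startsWith(sim$truth$kind, "decoy"), ]
  for (j in seq_len(nrow(decoys))) {
    expect_false(any(hits$start <= decoys$end[j] & decoys$start[j] <= hits$end))
  }
  # greedy selection never reports overlapping intervals
  if (nrow(hits) > 1) {
    ord <- order(hits$start)
    expect_true(all(hits$start[ord][-1] > hits$end[ord][-nrow(hits)]))
  }
})

test_that("scanning the reverse-complemented genome mirrors the hit set", {
  gs <- genome_spec(length = 20000, gc = 0.45,
                    plants = list(list(seq = tpl$template, pos = 8000, strand = "+")),
                    seed = 8)
  sim <- simulate_genome(gs)
  L <- nchar(sim$genome)
  h1 <- scan_genome(sim$genome, model)
  h2 <- scan_genome(reverse_complement(sim$genome), model)
  expect_equal(nrow(h1), nrow(h2))
  m_start <- L - h2$end + 1L
  m_end <- L - h2$start + 1L
  m_strand <- ifelse(h2$strand == "+", "-", "+")
  expect_setequal(paste(h1$start, h1$end, h1$strand),
                  paste(m_start, m_end, m_strand))
})

test_that("a pure background genome yields no hits at the default threshold", {
  for (seed in c(3, 14, 159)) {
    sim <- simulate_genome(genome_spec(length = 30000, gc = 0.43, seed = seed))
    expect_equal(nrow(scan_genome(sim$genome, model)), 0L)
  }
})

test_that("circular scanning finds an element split across the origin", {
  set.seed(77)
  bg <- random_seq(12000, at = 0.57)
  s <- tpl$template
  front <- substr(s, 81, nchar(s))       # second part at genome start
  back <- substr(s, 1, 80)               # first part at genome end
  genome <- paste0(front, substr(bg, 1, 11000), back)
  hits_lin <- scan_genome(genome, model, circular = FALSE)
  hits_circ <- scan_genome(genome, model, circular = TRUE)
  expect_equal(nrow(hits_lin), 0L)
  expect_equal(nrow(hits_circ), 1L)
  expect_gt(hits_circ$end[1], nchar(genome))  # origin-spanning convention
})

test_that("models survive a config round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$length_min, model$length_min)
  expect_equal(back$length_max, model$length_max)
  expect_equal(length(back$elements), length(model$elements))
  sim <- simulate_genome(genome_spec(length = 20000, gc = 0.45,
                                     plants = list(list(seq = tpl$template,
                                                        pos = 5000, strand = "+")),
                                     seed = 4))
  h1 <- scan_genome(sim$genome, model)
  h2 <- scan_genome(sim$genome, back)
  expect_equal(h1$start, h2$start)
  expect_equal(h1$score, h2$score)
})
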
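test_that("core hit detection finds the published dyad compositions", {
  h <- find_core_hits("TTTTTGACGTACAAAAA", ds_terminal_spec())
  expect_equal(nrow(h), 1L)
  expect_equal(h$left_pos, 1L)
  expect_equal(h$spacer, 5L)

  expect_equal(nrow(find_core_hits(strrep("G", 60), ds_terminal_spec())), 0L)

  hc <- find_core_hits("GAAGACTATCCCCCCCCCATAGTCTTC", ds_central_spec())
  expect_equal(nrow(hc), 1L)
  expect_equal(hc$spacer, 9L)
  # both cores verified degenerate-compatible by the IUPAC oracle
  expect_true(oracle_iupac_match("GWAGACTWT", "GAAGACTAT"))
  expect_true(oracle_iupac_match("AHAGTCTWC", "ATAGTCTTC"))
})

test_that("arm extension yields the 17-bp and 27-bp core dyads and grows through complements", {
  spec <- ds_terminal_spec()
  s <- "CCTTTTTGACGTACAAAAACC"  # C/C flanks do not pair
  h <- find_core_hits(s, spec)
  e <- extend_arms(s, h[1, ], spec)
  expect_equal(e$arm_length, 6L)
  expect_equal(e$total_span, 17L)
  expect_equal(e$spacer_length, 5L)

  s2 <- "CATTTTTGACGTACAAAAATG"  # A..T then C..G complement outward
  e2 <- extend_arms(s2, find_core_hits(s2, spec)[1, ], spec)
  expect_equal(e2$arm_length, 8L)
  expect_equal(e2$total_span, 21L)

  cspec <- ds_central_spec()
  s3 <- "CCGAAGACTATCCCCCCCCCATAGTCTTCAA"
  e3 <- extend_arms(s3, find_core_hits(s3, cspec)[1, ], cspec)
  expect_equal(e3$arm_length, 9L)
  expect_equal(e3$total_span, 27L)
})

test_that("the enumeration oracle handles palindromes and empty cases", {
  els <- enumerate_inverted_repeats("AAATTT", min_arm = 3, spacer_min = 0)
  expect_length(els, 1L)
  expect_equal(els[[1]]$arm_length, 3L)
  expect_equal(els[[1]]$left_start, 1L)

  expect_length(enumerate_inverted_repeats("ACGT", min_arm = 3, spacer_min = 0), 0L)
  expect_error(enumerate_inverted_repeats(strrep("A", 10001), 3, 0), "10 kb")
})

test_that("detection with extension agrees with exhaustive enumeration", {
  # Extended elements whose cores are exactly complementary must appear in
  # the exhaustive enumeration with identical arms and positions.
  set.seed(71)
  spec <- ds_terminal_spec()
  n_checked <- 0L
  for (i in 1:40) {
    s <- random_seq(300, at = 0.65)
    # plant one concrete core DS to guarantee hits in some sequences
    if (i %% 2 == 0) {
      pos <- sample(50:230, 1)
      core <- paste0("TTTTTG", random_seq(5, at = 0.5), "CAAAAA")
      substr(s, pos, pos + 16) <- core
    }
    hits <- find_core_hits(s, spec)
    if (!nrow(hits)) next
    enum <- enumerate_inverted_repeats(s, min_arm = 6, spacer_min = 5)
    for (k in seq_len(nrow(hits))) {
      e <- extend_arms(s, hits[k, ], spec)
      left_arm <- substr(s, e$left_start, e$left_end)
      right_arm <- substr(s, e$right_start, e$right_end)
      if (reverse_complement(left_arm) != right_arm) next  # imperfect core
      n_checked <- n_checked + 1L
      match <- Filter(function(x) {
        x$left_end == e$left_end && x$spacer_length == e$spacer_length
      }, enum)
      expect_length(match, 1L)
      expect_equal(match[[1]]$arm_length, e$arm_length)
      expect_equal(match[[1]]$left_start, e$left_start)
      expect_equal(match[[1]]$right_end, e$right_end)
    }
  }
  expect_gte(n_checked, 15L)
})

test_that("the template's three dyads are classified at their planted positions", {
  tpl <- default_cne_template()
  d <- classify_cne_dyads(tpl$template)
  el <- tpl$elements
  expect_equal(d$DSl$left_start, el$start[el$element_id == "DSl"])
  expect_equal(d$DSl$right_end, el$end[el$element_id == "DSl"])
  expect_equal(d$DSc$left_start, el$start[el$element_id == "DSc"])
  expect_equal(d$DSc$right_end, el$end[el$element_id == "DSc"])
  expect_equal(d$DSr$left_start, el$start[el$element_id == "DSr"])
  expect_equal(d$DSr$right_end, el$end[el$element_id == "DSr"])
  expect_equal(d$DSl$total_span, 17L)
  expect_equal(d$DSc$total_span, 27L)
})

test_that("ablating the central dyad removes only DSc", {
  tpl <- default_cne_template()
  s <- tpl$template
  el <- tpl$elements
  dsc_start <- el$start[el$element_id == "DSc"]
  substr(s, dsc_start, dsc_start + 8) <- "GGGGGGGGG"  # kill the left nonamer
  d <- classify_cne_dyads(s)
  expect_null(d$DSc)
  expect_false(is.null(d$DSl))
  expect_false(is.null(d$DSr))
})

test_that("classification is strand-symmetric", {
  tpl <- default_cne_template()$template
  L <- nchar(tpl)
  d <- classify_cne_dyads(tpl)
  dr <- classify_cne_dyads(reverse_complement(tpl))
  # DSl and DSr swap, coordinates mirror
  expect_equal(dr$DSl$left_start, L - d$DSr$right_end + 1L)
  expect_equal(dr$DSl$right_end, L - d$DSr$left_start + 1L)
  expect_equal(dr$DSr$left_start, L - d$DSl$right_end + 1L)
  # DSc maps onto itself (mutually reverse-complementary core pair)
  expect_equal(dr$DSc$left_start, L - d$DSc$right_end + 1L)
  expect_equal(dr$DSc$right_end, L - d$DSc$left_start + 1L)
})

test_that("degenerate-core fallbacks rescue the exceptional arm variants", {
  tpl <- default_cne_template()
  s <- tpl$template
  # convert both terminal dyads to the TTATTG/CAATAA variant (not covered by
  # the WTTWTG primary core)
  for (st in tpl$elements$start[tpl$elements$kind == "dyad"][c(1, 3)]) {
    substr(s, st, st + 5) <- "TTATTG"
    substr(s, st + 11, st + 16) <- "CAATAA"
  }
  expect_false(iupac_match("WTTWTG", "TTATTG"))
  d <- classify_cne_dyads(s)
  expect_false(is.null(d$DSl))
  expect_false(is.null(d$DSr))
  expect_true("DS_terminal_TTATTG" %in% attr(d, "fallback_used"))
})

test_that("overlap resolution keeps the longest arm and total spans stay >= 17", {
  fam <- simulate_family(family_spec(seed = 29))
  for (i in c(1, 10, 25)) {
    d <- classify_cne_dyads(fam$sequences[[i]])
    for (nm in c("DSl", "DSr")) {
      if (is.null(d[[nm]])) next
      expect_gte(d[[nm]]$total_span, 17L)
      expect_gte(d[[nm]]$arm_length, d[[nm]]$core_length)
    }
  }
})
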
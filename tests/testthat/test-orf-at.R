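test_that("a 92-codon construct yields a single 279-bp ORF", {
  set.seed(51)
  sense <- c("GCT", "GAA", "CTT", "ATC", "AAA", "TGG", "TAC", "CAT")
  body <- paste(sample(sense, 91, replace = TRUE), collapse = "")
  construct <- paste0("TAATAGTGATAA", "ATG", body, "TAA", "TGATAGTAA")
  orfs <- find_orfs(construct, min_len = 150)
  fwd <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$length, 279L)
  expect_equal(fwd$length %% 3, 0L)
})

test_that("sequences without a stop codon give no complete ORF", {
  expect_equal(nrow(find_orfs(strrep("A", 600), min_len = 150)), 0L)
  # but the truncated flag reports the open stretch
  tr <- find_orfs(paste0("ATG", strrep("AAA", 60)), min_len = 150,
                  include_truncated = TRUE)
  expect_true(all(tr$truncated))
  expect_equal(nrow(tr[tr$strand == "+", ]), 1L)
})

test_that("ORF sets are strand-symmetric", {
  set.seed(52)
  for (i in 1:5) {
    s <- random_seq(800, at = 0.55)
    L <- nchar(s)
    f <- find_orfs(s, min_len = 90)
    r <- find_orfs(reverse_complement(s), min_len = 90)
    # mirror r back onto s's coordinates; strands swap
    r_m <- data.frame(start = L - r$end + 1L, end = L - r$start + 1L,
                      strand = ifelse(r$strand == "+", "-", "+"))
    f_key <- sort(paste(f$start, f$end, f$strand))
    r_key <- sort(paste(r_m$start, r_m$end, r_m$strand))
    expect_identical(f_key, r_key)
  }
})

test_that("forward ORFs match the codon-walk oracle on random sequences", {
  set.seed(53)
  for (i in 1:3) {
    s <- random_seq(1000, at = 0.6)
    want <- oracle_orfs_fwd(s, min_len = 60)
    got <- find_orfs(s, min_len = 60)
    got <- got[got$strand == "+", ]
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(got$start), sort(want$start))
    expect_equal(sort(got$end), sort(want$end))
  }
})

test_that("overlap classification reproduces the published table relations", {
  cne <- genomic_interval("NC_001623", 132228, 132383)
  orf <- genomic_interval("NC_001623", 132109, 132387)
  expect_identical(overlap_classify(orf, cne), "orf_contains_region")

  eups_cne <- genomic_interval("NC_012639", 5241, 5395)
  eups_orf <- genomic_interval("NC_012639", 5295, 5465)
  expect_identical(overlap_classify(eups_orf, eups_cne), "partial")

  expect_identical(overlap_classify(genomic_interval("x", 1, 10),
                                    genomic_interval("x", 50, 60)), "none")
  expect_identical(overlap_classify(genomic_interval("x", 20, 30),
                                    genomic_interval("x", 10, 60)),
                   "region_contains_orf")
  expect_identical(overlap_classify(genomic_interval("x", 5, 9),
                                    genomic_interval("x", 5, 9)),
                   "orf_contains_region")
  expect_error(overlap_classify(genomic_interval("a", 1, 10),
                                genomic_interval("b", 1, 10)),
               "different sequences")
})

test_that("AT content follows its definition and is reverse-complement invariant", {
  expect_equal(at_content("ATAT"), 100)
  expect_equal(at_content("ACGT"), 50)
  expect_equal(at_content("ANT"), 100)   # N excluded from both sides
  expect_true(is.na(at_content("NNN")))

  set.seed(54)
  for (i in 1:20) {
    s <- random_seq(sample(10:500, 1), at = runif(1, 0.3, 0.7))
    expect_equal(at_content(s), at_content(reverse_complement(s)))
  }
})

test_that("AT enrichment applies the two-part AT-rich criterion", {
  st <- at_enrichment("ATATAT", "ACGTACGT")
  expect_true(st$is_at_rich)
  expect_gt(st$enrichment, 0)

  st2 <- at_enrichment("ACGTACGT", "ACGTACGT")
  expect_equal(st2$enrichment, 0)
  expect_false(st2$is_at_rich)

  # above background but not above 50% -> not AT-rich
  st3 <- at_enrichment("AACCGGCC", "CCGGCCGG")
  expect_false(st3$is_at_rich)
})

test_that("the region comparison table handles bounds errors row-wise", {
  seqs <- c(g1 = strrep("ACGT", 25), g2 = strrep("AT", 50))
  regions <- list(genomic_interval("g1", 1, 100),
                  genomic_interval("g2", 1, 10),
                  genomic_interval("g2", 90, 150))
  tab <- at_compare_table(seqs, regions)
  expect_equal(nrow(tab), 3L)  # two regions + mean row
  expect_equal(tab$enrichment[1], 0)
  expect_length(attr(tab, "errors"), 1L)
  expect_match(attr(tab, "errors"), "out of bounds")
})
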
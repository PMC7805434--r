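test_that("JASPAR parsing applies the pseudocount before row normalization", {
  p <- withr::local_tempfile(fileext = ".jaspar")
  write_lines_tsv(c(
    ">M1 testmotif",
    "A [ 8 0 ]",
    "C [ 0 8 ]",
    "G [ 0 0 ]",
    "T [ 0 0 ]"
  ), p)
  got <- parse_pfm(p, "jaspar", pseudocount = 1)
  expect_length(got, 1)
  m <- got[[1]]
  expect_equal(m$id, "M1")
  expect_equal(m$n_sequences, 8) # sum of first count row
  expect_equal(unname(m$matrix[1, ]), c(9, 1, 1, 1) / 12) # (8+1)/(8+4*1)
  expect_equal(unname(m$matrix[2, ]), c(1, 9, 1, 1) / 12)
  expect_equal(rowSums(m$matrix), rep(1, 2))

  # already probabilistic + zero pseudocount passes through unchanged
  probs <- matrix(c(0.7, 0.1, 0.1, 0.1, 0.25, 0.25, 0.25, 0.25),
    nrow = 2, byrow = TRUE
  )
  expect_equal(unname(pfm(probs, pseudocount = 0)$matrix), unname(probs))

  # zero row without pseudocount errors
  expect_error(pfm(matrix(0, 1, 4), pseudocount = 0), "zero")

  empty <- withr::local_tempfile()
  write_lines_tsv(character(), empty)
  expect_warning(out <- parse_pfm(empty, "jaspar"), "empty")
  expect_length(out, 0)
})

test_that("TRANSFAC flat files parse into the same PFM objects", {
  p <- withr::local_tempfile(fileext = ".dat")
  write_lines_tsv(c(
    "AC  M00001",
    "XX",
    "ID  V$TEST",
    "P0      A      C      G      T",
    "01      8      0      0      0      A",
    "02      0      8      0      0      C",
    "XX",
    "//"
  ), p)
  got <- parse_pfm(p, "transfac", pseudocount = 1)
  expect_length(got, 1)
  expect_equal(got[[1]]$id, "M00001")
  expect_equal(unname(got[[1]]$matrix[1, ]), c(9, 1, 1, 1) / 12)
  expect_equal(got[[1]]$length, 2)
})

test_that("uniform PFM on uniform background gives TBA = window count", {
  withr::local_seed(7)
  for (rep in 1:20) {
    L <- sample(20:200, 1)
    l <- sample(1:12, 1)
    expect_identical(tba(random_seq(L), uniform_pfm(l)), as.numeric(L - l + 1))
    expect_identical(normalize_tba(L - l + 1, L, l), 1)
  }
})

test_that("TBA matches the hand-evaluated single-position example", {
  p1 <- pfm(matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 1), pseudocount = 0)
  # each window: max(0.97/0.25, 0.01/0.25) = 3.88
  expect_equal(tba("AA", p1), 7.76)
  expect_equal(normalize_tba(tba("AA", p1), 2, 1), 3.88)
  # complementary base on the minus strand scores the A column too
  expect_equal(tba("TT", p1), 7.76)
  expect_error(tba("A", uniform_pfm(3)), "shorter than the motif")
  expect_error(tba("AXA", p1), "non-ACGTN")
  expect_error(normalize_tba(1, 2, 3), "L must be >=")
})

test_that("log-space TBA equals the direct-product oracle and is strand symmetric", {
  withr::local_seed(8)
  for (rep in 1:40) {
    s <- random_seq(sample(30:200, 1))
    p <- random_pfm(sample(2:12, 1))
    got <- tba(s, p)
    expect_equal(got, tba_oracle(s, p), tolerance = 1e-11)
    expect_identical(got, tba(revcomp_chr(s), p)) # bit-exact, same floating path
  }
})

test_that("N bases are neutral and raw TBA grows when appending bases", {
  p <- sharp12()
  sN <- paste0(strrep("N", 20), SHARP_CONSENSUS, strrep("N", 20))
  expect_equal(tba(sN, p), tba_oracle(sN, p), tolerance = 1e-11)
  withr::local_seed(9)
  s <- random_seq(60)
  for (extra in c("A", "C", "G", "T")) {
    expect_gt(tba(paste0(s, extra), p), tba(s, p))
  }
})

test_that("reference distributions are reproducible with monotone thresholds", {
  g <- tiny_genome(c(chr1 = 30000L))
  p <- random_pfm(6)
  r1 <- build_reference_distribution(p, g, 400, function(n) rep(80, n), seed = 12)
  r2 <- build_reference_distribution(p, g, 400, function(n) rep(80, n), seed = 12)
  expect_identical(r1, r2)
  r3 <- build_reference_distribution(p, g, 400, function(n) rep(80, n), seed = 13)
  expect_false(identical(r1$sample, r3$sample))
  # thresholds non-decreasing as the cutoff decreases
  expect_true(all(diff(unname(r1$thresholds)) >= 0))
  expect_true(all(r1$sample == sort(r1$sample)))
})

test_that("significance bins honor the >= boundary convention", {
  ref <- structure(
    list(
      pfm_id = "m", sample = 1:100 / 100,
      thresholds = c("5e-02" = 1.0, "1e-02" = 2.0, "1e-03" = 3.0, "1e-04" = 4.0, "1e-05" = 5.0),
      cutoffs = c(5e-02, 1e-02, 1e-03, 1e-04, 1e-05),
      n_regions = 100L, rng_seed = 1L
    ),
    class = "tba_reference"
  )
  expect_equal(significance(0.5, ref), "ns")
  expect_equal(significance(6.0, ref), "1e-05")
  expect_equal(significance(3.0, ref), "1e-03") # exactly at the threshold
  expect_equal(significance(c(1.5, 4.2), ref), c("5e-02", "1e-04"))
  expect_error(significance(1, ref, pfm_id = "other"), "not")
  expect_true(significant_at("1e-03", 1e-02))
  expect_false(significant_at("1e-02", 1e-03))
  expect_false(significant_at("ns", 5e-02))
})

test_that("region annotation applies the PFM quality filters", {
  g <- tiny_genome(c(chr1 = 30000L))
  cres <- genomic_intervals("chr1", c(1000, 5000), c(1500, 5600))
  sharp <- sharp12()
  weak <- sharp_pfm("ACGT", n_sites = 10, id = "tiny") # n_sequences < 50
  refs <- list(
    sharp12 = build_reference_distribution(sharp, g, 300, function(n) rep(550, n), seed = 3),
    tiny = build_reference_distribution(weak, g, 300, function(n) rep(550, n), seed = 3)
  )
  ann <- annotate_cres_with_tba(cres, g, list(sharp, weak), refs, min_seq = 50, max_frac = 1)
  expect_equal(nrow(ann), 2) # 2 CREs x 1 surviving PFM
  expect_true(all(ann$pfm_id == "sharp12"))
  ann_all <- annotate_cres_with_tba(cres, g, list(sharp, weak), refs, min_seq = 1, max_frac = 1)
  expect_equal(nrow(ann_all), 4) # full cross product

  # a PFM "enriched" in every region is dropped by the fraction filter:
  # force it by a reference whose thresholds sit below any score
  cheat <- refs$sharp12
  cheat$thresholds[] <- 0
  ann_drop <- annotate_cres_with_tba(cres, g, list(sharp), list(sharp12 = cheat),
    cutoff = 1e-05, min_seq = 1, max_frac = 0.5
  )
  expect_equal(nrow(ann_drop), 0)

  expect_error(
    annotate_cres_with_tba(genomic_intervals("chr1", 0, 99999), g, list(sharp), refs),
    "outside genome bounds"
  )
})
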
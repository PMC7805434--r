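test_that("replicate combination is the exact intersection of all tracks", {
  one <- combine_replicates(list(bed("chr1", 0, 100)))
  expect_equal(as_bed_frame(one), bed("chr1", 0, 100))
  two <- combine_replicates(list(bed("chr1", 0, 100), bed("chr1", 50, 150)))
  expect_equal(as_bed_frame(two), bed("chr1", 50, 100))
  three <- combine_replicates(list(
    bed("chr1", 0, 100), bed("chr1", 50, 150), bed("chr1", 80, 200)
  ))
  # per-base oracle: bases in all three tracks
  expect_setequal(
    gr_bases(three),
    Reduce(intersect, lapply(
      list(bed("chr1", 0, 100), bed("chr1", 50, 150), bed("chr1", 80, 200)),
      oracle_bases
    ))
  )
  expect_equal(as_bed_frame(three), bed("chr1", 80, 100))
  expect_error(combine_replicates(list()), "at least one")
})

test_that("experiment combination keeps >=2-experiment segments with max support", {
  two <- combine_experiments(list(bed("chr1", 0, 100), bed("chr1", 50, 150)))
  expect_equal(as_bed_frame(two), cbind(bed("chr1", 50, 100), n_support = 2L))

  single <- combine_experiments(list(bed("chr1", 0, 100)))
  expect_equal(as_bed_frame(single), cbind(bed("chr1", 0, 100), n_support = 1L))

  tracks <- list(bed("chr1", 0, 30), bed("chr1", 20, 60), bed("chr1", 50, 90))
  got <- combine_experiments(tracks)
  expect_equal(
    as_bed_frame(got),
    cbind(bed("chr1", c(20, 50), c(30, 60)), n_support = c(2L, 2L))
  )
  counts <- oracle_track_counts(tracks)
  expect_setequal(gr_bases(got), names(counts)[counts >= 2])
})

test_that("experiment and cell-line combiners match per-base counting oracles", {
  withr::local_seed(202)
  for (rep in 1:25) {
    k <- sample(2:6, 1)
    tracks <- lapply(seq_len(k), function(i) random_interval_set(sample(1:5, 1)))
    counts <- oracle_track_counts(lapply(tracks, function(df) {
      as_bed_frame(merge_intervals(df))
    }))
    got <- combine_experiments(tracks)
    expect_setequal(gr_bases(got), names(counts)[counts >= 2])
    full <- build_higher_consensus(tracks, min_labels = 2, full_extent = TRUE)
    expect_setequal(
      gr_bases(full),
      oracle_full_extent(lapply(tracks, function(df) as_bed_frame(merge_intervals(df))))
    )
    seg <- build_higher_consensus(tracks, min_labels = 2, full_extent = FALSE)
    expect_setequal(gr_bases(seg), names(counts)[counts >= 2])
  }
})

test_that("adding an experiment track never shrinks the combined cover", {
  withr::local_seed(303)
  for (rep in 1:10) {
    tracks <- lapply(1:3, function(i) random_interval_set(sample(1:4, 1)))
    base_cover <- gr_bases(combine_experiments(tracks))
    more <- c(tracks, list(random_interval_set(sample(1:4, 1))))
    expect_true(all(base_cover %in% gr_bases(combine_experiments(more))))
  }
})

test_that("higher-level consensus retains full extents of overlapping regions", {
  got <- build_higher_consensus(list(A = bed("chr1", 0, 100), B = bed("chr1", 50, 150)))
  expect_equal(as_bed_frame(got), cbind(bed("chr1", 0, 150), n_support = 2L))
  expect_equal(length(build_higher_consensus(list(A = bed("chr1", 0, 100)))), 0)
  expect_equal(
    length(build_higher_consensus(list(A = bed("chr1", 0, 30), B = bed("chr1", 100, 150)))),
    0
  )
})

test_that("element classification follows the promoter/enhancer/active rules", {
  tss <- data.frame(chrom = "chr1", start = 1200, end = 1201, gene = "g", score = 15)

  got <- classify_cell_line_elements(h3k4me3 = bed("chr1", 1000, 1400), tss = tss)
  expect_equal(as_bed_frame(got$promoter)[, 1:3], bed("chr1", 1000, 1400))

  # enhancer = H3K4me1 depleted of H3K4me3 and of TSS windows
  got <- classify_cell_line_elements(
    h3k4me3 = bed("chr1", 5400, 5600),
    h3k4me1 = bed("chr1", 5000, 6000),
    tss = tss[0, , drop = FALSE]
  )
  expect_equal(as_bed_frame(got$enhancer)[, 1:3], bed("chr1", c(5000, 5600), c(5400, 6000)))
  expect_equal(length(got$promoter), 0) # no TSS window to overlap
  expect_null(got$active_enhancer) # no H3K27ac track

  # whole enhancer region flagged active by >= 1 bp of H3K27ac
  got <- classify_cell_line_elements(
    h3k4me1 = bed("chr1", 5000, 5400),
    h3k27ac = bed("chr1", 5100, 5200),
    tss = tss[0, , drop = FALSE]
  )
  expect_equal(as_bed_frame(got$active_enhancer)[, 1:3], bed("chr1", 5000, 5400))

  # a TSS window removes enhancer bases within 1 kb of the TSS
  got <- classify_cell_line_elements(
    h3k4me1 = bed("chr1", 0, 5000),
    tss = tss
  )
  expect_equal(as_bed_frame(got$enhancer)[, 1:3], bed("chr1", c(0, 2200), c(200, 5000)))

  # sub-threshold TSS are ignored
  low <- data.frame(chrom = "chr1", start = 1200, end = 1201, gene = "g", score = 5)
  got <- classify_cell_line_elements(h3k4me3 = bed("chr1", 1000, 1400), tss = low)
  expect_equal(length(got$promoter), 0)

  expect_warning(out <- classify_cell_line_elements(tss = tss), "no H3K4me3 or H3K4me1")
  expect_equal(length(out), 0)
})

test_that("promoter and enhancer tracks are basepair-disjoint with active subset", {
  withr::local_seed(404)
  for (rep in 1:10) {
    k4me3 <- random_interval_set(4, chroms = "chr1", max_coord = 30000, max_len = 800)
    k4me1 <- random_interval_set(5, chroms = "chr1", max_coord = 30000, max_len = 1200)
    k27 <- random_interval_set(3, chroms = "chr1", max_coord = 30000, max_len = 600)
    tss <- data.frame(
      chrom = "chr1", start = sample(29000, 3), gene = letters[1:3], score = 20
    )
    tss$end <- tss$start + 1
    got <- classify_cell_line_elements(
      h3k4me3 = k4me3, h3k4me1 = k4me1, h3k27ac = k27, tss = tss
    )
    expect_equal(length(intersect(gr_bases(got$promoter), gr_bases(got$enhancer))), 0)
    # active enhancers are whole enhancer regions
    expect_true(all(as_bed_frame(got$active_enhancer)$name %in% as_bed_frame(got$enhancer)$name) ||
      all(gr_bases(got$active_enhancer) %in% gr_bases(got$enhancer)))
    # no enhancer base within the TSS windows
    win <- bed("chr1", pmax(0, tss$start - 1000), tss$start + 1000)
    expect_equal(length(intersect(gr_bases(got$enhancer), oracle_bases(win))), 0)
  }
})

test_that("the full pipeline composes the stages deterministically", {
  spec <- fixture_spec(
    chrom_lengths = c(chr1 = 300000L),
    cell_lines = data.frame(
      cell_line = c("X1", "X2"), tissue = c("lung", "lung"),
      stringsAsFactors = FALSE
    ),
    planted_elements = data.frame(
      element_class = "promoter", chrom = "chr1",
      start = 50000, end = 51000, cell_lines = "X1,X2",
      stringsAsFactors = FALSE
    ),
    seed = 5
  )
  d <- withr::local_tempdir()
  fx <- write_fixture(spec, d)
  peaks <- load_sample_sheet_peaks(fx$sample_sheet)
  tss <- read_tss(fx$tss)
  cons <- run_consensus_pipeline(peaks, tss, run_config())

  # shared promoter locus present at tissue level with support 2
  tis <- cons[cons$level == "tissue" & cons$element_class == "promoter", ]
  expect_equal(nrow(tis), 1)
  expect_equal(tis$n_support, 2L)
  expect_equal(c(tis$start, tis$end), c(50000, 51000))

  # determinism: identical inputs -> byte-identical BED outputs
  o1 <- file.path(d, "o1")
  o2 <- file.path(d, "o2")
  write_consensus_tracks(cons, o1)
  write_consensus_tracks(run_consensus_pipeline(peaks, tss, run_config()), o2)
  for (f in list.files(o1)) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)))
  }
})

test_that("single cell line yields no tissue/global tracks; H3K4me3-only yields promoters only", {
  spec <- fixture_spec(
    chrom_lengths = c(chr1 = 300000L),
    cell_lines = data.frame(
      cell_line = "solo", tissue = "lung",
      stringsAsFactors = FALSE
    ),
    planted_elements = data.frame(
      element_class = "promoter", chrom = "chr1",
      start = 50000, end = 51000, cell_lines = "solo",
      stringsAsFactors = FALSE
    ),
    seed = 6
  )
  d <- withr::local_tempdir()
  fx <- write_fixture(spec, d)
  cons <- run_consensus_pipeline(
    load_sample_sheet_peaks(fx$sample_sheet), read_tss(fx$tss), run_config()
  )
  expect_true(all(cons$level == "cell_line"))
  expect_true(all(cons$element_class == "promoter"))
})
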
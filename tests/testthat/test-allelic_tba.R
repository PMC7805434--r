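# shared mini-cohort used across allelic tests
make_cohort <- function(n_individuals = 50L, seed = 21L, snps = NULL,
                        motifs = NULL) {
  spec <- fixture_spec(
    chrom_lengths = c(chr1 = 50000L),
    cell_lines = data.frame(cell_line = "c", tissue = "t", stringsAsFactors = FALSE),
    planted_elements = data.frame(
      element_class = "promoter", chrom = "chr1", start = 1000, end = 2000,
      cell_lines = "c", stringsAsFactors = FALSE
    ),
    planted_motifs = motifs,
    n_individuals = n_individuals, seed = seed
  )
  genome <- make_genome(spec)
  vcf_path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  if (!is.null(snps)) make_vcf(spec, genome, snps, vcf_path)
  list(spec = spec, genome = genome, vcf = vcf_path)
}

test_that("a region with no variants yields the single reference allele", {
  co <- make_cohort()
  ref_base <- substr(as.character(co$genome[["chr1"]]), 40000, 40000)
  make_vcf(co$spec, co$genome, data.frame(
    chrom = "chr1", pos = 40000,
    alt = setdiff(c("A", "C", "G", "T"), ref_base)[1], hap_fraction = 0.5
  ), co$vcf)
  # variant lies far outside the region
  aset <- enumerate_alleles(genomic_intervals("chr1", 1000, 2000), co$genome, read_phased_vcf(co$vcf))
  expect_equal(nrow(aset$alleles), 1)
  expect_equal(aset$alleles$frequency, 1.0)
  expect_true(aset$alleles$is_reference)
  expect_equal(aset$total_haplotypes, 100)
  expect_equal(aset$alleles$sequence, aset$ref_sequence)
})

test_that("haplotype enumeration groups phased SNPs into alleles with exact frequencies", {
  co <- make_cohort(n_individuals = 2L)
  # pick an alt different from the reference base
  ref_base <- substr(as.character(co$genome[["chr1"]]), 1500, 1500)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  make_vcf(co$spec, co$genome, data.frame(
    chrom = "chr1", pos = 1500, alt = alt, hap_fraction = 0.5
  ), co$vcf)
  aset <- enumerate_alleles(genomic_intervals("chr1", 1000, 2000), co$genome, read_phased_vcf(co$vcf))
  # 4 haplotypes, SNP on exactly 2 -> two alleles at 0.5, both retained
  expect_equal(nrow(aset$alleles), 2)
  expect_equal(aset$alleles$frequency, c(0.5, 0.5))
  expect_equal(sum(aset$alleles$n_haplotypes), aset$total_haplotypes)
  expect_equal(sum(aset$alleles$is_reference), 1)
  alt_seq <- aset$alleles$sequence[!aset$alleles$is_reference]
  expect_equal(substr(alt_seq, 500, 500), alt) # 1-based offset of pos 1500 in [1000,2000)
})

test_that("rare alleles below the 1% threshold are dropped (strict inequality)", {
  co <- make_cohort(n_individuals = 100L) # 200 haplotypes; 1/200 = 0.005
  ref_base <- substr(as.character(co$genome[["chr1"]]), 1500, 1500)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  make_vcf(co$spec, co$genome, data.frame(
    chrom = "chr1", pos = 1500, alt = alt, hap_fraction = 1 / 200
  ), co$vcf)
  aset <- enumerate_alleles(genomic_intervals("chr1", 1000, 2000), co$genome, read_phased_vcf(co$vcf))
  expect_equal(nrow(aset$alleles), 1)
  expect_true(aset$alleles$is_reference)
  # exactly at the threshold is also excluded: 2/200 = 0.01
  make_vcf(co$spec, co$genome, data.frame(
    chrom = "chr1", pos = 1500, alt = alt, hap_fraction = 2 / 200
  ), co$vcf)
  aset <- enumerate_alleles(genomic_intervals("chr1", 1000, 2000), co$genome, read_phased_vcf(co$vcf))
  expect_equal(nrow(aset$alleles), 1)
})

test_that("unphased genotypes error by default and can be skipped", {
  co <- make_cohort(n_individuals = 2L)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    sprintf(
      "chr1\t1500\t.\t%s\tN\t.\tPASS\t.\tGT\t0/1\t0|0",
      substr(as.character(co$genome[["chr1"]]), 1500, 1500)
    )
  )
  lines <- sub("\tN\t", sprintf("\t%s\t", setdiff(
    c("A", "C", "G", "T"),
    substr(as.character(co$genome[["chr1"]]), 1500, 1500)
  )[1]), lines)
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, p)
  v <- read_phased_vcf(p)
  cre <- genomic_intervals("chr1", 1000, 2000)
  expect_error(enumerate_alleles(cre, co$genome, v), "unphased")
  expect_warning(
    aset <- enumerate_alleles(cre, co$genome, v, on_unphased = "skip"),
    "unphased"
  )
  expect_equal(nrow(aset$alleles), 1)
})

test_that("indel records are skipped with a counted warning", {
  co <- make_cohort(n_individuals = 2L)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    sprintf(
      "chr1\t1500\t.\t%s\t%sAA\t.\tPASS\t.\tGT\t0|1\t0|0",
      substr(as.character(co$genome[["chr1"]]), 1500, 1500),
      substr(as.character(co$genome[["chr1"]]), 1500, 1500)
    )
  )
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, p)
  expect_warning(
    aset <- enumerate_alleles(
      genomic_intervals("chr1", 1000, 2000), co$genome,
      read_phased_vcf(p)
    ),
    "non-SNP"
  )
  expect_equal(aset$n_skipped_indels, 1)
  expect_equal(nrow(aset$alleles), 1)
})

test_that("allele-specific motif creation yields fraction_supporting = 0.5 exactly", {
  # the genome carries a 4-mismatch (dead) copy of the consensus; four SNPs
  # in perfect linkage restore the full site on exactly half the haplotypes
  co <- make_cohort()
  planted <- plant_allelic_motif(co$genome, "chr1", at = 1401)
  co$genome <- planted$genome
  make_vcf(co$spec, co$genome, planted$snps, co$vcf)

  p <- sharp12()
  ref <- build_reference_distribution(p, co$genome, 800, function(n) rep(1000, n), seed = 4)
  aset <- enumerate_alleles(genomic_intervals("chr1", 1000, 2000), co$genome, read_phased_vcf(co$vcf))
  expect_equal(nrow(aset$alleles), 2) # 4 linked SNPs -> 2 haplotype alleles
  enr <- allelic_enrichment(aset, p, ref, cutoff = 1e-02)
  expect_identical(enr$fraction_supporting, 0.5)
  expect_equal(enr$n_common_alleles, 2)

  # looser cutoffs can only increase the supporting fraction
  fr <- vapply(c(1e-05, 1e-04, 1e-03, 1e-02, 5e-02), function(cf) {
    allelic_enrichment(aset, p, ref, cutoff = cf)$fraction_supporting
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("without variants the allelic result equals the reference-sequence result", {
  co <- make_cohort(n_individuals = 10L)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      sprintf("S%02d", 1:10)
    ), collapse = "\t")
  )
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, p)
  cre <- genomic_intervals("chr1", 1000, 2000)
  pf <- sharp12()
  ref <- build_reference_distribution(pf, co$genome, 400, function(n) rep(1000, n), seed = 4)
  aset <- enumerate_alleles(cre, co$genome, read_phased_vcf(p))
  enr <- allelic_enrichment(aset, pf, ref)
  ref_seq <- as.character(Biostrings::subseq(co$genome[["chr1"]], 1001, 2000))
  nt_ref <- tba_normalized(ref_seq, pf)
  expect_identical(enr$alleles$norm_tba, nt_ref)
  expect_identical(
    enr$fraction_supporting,
    as.numeric(significant_at(significance(nt_ref, ref), enr$cutoff))
  )
})
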
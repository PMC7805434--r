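#' Read a phased SNP VCF
#'
#' Thin wrapper around `vcfR` returning the fields needed for haplotype
#' enumeration.
#'
#' @param path Path to a VCF (4.x, plain or gzipped).
#' @return List of class `phased_vcf` with `fix` (data frame `chrom`, `pos`
#'   1-based, `ref`, `alt`), `gt` (variant x sample matrix of GT strings)
#'   and `samples`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) {
    fixm <- matrix(fixm, nrow = 1L, dimnames = list(NULL, names(fixm)))
  }
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- setdiff(colnames(gt), "FORMAT")
  gtm <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gtm))) gtm <- matrix(gtm, nrow = nrow(fix), dimnames = list(NULL, samples))
  out <- list(
    fix = data.frame(
      chrom = fix$CHROM, pos = as.numeric(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
    ),
    gt = gtm, samples = samples
  )
  class(out) <- "phased_vcf"
  out
}

#' Enumerate the haplotype alleles of a region
#'
#' Substitutes each haplotype's phased SNP alleles into the reference
#' sequence of the region, groups identical sequences into alleles, and
#' retains those with frequency strictly greater than `common_af_threshold`.
#' Records that are not pure SNPs (REF or any ALT longer than one base) are
#' skipped and counted. Multi-allelic SNPs are substituted per haplotype.
#'
#' @param cre A length-1 `GRanges` (or 1-row BED-style data frame).
#' @param genome `DNAStringSet`.
#' @param vcf A `phased_vcf` from [read_phased_vcf()].
#' @param common_af_threshold Frequency that an allele must strictly exceed
#'   to be retained (default 0.01).
#' @param on_unphased `"error"` (default) or `"skip"` (drop the record with
#'   a warning).
#' @return List of class `allele_set` with `cre_id`, `alleles` (data frame
#'   `sequence`, `frequency`, `n_haplotypes`, `is_reference`),
#'   `total_haplotypes`, `n_skipped_indels`, `ref_sequence`.
#' @export
enumerate_alleles <- function(cre, genome, vcf, common_af_threshold = 0.01,
                              on_unphased = c("error", "skip")) {
  on_unphased <- match.arg(on_unphased)
  gr <- .as_intervals(cre)
  stopifnot(length(gr) == 1L)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))
  start1 <- BiocGenerics::start(gr) # 1-based
  end1 <- BiocGenerics::end(gr)
  cre_id <- if (!is.null(names(gr)) && nzchar(names(gr)[1L])) {
    names(gr)[1L]
  } else {
    sprintf("%s:%d-%d", chrom, start1 - 1L, end1)
  }
  if (!chrom %in% names(genome)) stop(sprintf("chromosome '%s' absent from genome", chrom))
  ref_seq <- as.character(Biostrings::subseq(genome[[chrom]], start1, end1))

  fx <- vcf$fix
  in_region <- which(fx$chrom == chrom & fx$pos >= start1 & fx$pos <= end1)
  n_samp <- length(vcf$samples)
  total_hap <- 2L * n_samp

  n_indel <- 0L
  hap_seqs <- rep(ref_seq, total_hap)
  for (k in in_region) {
    alts <- strsplit(fx$alt[k], ",", fixed = TRUE)[[1L]]
    if (nchar(fx$ref[k]) != 1L || any(nchar(alts) != 1L) ||
      !all(c(fx$ref[k], alts) %in% DNA_BASES)) {
      n_indel <- n_indel + 1L
      next
    }
    off <- fx$pos[k] - start1 + 1L
    if (substr(ref_seq, off, off) != fx$ref[k]) {
      stop(sprintf(
        "VCF REF '%s' at %s:%d does not match the genome ('%s')",
        fx$ref[k], chrom, fx$pos[k], substr(ref_seq, off, off)
      ))
    }
    gts <- vcf$gt[k, vcf$samples]
    unphased <- grepl("/", gts, fixed = TRUE)
    if (any(unphased)) {
      if (on_unphased == "error") {
        stop(sprintf("unphased genotype at %s:%d (sample %s)", chrom, fx$pos[k], vcf$samples[which(unphased)[1L]]))
      }
      warning(sprintf("skipping unphased record at %s:%d", chrom, fx$pos[k]))
      next
    }
    parts <- strsplit(gts, "|", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) stop(sprintf("non-diploid genotype at %s:%d", chrom, fx$pos[k]))
    idx <- suppressWarnings(as.integer(unlist(parts))) # hap order: s1h1, s1h2, s2h1, ...
    if (anyNA(idx)) stop(sprintf("missing genotype at %s:%d", chrom, fx$pos[k]))
    carrier <- which(idx > 0L)
    for (h in carrier) {
      substr(hap_seqs[h], off, off) <- alts[idx[h]]
    }
  }
  if (n_indel > 0L) {
    warning(sprintf("%s: skipped %d non-SNP record(s)", cre_id, n_indel))
  }

  tab <- table(hap_seqs)
  alleles <- data.frame(
    sequence = names(tab),
    n_haplotypes = as.integer(tab),
    stringsAsFactors = FALSE
  )
  alleles$frequency <- alleles$n_haplotypes / total_hap
  alleles$is_reference <- alleles$sequence == ref_seq
  alleles <- alleles[order(-alleles$frequency, alleles$sequence), , drop = FALSE]
  stopifnot(abs(sum(alleles$frequency) - 1) < 1e-9)
  alleles <- alleles[alleles$frequency > common_af_threshold, , drop = FALSE]
  rownames(alleles) <- NULL
  out <- list(
    cre_id = cre_id,
    alleles = alleles[, c("sequence", "frequency", "n_haplotypes", "is_reference")],
    total_haplotypes = total_hap,
    n_skipped_indels = n_indel,
    ref_sequence = ref_seq
  )
  class(out) <- "allele_set"
  out
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf(
    "allele set %s: %d common allele(s) over %d haplotypes (%d non-SNP record(s) skipped)\n",
    x$cre_id, nrow(x$alleles), x$total_haplotypes, x$n_skipped_indels
  ))
  invisible(x)
}

#' Fraction of common alleles supporting a TBA enrichment
#'
#' Scores every retained (common) allele sequence of a region with the
#' normalized TBA and reports the share of distinct alleles significant at
#' `cutoff` against the PFM's reference distribution. Alleles differ from
#' the reference only through SNPs, so all share the same length and the
#' same reference distribution applies.
#'
#' @param allele_set An [enumerate_alleles()] result with >= 1 allele.
#' @param pfm A [pfm()].
#' @param ref The PFM's `tba_reference`.
#' @param bg A [background_model()].
#' @param cutoff P-value cutoff defining "significant".
#' @return List of class `allelic_enrichment` with `cre_id`, `pfm_id`,
#'   `n_common_alleles`, `fraction_supporting`, `cutoff`, and the per-allele
#'   table `alleles` (with `norm_tba` and `p_value_bin` columns).
#' @export
allelic_enrichment <- function(allele_set, pfm, ref, bg = background_model(),
                               cutoff = 1e-05) {
  stopifnot(inherits(allele_set, "allele_set"), inherits(pfm, "pfm"))
  al <- allele_set$alleles
  if (!nrow(al)) stop("allele set retained no common alleles")
  nt <- vapply(al$sequence, function(s) {
    normalize_tba(tba(s, pfm, bg), nchar(s), pfm$length)
  }, 0, USE.NAMES = FALSE)
  bins <- significance(nt, ref, pfm_id = pfm$id)
  al$norm_tba <- nt
  al$p_value_bin <- bins
  out <- list(
    cre_id = allele_set$cre_id,
    pfm_id = pfm$id,
    n_common_alleles = nrow(al),
    fraction_supporting = mean(significant_at(bins, cutoff)),
    cutoff = cutoff,
    alleles = al
  )
  class(out) <- "allelic_enrichment"
  out
}

#' @export
print.allelic_enrichment <- function(x, ...) {
  cat(sprintf(
    "%s x %s: %.3f of %d common allele(s) significant at %s\n",
    x$cre_id, x$pfm_id, x$fraction_supporting, x$n_common_alleles,
    .format_cutoff(x$cutoff)
  ))
  invisible(x)
}
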
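#' Construct a set of genomic intervals
#'
#' Builds a \link[GenomicRanges]{GRanges} from BED-style coordinates
#' (0-based start, exclusive end). All interval algebra in this package is
#' strand-blind: strand is set to \code{"*"}.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts (bp).
#' @param end Integer vector, 0-based exclusive ends (bp); must satisfy
#'   \code{0 <= start < end}.
#' @return A `GRanges` with lexicographically sorted seqlevels.
#' @examples
#' genomic_intervals("chr1", c(10, 15), c(20, 30))
#' @export
genomic_intervals <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(start) == 1L) start <- rep(start, n)
  if (length(end) == 1L) end <- rep(end, n)
  if (length(chrom) != n || length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length (or length 1)")
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf(
      "invalid interval(s) at position(s) %s: need 0 <= start < end",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr
}

#' Convert intervals back to a BED-style data frame
#'
#' @param gr A `GRanges`.
#' @return `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), plus any metadata columns.
#' @export
as_bed_frame <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(mc)) df <- cbind(df, mc)
  rownames(df) <- NULL
  df
}

.as_intervals <- function(x) {
  if (is.null(x)) return(GenomicRanges::GRanges())
  if (methods::is(x, "GRanges")) {
    BiocGenerics::strand(x) <- "*"
    return(x)
  }
  if (is.data.frame(x)) {
    return(genomic_intervals(x$chrom, x$start, x$end))
  }
  stop("expected a GRanges or a data.frame with chrom/start/end")
}

.sort_intervals <- function(gr) {
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Merge intervals into a minimal disjoint cover
#'
#' BEDTools-merge semantics with default parameters: overlapping and
#' book-ended intervals (where one ends exactly where the next starts) are
#' merged.
#'
#' @param intervals `GRanges` (or BED-style data frame).
#' @return Sorted, disjoint `GRanges` covering exactly the same bases.
#' @export
merge_intervals <- function(intervals) {
  gr <- .as_intervals(intervals)
  .sort_intervals(GenomicRanges::reduce(gr, ignore.strand = TRUE))
}

#' Basepair intersection of two interval sets
#'
#' @param a,b `GRanges` (or BED-style data frames).
#' @return Sorted, disjoint `GRanges` covering exactly the bases present in
#'   both `a` and `b`.
#' @export
intersect_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  lv <- sort(union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b)))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  merge_intervals(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Basepair subtraction of two interval sets
#'
#' @param a,b `GRanges` (or BED-style data frames).
#' @return Sorted, disjoint `GRanges` covering the bases of `a` not in `b`.
#' @export
subtract_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  lv <- sort(union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b)))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  merge_intervals(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Compare two region sets
#'
#' Computes the three statistics used to contrast regulatory-element
#' resources: the fraction of `a`'s regions with at least 1 bp of overlap in
#' `b`; the fraction of `a`'s covered bases that are also covered by `b`;
#' and the basepair Jaccard index of the two covers.
#'
#' @param a,b `GRanges` (or BED-style data frames). Regions of `a` are
#'   counted as given (not merged) for the region-overlap percentage.
#' @return A list of class `region_set_comparison` with fields
#'   `pct_a_overlapping_b`, `coverage_ratio_a`, `jaccard` and `degenerate`
#'   (`TRUE` when `a` is empty, in which case all statistics are 0).
#' @export
compare_region_sets <- function(a, b) {
  a <- .as_intervals(a)
  b <- .as_intervals(b)
  if (length(a) == 0) {
    out <- list(
      pct_a_overlapping_b = 0, coverage_ratio_a = 0, jaccard = 0,
      degenerate = TRUE
    )
    class(out) <- "region_set_comparison"
    return(out)
  }
  lv <- sort(union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b)))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  pct <- mean(GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0)
  ra <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  rb <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  bp_a <- sum(as.numeric(BiocGenerics::width(ra)))
  inter <- GenomicRanges::intersect(ra, rb, ignore.strand = TRUE)
  bp_i <- sum(as.numeric(BiocGenerics::width(inter)))
  uni <- GenomicRanges::reduce(c(ra, rb), ignore.strand = TRUE)
  bp_u <- sum(as.numeric(BiocGenerics::width(uni)))
  out <- list(
    pct_a_overlapping_b = pct,
    coverage_ratio_a = if (bp_a > 0) bp_i / bp_a else 0,
    jaccard = if (bp_u > 0) bp_i / bp_u else 0,
    degenerate = FALSE
  )
  class(out) <- "region_set_comparison"
  out
}

#' @export
print.region_set_comparison <- function(x, ...) {
  cat(sprintf(
    "region set comparison: %.1f%% of A regions overlap B; %.1f%% of A bases covered by B; Jaccard %.4f%s\n",
    100 * x$pct_a_overlapping_b, 100 * x$coverage_ratio_a, x$jaccard,
    if (isTRUE(x$degenerate)) " (degenerate: A empty)" else ""
  ))
  invisible(x)
}

#' Nearest gene of a single region
#'
#' Distance is the gap in bp between closest ends (0 when overlapping or
#' book-ended). Ties are broken deterministically: the gene with the smaller
#' (chrom, start) wins.
#'
#' @param cre A length-1 `GRanges` (or 1-row BED-style data frame).
#' @param genes `GRanges` with gene names in `names()` or a `gene`/`name`
#'   metadata column, or a data frame with `chrom`, `start`, `end`, `gene`.
#' @return List with `gene` (character, `NA` if no gene on the chromosome)
#'   and `distance` (bp, `NA` if no neighbor).
#' @export
nearest_gene <- function(cre, genes) {
  cre <- .as_intervals(cre)
  stopifnot(length(cre) == 1L)
  gg <- .gene_granges(genes)
  nearest_genes(cre, gg)[[1L]]
}

.gene_granges <- function(genes) {
  if (is.data.frame(genes)) {
    gg <- genomic_intervals(genes$chrom, genes$start, genes$end)
    names(gg) <- genes$gene
    return(gg)
  }
  gg <- .as_intervals(genes)
  if (is.null(names(gg))) {
    mc <- S4Vectors::mcols(gg)
    nm <- intersect(c("gene", "name"), colnames(mc))
    if (!length(nm)) stop("genes must carry names or a 'gene'/'name' column")
    names(gg) <- mc[[nm[1L]]]
  }
  gg
}

#' Nearest gene for each of several regions
#'
#' Vectorized version of [nearest_gene()].
#'
#' @inheritParams nearest_gene
#' @param cres `GRanges` of regions.
#' @return A list (one element per region) of `list(gene, distance)`.
#' @export
nearest_genes <- function(cres, genes) {
  cres <- .as_intervals(cres)
  gg <- .gene_granges(genes)
  lv <- sort(union(GenomeInfoDb::seqlevels(cres), GenomeInfoDb::seqlevels(gg)))
  GenomeInfoDb::seqlevels(cres) <- lv
  GenomeInfoDb::seqlevels(gg) <- lv
  lapply(seq_along(cres), function(i) {
    on_chr <- which(as.character(GenomeInfoDb::seqnames(gg)) ==
      as.character(GenomeInfoDb::seqnames(cres[i])))
    if (!length(on_chr)) {
      return(list(gene = NA_character_, distance = NA_real_))
    }
    d <- GenomicRanges::distance(cres[i], gg[on_chr], ignore.strand = TRUE)
    cand <- on_chr[which(d == min(d))]
    if (length(cand) > 1L) {
      cand <- cand[order(BiocGenerics::start(gg[cand]))][1L]
    }
    list(gene = names(gg)[cand], distance = as.numeric(min(d)))
  })
}
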
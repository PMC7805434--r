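#' Workflow configuration
#'
#' Collects the tunable parameters of the consensus/TBA workflow with their
#' conventional defaults: broad peaks are kept when their reported p-value is
#' below 0.01 (narrow peaks are not filtered), TSS annotations need a score
#' of at least 10, the promoter window is +/-1 kb around a TSS, regions must
#' be supported by at least two experiments (cell-line level) and two cell
#' lines (tissue/global level), TBA significance is binned at cutoffs from
#' 5e-2 down to 1e-5 with 1e-5 the default reporting cutoff, PFMs built from
#' fewer than 50 sites or enriched in more than half of the elements are
#' dropped, common alleles need frequency strictly above 1%, and reference
#' distributions use 100,000 background regions (use a smaller
#' `n_background_regions` for desk-scale runs).
#'
#' @param peak_format `"narrow"` or `"broad"`; which collection a run uses.
#' @param broad_pvalue_max Upper bound (exclusive) on broad-peak p-values.
#' @param tss_min_score Minimum TSS confidence score retained.
#' @param tss_window Half-width in bp of the window around a TSS.
#' @param min_experiments Experiments that must share a base at cell-line level.
#' @param min_cell_lines Cell lines that must share a base at tissue/global level.
#' @param tba_cutoffs Decreasing p-value cutoffs for significance bins.
#' @param default_cutoff Cutoff used when a single significance call is needed.
#' @param pfm_min_sequences Minimum number of sites behind a usable PFM.
#' @param pfm_max_cre_fraction Maximum fraction of elements a PFM may enrich.
#' @param common_af_threshold Allele-frequency threshold (strictly greater).
#' @param n_background_regions Background regions per reference distribution.
#' @param full_extent_union Whether tissue/global consensus retains full
#'   interval extents (`TRUE`, the default) or only the >=2-label segments.
#' @param seed Integer seed for all randomized steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(peak_format = "narrow",
                       broad_pvalue_max = 0.01,
                       tss_min_score = 10,
                       tss_window = 1000L,
                       min_experiments = 2L,
                       min_cell_lines = 2L,
                       tba_cutoffs = c(5e-02, 1e-02, 1e-03, 1e-04, 1e-05),
                       default_cutoff = 1e-05,
                       pfm_min_sequences = 50L,
                       pfm_max_cre_fraction = 0.50,
                       common_af_threshold = 0.01,
                       n_background_regions = 100000L,
                       full_extent_union = TRUE,
                       seed = 1L) {
  stopifnot(
    peak_format %in% c("narrow", "broad"),
    broad_pvalue_max > 0, broad_pvalue_max < 1,
    tss_window > 0, min_experiments >= 1, min_cell_lines >= 2,
    all(diff(tba_cutoffs) < 0), default_cutoff %in% tba_cutoffs,
    pfm_max_cre_fraction > 0, pfm_max_cre_fraction <= 1,
    common_af_threshold >= 0, common_af_threshold < 1,
    n_background_regions >= 1
  )
  cfg <- list(
    peak_format = peak_format,
    broad_pvalue_max = broad_pvalue_max,
    tss_min_score = tss_min_score,
    tss_window = as.integer(tss_window),
    min_experiments = as.integer(min_experiments),
    min_cell_lines = as.integer(min_cell_lines),
    tba_cutoffs = tba_cutoffs,
    default_cutoff = default_cutoff,
    pfm_min_sequences = as.integer(pfm_min_sequences),
    pfm_max_cre_fraction = pfm_max_cre_fraction,
    common_af_threshold = common_af_threshold,
    n_background_regions = as.integer(n_background_regions),
    full_extent_union = isTRUE(full_extent_union),
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

.format_cutoff <- function(x) formatC(x, format = "e", digits = 0)
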
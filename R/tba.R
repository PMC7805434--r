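# Base encoding: A=1 C=2 G=3 T=4 N=5 (N is neutral: ratio contribution 1).
.CODE_TABLE <- local({
  tb <- rep(NA_integer_, 256L)
  tb[utf8ToInt("A")] <- 1L; tb[utf8ToInt("a")] <- 1L
  tb[utf8ToInt("C")] <- 2L; tb[utf8ToInt("c")] <- 2L
  tb[utf8ToInt("G")] <- 3L; tb[utf8ToInt("g")] <- 3L
  tb[utf8ToInt("T")] <- 4L; tb[utf8ToInt("t")] <- 4L
  tb[utf8ToInt("N")] <- 5L; tb[utf8ToInt("n")] <- 5L
  tb
})
.COMPLEMENT <- c(4L, 3L, 2L, 1L, 5L)

.encode_seq <- function(seq) {
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet")) {
    seq <- as.character(seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  codes <- .CODE_TABLE[utf8ToInt(seq)]
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf(
      "sequence contains non-ACGTN character '%s' at position %d",
      substr(seq, bad, bad), bad
    ))
  }
  codes
}

# Per-window best-of-strands log ratios. Returns numeric vector of length
# L - l + 1 holding max(log fwd product, log rev product) per window.
.tba_window_logs <- function(codes, pfm, bg) {
  l <- pfm$length
  L <- length(codes)
  n_win <- L - l + 1L
  # log P(w_j, n)/P(b, n), with a 5th column of zeros so N is neutral
  lr_f <- cbind(log(pfm$matrix) - rep(log(bg), each = l), 0)
  # reverse-strand scan as a forward scan of the reverse-complemented matrix
  lr_r <- lr_f[l:1L, .COMPLEMENT, drop = FALSE]
  acc_f <- numeric(n_win)
  acc_r <- numeric(n_win)
  # forward sums accumulate j ascending, reverse sums j descending: this
  # ordering makes tba(s) and tba(revcomp(s)) follow identical floating paths
  for (j in seq_len(l)) {
    idx <- codes[j:(j + n_win - 1L)]
    acc_f <- acc_f + lr_f[j, idx]
    jr <- l - j + 1L
    idxr <- codes[jr:(jr + n_win - 1L)]
    acc_r <- acc_r + lr_r[jr, idxr]
  }
  pmax(acc_f, acc_r)
}

#' Total binding affinity (TBA) of a sequence for a PFM
#'
#' Sums, over every length-l window of the sequence, the larger of the two
#' strands' products of position-probability/background ratios:
#' \deqn{a_{rw} = \sum_{i=1}^{L-l+1} \max\left(\prod_{j=1}^{l}
#'   \frac{P(w_j, r_{i+j-1})}{P(b, r_{i+j-1})},\; \prod_{j=1}^{l}
#'   \frac{P(w_{l-j+1}, r'_{i+j-1})}{P(b, r'_{i+j-1})}\right)}
#' where \eqn{r'} is the complementary base. Window products are accumulated
#' in log space and re-exponentiated per window; the window terms are then
#' summed in ascending order, which makes the result independent of window
#' order and hence bit-identical under reverse complementation. `N` bases
#' contribute a neutral ratio of 1 on both strands.
#'
#' @param seq Nucleotide sequence (character, `DNAString`, or length-1
#'   `DNAStringSet`); ACGTN only; must be at least as long as the motif.
#' @param pfm A [pfm()].
#' @param bg A [background_model()].
#' @return Raw TBA (positive scalar on the natural scale).
#' @export
tba <- function(seq, pfm, bg = background_model()) {
  stopifnot(inherits(pfm, "pfm"))
  codes <- .encode_seq(seq)
  if (length(codes) < pfm$length) {
    stop(sprintf(
      "sequence length %d is shorter than the motif length %d",
      length(codes), pfm$length
    ))
  }
  w <- exp(.tba_window_logs(codes, pfm, bg))
  sum(sort(w))
}

#' Length-normalize a raw TBA score
#'
#' Raw TBA grows linearly with the number of scored windows, so scores are
#' divided by the window count \eqn{L - l + 1} (the mean per-window
#' affinity) before comparison across regions of different lengths.
#'
#' @param raw Raw TBA value(s).
#' @param L Sequence length (bp).
#' @param l Motif length (positions).
#' @return Normalized TBA.
#' @export
normalize_tba <- function(raw, L, l) {
  if (any(L < l)) stop("sequence length L must be >= motif length l")
  raw / (L - l + 1)
}

#' Normalized TBA of one sequence
#'
#' Convenience wrapper: `tba()` followed by [normalize_tba()].
#'
#' @inheritParams tba
#' @return Normalized TBA (positive scalar).
#' @export
tba_normalized <- function(seq, pfm, bg = background_model()) {
  codes_len <- if (methods::is(seq, "XString")) length(seq) else nchar(as.character(seq))
  normalize_tba(tba(seq, pfm, bg), codes_len, pfm$length)
}

.threshold_ranks <- function(n, cutoffs) {
  # Upper empirical quantile with the (k+1)/(n+1) plotting convention: the
  # threshold is the k-th order statistic with k the smallest rank whose
  # rank-based exceedance probability (n - k + 2)/(n + 1) is <= alpha.
  k <- ceiling(n + 2 - cutoffs * (n + 1))
  pmin(pmax(k, 1L), n)
}

#' Build a PFM-specific reference distribution of normalized TBA
#'
#' Samples `n_regions` regions uniformly over genome positions (chromosome
#' chosen proportionally to length) with lengths drawn from
#' `length_sampler`, scores each with the normalized TBA, and pre-computes
#' significance thresholds at the given p-value cutoffs as upper empirical
#' quantiles under the (k+1)/(n+1) convention. Regions containing `N` are
#' resampled up to a bounded retry budget. Fully reproducible from `seed`.
#'
#' @param pfm A [pfm()].
#' @param genome A `DNAStringSet` (names are chromosome names).
#' @param n_regions Number of background regions.
#' @param length_sampler Either a numeric vector of lengths to resample from
#'   (e.g. the observed CRE lengths) or a `function(n)` returning `n` lengths.
#' @param bg A [background_model()].
#' @param seed Integer seed.
#' @param cutoffs Decreasing p-value cutoffs for the threshold table.
#' @return Object of class `tba_reference` with fields `pfm_id`, `sample`
#'   (sorted normalized TBAs), `thresholds` (named by formatted cutoff),
#'   `cutoffs`, `n_regions`, `rng_seed`.
#' @export
build_reference_distribution <- function(pfm, genome, n_regions,
                                         length_sampler,
                                         bg = background_model(),
                                         seed = 1L,
                                         cutoffs = c(5e-02, 1e-02, 1e-03, 1e-04, 1e-05)) {
  stopifnot(inherits(pfm, "pfm"), n_regions >= 1L, all(diff(cutoffs) < 0))
  chrom_len <- Biostrings::width(genome)
  if (max(chrom_len) < pfm$length) stop("genome sequences shorter than the motif")
  draw_len <- if (is.function(length_sampler)) {
    length_sampler
  } else {
    lens <- as.numeric(length_sampler)
    stopifnot(all(lens >= pfm$length))
    function(n) sample(lens, n, replace = TRUE)
  }
  vals <- withr::with_seed(seed, {
    v <- numeric(n_regions)
    retries <- 0L
    max_retries <- 100L + 10L * n_regions
    i <- 1L
    while (i <= n_regions) {
      len <- max(pfm$length, round(draw_len(1L)))
      ok_chr <- which(chrom_len >= len)
      if (!length(ok_chr)) stop("no chromosome long enough for a sampled region length")
      chr <- if (length(ok_chr) == 1L) ok_chr else {
        sample(ok_chr, 1L, prob = chrom_len[ok_chr])
      }
      start <- sample.int(chrom_len[chr] - len + 1L, 1L)
      s <- as.character(Biostrings::subseq(genome[[chr]], start, start + len - 1L))
      if (grepl("N", s, fixed = TRUE)) {
        retries <- retries + 1L
        if (retries > max_retries) stop("region sampling exhausted retries on N-runs")
        next
      }
      v[i] <- normalize_tba(tba(s, pfm, bg), len, pfm$length)
      i <- i + 1L
    }
    v
  })
  sample_sorted <- sort(vals)
  ranks <- .threshold_ranks(n_regions, cutoffs)
  thresholds <- sample_sorted[ranks]
  names(thresholds) <- .format_cutoff(cutoffs)
  out <- list(
    pfm_id = pfm$id, sample = sample_sorted, thresholds = thresholds,
    cutoffs = cutoffs, n_regions = as.integer(n_regions),
    rng_seed = as.integer(seed)
  )
  class(out) <- "tba_reference"
  out
}

#' @export
print.tba_reference <- function(x, ...) {
  cat(sprintf(
    "TBA reference for %s: %d background regions, thresholds %s\n",
    x$pfm_id, x$n_regions,
    paste(sprintf("%s=%.4g", names(x$thresholds), x$thresholds), collapse = ", ")
  ))
  invisible(x)
}

#' Empirical significance bin of a normalized TBA score
#'
#' Returns, per score, the smallest p-value cutoff whose pre-computed
#' threshold is less than or equal to the score (a score exactly at a
#' threshold is significant at that cutoff), or `"ns"` when below all
#' thresholds.
#'
#' @param norm_tba Normalized TBA value(s).
#' @param ref A `tba_reference` from [build_reference_distribution()].
#' @param pfm_id Optional motif id; when given it must match `ref$pfm_id`.
#' @return Character vector of bins (formatted cutoffs, e.g. `"1e-05"`, or
#'   `"ns"`).
#' @export
significance <- function(norm_tba, ref, pfm_id = NULL) {
  stopifnot(inherits(ref, "tba_reference"))
  if (!is.null(pfm_id) && !identical(pfm_id, ref$pfm_id)) {
    stop(sprintf("reference was built for PFM '%s', not '%s'", ref$pfm_id, pfm_id))
  }
  cut_sorted <- sort(ref$cutoffs) # smallest first
  th <- ref$thresholds[.format_cutoff(cut_sorted)]
  vapply(norm_tba, function(v) {
    hit <- which(th <= v)
    if (length(hit)) .format_cutoff(cut_sorted[hit[1L]]) else "ns"
  }, "")
}

#' Is a significance bin significant at a given cutoff?
#'
#' @param bin Bins as returned by [significance()].
#' @param cutoff P-value cutoff.
#' @return Logical vector.
#' @export
significant_at <- function(bin, cutoff) {
  num <- suppressWarnings(as.numeric(bin))
  !is.na(num) & num <= cutoff
}

#' Score consensus regions against a PFM collection
#'
#' Extracts each region's reference sequence, computes normalized TBA and
#' its significance bin for every (region, PFM) pair, then applies the PFM
#' quality filters: motifs built from fewer than `min_seq` sites are
#' dropped, as are motifs enriched (significant at `cutoff`) in more than
#' `max_frac` of the regions.
#'
#' @param cres Consensus regions: `GRanges` or a BED-style data frame (the
#'   output of [run_consensus_pipeline()] works); a `name` column provides
#'   region ids.
#' @param genome `DNAStringSet`.
#' @param pfms List of [pfm()] objects.
#' @param refs Named list of `tba_reference`, keyed by PFM id.
#' @param bg A [background_model()].
#' @param cutoff Active p-value cutoff for the enrichment-fraction filter.
#' @param min_seq Minimum `n_sequences` per retained PFM.
#' @param max_frac Maximum fraction of regions a retained PFM may enrich.
#' @return `data.frame` with columns `cre_id`, `chrom`, `start`, `end`,
#'   `element_class` (when available), `pfm_id`, `norm_tba`, `p_value_bin`.
#' @export
annotate_cres_with_tba <- function(cres, genome, pfms, refs,
                                   bg = background_model(),
                                   cutoff = 1e-05,
                                   min_seq = 50L, max_frac = 0.50) {
  df <- if (methods::is(cres, "GRanges")) as_bed_frame(cres) else as.data.frame(cres)
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  if (!"name" %in% colnames(df)) {
    df$name <- sprintf("cre_%05d", seq_len(nrow(df)))
  }
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  bad <- which(!(df$chrom %in% names(genome)) | df$end > chrom_len[df$chrom] | df$start < 0)
  if (length(bad)) {
    stop(sprintf(
      "region(s) outside genome bounds: %s",
      paste(utils::head(df$name[bad], 5), collapse = ", ")
    ))
  }
  keep_pfms <- Filter(function(p) p$n_sequences >= min_seq, pfms)
  seqs <- vapply(seq_len(nrow(df)), function(i) {
    as.character(Biostrings::subseq(genome[[df$chrom[i]]], df$start[i] + 1L, df$end[i]))
  }, "")
  rows <- lapply(keep_pfms, function(p) {
    ref <- refs[[p$id]]
    if (is.null(ref)) stop(sprintf("no reference distribution for PFM '%s'", p$id))
    nt <- vapply(seqs, function(s) {
      normalize_tba(tba(s, p, bg), nchar(s), p$length)
    }, 0, USE.NAMES = FALSE)
    data.frame(
      cre_id = df$name, chrom = df$chrom, start = df$start, end = df$end,
      element_class = if ("element_class" %in% colnames(df)) df$element_class else NA_character_,
      pfm_id = p$id, norm_tba = nt,
      p_value_bin = significance(nt, ref),
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(
      cre_id = character(), chrom = character(), start = numeric(),
      end = numeric(), element_class = character(), pfm_id = character(),
      norm_tba = numeric(), p_value_bin = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  # enrichment-fraction filter
  frac <- vapply(split(significant_at(out$p_value_bin, cutoff), out$pfm_id), mean, 0)
  drop_ids <- names(frac)[frac > max_frac]
  out <- out[!(out$pfm_id %in% drop_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}
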
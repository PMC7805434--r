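#' Filter peaks by their reported p-value
#'
#' Retains exactly the peaks whose reported p-value \eqn{10^{-x}} (with
#' \eqn{x} the stored \eqn{-\log_{10} p}) is strictly smaller than `alpha`.
#' Input order is preserved.
#'
#' @param peaks Peak `data.frame` (see [read_peaks()]) carrying a
#'   `neg_log10_p` column.
#' @param alpha P-value threshold in (0, 1).
#' @return The retained rows of `peaks`.
#' @export
filter_peaks_by_pvalue <- function(peaks, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!nrow(peaks)) return(peaks)
  if (!"neg_log10_p" %in% colnames(peaks)) {
    stop("peaks carry no 'neg_log10_p' column; cannot filter by p-value")
  }
  if (anyNA(peaks$neg_log10_p)) {
    stop(sprintf(
      "%d peak(s) have no reported p-value (-1 sentinel); cannot apply the p-value filter",
      sum(is.na(peaks$neg_log10_p))
    ))
  }
  keep <- 10^(-peaks$neg_log10_p) < alpha
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.check_tracks <- function(tracks, what) {
  if (length(tracks) == 0L) stop(sprintf("need at least one %s track", what))
  lapply(tracks, merge_intervals)
}

#' Combine replicate tracks by intersection
#'
#' One replicate passes through (merged); two or more are combined by exact
#' basepair intersection of all of them.
#'
#' @param replicate_tracks List of interval sets (`GRanges` or BED frames).
#' @return Sorted, disjoint `GRanges`.
#' @export
combine_replicates <- function(replicate_tracks) {
  tracks <- .check_tracks(replicate_tracks, "replicate")
  Reduce(intersect_intervals, tracks)
}

.coverage_granges <- function(tracks) {
  # tracks: list of reduced GRanges. Returns coverage RleList over the union
  # of seqlevels, each track contributing at most 1 per base.
  lv <- sort(unique(unlist(lapply(tracks, GenomeInfoDb::seqlevels))))
  tracks <- lapply(tracks, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  all <- do.call(c, unname(tracks))
  list(cov = GenomicRanges::coverage(all), tracks = tracks, all = all)
}

.slice_granges <- function(cov, lower) {
  sl <- IRanges::slice(cov, lower = lower, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sl)
  .sort_intervals(gr)
}

#' Combine experiment tracks of one marker
#'
#' With a single experiment the track passes through with support 1. With
#' several, bases covered by at least two distinct experiments are the
#' seeds; the output is the merge of maximal seed runs, and each region's
#' support is the maximum number of distinct experiments covering any of its
#' bases.
#'
#' @param experiment_tracks List of interval sets, one per experiment.
#' @param min_experiments Minimum distinct experiments per seed base.
#' @return `GRanges` with an `n_support` metadata column.
#' @export
combine_experiments <- function(experiment_tracks, min_experiments = 2L) {
  tracks <- .check_tracks(experiment_tracks, "experiment")
  if (length(tracks) == 1L) {
    out <- tracks[[1L]]
    if (length(out)) S4Vectors::mcols(out)$n_support <- 1L else S4Vectors::mcols(out)$n_support <- integer()
    return(out)
  }
  cv <- .coverage_granges(tracks)
  out <- .slice_granges(cv$cov, lower = min_experiments)
  if (!length(out)) {
    S4Vectors::mcols(out)$n_support <- integer()
    return(out)
  }
  S4Vectors::mcols(out)$n_support <- .max_coverage_in(cv$cov, out)
  out
}

.max_coverage_in <- function(cov, regions) {
  vapply(seq_along(regions), function(i) {
    chr <- as.character(GenomeInfoDb::seqnames(regions[i]))
    v <- IRanges::Views(
      cov[[chr]],
      BiocGenerics::start(regions[i]), BiocGenerics::end(regions[i])
    )
    as.integer(max(IRanges::viewMaxs(v)))
  }, integer(1))
}

#' Build a tissue or global consensus from per-label tracks
#'
#' Bases covered by at least `min_labels` distinct labels (cell lines) seed
#' the consensus. By default every input interval containing a seed base is
#' retained and the union of their full extents is merged; with
#' `full_extent = FALSE` only the merged seed segments themselves are
#' returned. Support is the number of distinct labels contributing intervals
#' to each output region.
#'
#' @param per_label_tracks Named list, label -> interval set.
#' @param min_labels Minimum number of distinct labels per seed base.
#' @param full_extent Retain full interval extents (default) or seed
#'   segments only.
#' @return `GRanges` with an `n_support` metadata column.
#' @export
build_higher_consensus <- function(per_label_tracks, min_labels = 2L,
                                   full_extent = TRUE) {
  tracks <- .check_tracks(per_label_tracks, "label")
  cv <- .coverage_granges(tracks)
  seeds <- .slice_granges(cv$cov, lower = min_labels)
  if (!length(seeds)) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$n_support <- integer()
    return(out)
  }
  if (full_extent) {
    keep <- lapply(cv$tracks, function(g) {
      g[GenomicRanges::countOverlaps(g, seeds, ignore.strand = TRUE) > 0]
    })
    out <- merge_intervals(do.call(c, unname(keep)))
  } else {
    out <- seeds
  }
  support <- vapply(seq_along(out), function(i) {
    sum(vapply(cv$tracks, function(g) {
      any(GenomicRanges::countOverlaps(g, out[i], ignore.strand = TRUE) > 0)
    }, logical(1)))
  }, integer(1))
  S4Vectors::mcols(out)$n_support <- support
  out
}

#' Classify cell-line consensus tracks into regulatory elements
#'
#' Promoters are whole H3K4me3 consensus regions overlapping a window of
#' +/- `tss_window` bp around a retained TSS. Enhancers are H3K4me1 regions
#' basepair-depleted of all H3K4me3 regions and of all TSS windows. Active
#' enhancers are the enhancer regions overlapped (>= 1 bp) by an H3K27ac
#' region, retained whole. An element class is only emitted when its
#' required marker(s) are present.
#'
#' @param h3k4me3,h3k4me1,h3k27ac Marker consensus tracks (`GRanges`, with
#'   optional `n_support` column) or `NULL` when the marker is unavailable.
#' @param tss TSS `data.frame` (see [read_tss()]).
#' @param tss_min_score Minimum TSS score retained.
#' @param tss_window Window half-width in bp around each TSS.
#' @return Named list with any of `promoter`, `enhancer`, `active_enhancer`
#'   (`GRanges` with `n_support`); empty list (with a warning) when no
#'   marker is present.
#' @export
classify_cell_line_elements <- function(h3k4me3 = NULL, h3k4me1 = NULL,
                                        h3k27ac = NULL, tss,
                                        tss_min_score = 10,
                                        tss_window = 1000L) {
  if (is.null(h3k4me3) && is.null(h3k4me1)) {
    warning("no H3K4me3 or H3K4me1 track: no elements can be classified")
    return(list())
  }
  tss <- tss[tss$score >= tss_min_score, , drop = FALSE]
  windows <- if (nrow(tss)) {
    genomic_intervals(tss$chrom, pmax(0, tss$start - tss_window), tss$start + tss_window)
  } else {
    GenomicRanges::GRanges()
  }
  out <- list()
  if (!is.null(h3k4me3)) {
    k4me3 <- .with_support(h3k4me3)
    hit <- GenomicRanges::countOverlaps(k4me3, windows, ignore.strand = TRUE) > 0
    out$promoter <- .sort_intervals(k4me3[hit])
  }
  if (!is.null(h3k4me1)) {
    k4me1 <- .with_support(h3k4me1)
    drop <- merge_intervals(c(
      if (is.null(h3k4me3)) GenomicRanges::GRanges() else .strip_mcols(.as_intervals(h3k4me3)),
      .strip_mcols(windows)
    ))
    enh <- subtract_intervals(.strip_mcols(k4me1), drop)
    S4Vectors::mcols(enh)$n_support <- .inherit_support(enh, k4me1)
    out$enhancer <- enh
    if (!is.null(h3k27ac)) {
      ac <- .as_intervals(h3k27ac)
      hit <- GenomicRanges::countOverlaps(enh, ac, ignore.strand = TRUE) > 0
      out$active_enhancer <- enh[hit]
    }
  }
  out
}

.strip_mcols <- function(gr) {
  S4Vectors::mcols(gr) <- NULL
  gr
}

.with_support <- function(x) {
  gr <- .as_intervals(x)
  if (!"n_support" %in% colnames(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$n_support <- rep(1L, length(gr))
  }
  .sort_intervals(gr)
}

.inherit_support <- function(fragments, sources) {
  if (!length(fragments)) return(integer())
  hits <- GenomicRanges::findOverlaps(fragments, sources, ignore.strand = TRUE)
  sup <- rep(NA_integer_, length(fragments))
  sup[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(sources)$n_support[S4Vectors::subjectHits(hits)]
  sup[is.na(sup)] <- 1L
  sup
}

#' Run the full consensus pipeline
#'
#' Composes, per peak format: the broad-peak p-value filter, replicate
#' intersection, >=2-experiment combination, element classification per cell
#' line, and tissue/global consensus over cell lines. Narrow and broad peak
#' collections are processed separately; only the format named in `config`
#' is used.
#'
#' @param peaks Peak `data.frame` with metadata columns `marker`,
#'   `peak_format`, `experiment_id`, `replicate_id`, `cell_line`, `tissue`
#'   (see [load_sample_sheet_peaks()]).
#' @param tss TSS `data.frame` (see [read_tss()]).
#' @param config A [run_config()].
#' @return `data.frame` of consensus regions with columns `level`, `label`,
#'   `element_class`, `peak_format`, `chrom`, `start` (0-based), `end`,
#'   `name`, `n_support`, sorted within each track.
#' @export
run_consensus_pipeline <- function(peaks, tss, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  peaks <- peaks[peaks$peak_format == config$peak_format, , drop = FALSE]
  if (config$peak_format == "broad" && nrow(peaks)) {
    peaks <- filter_peaks_by_pvalue(peaks, config$broad_pvalue_max)
  }
  cell_lines <- unique(peaks$cell_line)
  tissue_of <- vapply(cell_lines, function(cl) peaks$tissue[peaks$cell_line == cl][1L], "")

  # cell-line level: per marker, replicates -> experiments -> classification
  per_cell <- lapply(cell_lines, function(cl) {
    pk_cl <- peaks[peaks$cell_line == cl, , drop = FALSE]
    marker_tracks <- lapply(c("H3K4me1", "H3K4me3", "H3K27ac"), function(mk) {
      pk <- pk_cl[pk_cl$marker == mk, , drop = FALSE]
      if (!nrow(pk)) return(NULL)
      exps <- unique(pk$experiment_id)
      exp_tracks <- lapply(exps, function(ex) {
        pe <- pk[pk$experiment_id == ex, , drop = FALSE]
        reps <- unique(pe$replicate_id)
        rep_tracks <- lapply(reps, function(rp) {
          genomic_intervals(
            pe$chrom[pe$replicate_id == rp],
            pe$start[pe$replicate_id == rp],
            pe$end[pe$replicate_id == rp]
          )
        })
        combine_replicates(rep_tracks)
      })
      combine_experiments(exp_tracks, min_experiments = config$min_experiments)
    })
    names(marker_tracks) <- c("H3K4me1", "H3K4me3", "H3K27ac")
    suppressWarnings(classify_cell_line_elements(
      h3k4me3 = marker_tracks$H3K4me3,
      h3k4me1 = marker_tracks$H3K4me1,
      h3k27ac = marker_tracks$H3K27ac,
      tss = tss,
      tss_min_score = config$tss_min_score,
      tss_window = config$tss_window
    ))
  })
  names(per_cell) <- cell_lines

  rows <- list()
  add <- function(gr, level, label, class) {
    if (is.null(gr) || !length(gr)) return()
    df <- as_bed_frame(.sort_intervals(gr))
    df$name <- .region_names(level, label, class, nrow(df))
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, label = label, element_class = class,
      peak_format = config$peak_format,
      df[, c("chrom", "start", "end", "name")],
      n_support = df$n_support,
      stringsAsFactors = FALSE
    )
  }

  for (cl in cell_lines) {
    for (class in names(per_cell[[cl]])) add(per_cell[[cl]][[class]], "cell_line", cl, class)
  }

  classes <- c("promoter", "enhancer", "active_enhancer")
  higher <- function(labels, level, label_name) {
    for (class in classes) {
      tracks <- Filter(Negate(is.null), lapply(labels, function(cl) per_cell[[cl]][[class]]))
      tracks <- Filter(length, tracks)
      if (length(tracks) < 1L) next
      cons <- build_higher_consensus(
        lapply(tracks, .strip_mcols),
        min_labels = config$min_cell_lines,
        full_extent = config$full_extent_union
      )
      add(cons, level, label_name, class)
    }
  }
  for (ts in unique(tissue_of)) higher(cell_lines[tissue_of == ts], "tissue", ts)
  if (length(cell_lines)) higher(cell_lines, "global", "global")

  if (!length(rows)) {
    return(data.frame(
      level = character(), label = character(), element_class = character(),
      peak_format = character(), chrom = character(), start = numeric(),
      end = numeric(), name = character(), n_support = integer(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.region_names <- function(level, label, class, n) {
  if (n == 0L) return(character())
  sprintf("%s:%s:%s:%05d", level, label, class, seq_len(n))
}

#' Write consensus pipeline output as one BED file per track
#'
#' Each (level, label, element_class, peak_format) track becomes one
#' headerless BED file `level.label.class.format.bed` with columns chrom,
#' start, end, name, n_support.
#'
#' @param consensus Output of [run_consensus_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_consensus_tracks <- function(consensus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  key <- paste(consensus$level, consensus$label, consensus$element_class,
    consensus$peak_format,
    sep = "."
  )
  paths <- character()
  for (k in unique(key)) {
    df <- consensus[key == k, c("chrom", "start", "end", "name", "n_support"), drop = FALSE]
    p <- file.path(dir, paste0(k, ".bed"))
    write_bed(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
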
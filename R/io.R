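#' Read an ENCODE narrowPeak or broadPeak file
#'
#' narrowPeak is BED6+4 (signalValue, pValue, qValue, peak) and broadPeak is
#' BED6+3 (signalValue, pValue, qValue); the pValue column holds
#' \eqn{-\log_{10}(p)} with \code{-1} meaning "not reported" (stored as
#' `NA`). Coordinates are kept exactly as on disk (0-based half-open).
#'
#' @param path Path to a tab-separated peak file.
#' @param peak_format `"narrow"` or `"broad"`.
#' @return `data.frame`, one row per peak, sorted by (chrom, start, end),
#'   with columns `chrom`, `start`, `end`, `name`, `score`, `strand`,
#'   `signal_value`, `neg_log10_p`, `neg_log10_q` and (narrow only) `peak`.
#' @export
read_peaks <- function(path, peak_format = c("narrow", "broad")) {
  peak_format <- match.arg(peak_format)
  ncol_req <- if (peak_format == "narrow") 10L else 9L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(.empty_peak_frame(peak_format))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != ncol_req)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d has %d fields, expected %d for %sPeak",
      path, bad[1L], nfield[bad[1L]], ncol_req, peak_format
    ))
  }
  m <- matrix(unlist(fields), ncol = ncol_req, byrow = TRUE)
  num <- function(j, what) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("%s: line %d has non-numeric %s '%s'", path, bad[1L], what, m[bad[1L], j]))
    }
    v
  }
  start <- num(2L, "start")
  end <- num(3L, "end")
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf(
      "%s: line %d has start >= end (%s >= %s)",
      path, bad[1L], m[bad[1L], 2L], m[bad[1L], 3L]
    ))
  }
  nlp <- num(8L, "-log10 p-value")
  nlp[nlp == -1] <- NA_real_
  if (any(nlp < 0, na.rm = TRUE)) {
    stop(sprintf("%s: negative -log10 p-value other than the -1 sentinel", path))
  }
  nlq <- num(9L, "-log10 q-value")
  nlq[nlq == -1] <- NA_real_
  df <- data.frame(
    chrom = m[, 1L],
    start = start,
    end = end,
    name = m[, 4L],
    score = num(5L, "score"),
    strand = m[, 6L],
    signal_value = num(7L, "signal value"),
    neg_log10_p = nlp,
    neg_log10_q = nlq,
    stringsAsFactors = FALSE
  )
  if (peak_format == "narrow") df$peak <- num(10L, "peak offset")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_peak_frame <- function(peak_format) {
  df <- data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    name = character(), score = numeric(), strand = character(),
    signal_value = numeric(), neg_log10_p = numeric(),
    neg_log10_q = numeric(), stringsAsFactors = FALSE
  )
  if (peak_format == "narrow") df$peak <- numeric()
  df
}

#' Read a scored TSS BED file
#'
#' Expects single-base features (end == start + 1) with the gene identifier
#' in the name column and a confidence score in the score column.
#'
#' @param path Path to a BED5/BED6 file.
#' @param min_score Optional score filter; rows with score below it are
#'   dropped (the conventional cutoff is 10).
#' @return `data.frame` with columns `chrom`, `start` (0-based TSS
#'   position), `end`, `gene`, `score`.
#' @export
read_tss <- function(path, min_score = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      gene = character(), score = numeric(), stringsAsFactors = FALSE
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield < 5L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, expected >= 5", path, bad[1L], nfield[bad[1L]]))
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.numeric(vapply(fields, `[`, "", 2L)),
    end = as.numeric(vapply(fields, `[`, "", 3L)),
    gene = vapply(fields, `[`, "", 4L),
    score = as.numeric(vapply(fields, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$score))
  if (length(bad)) stop(sprintf("%s: line %d has non-numeric coordinates or score", path, bad[1L]))
  bad <- which(df$end != df$start + 1)
  if (length(bad)) {
    stop(sprintf("%s: line %d is not a single-base TSS (end != start + 1)", path, bad[1L]))
  }
  if (!is.null(min_score)) df <- df[df$score >= min_score, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a plain BED3+ file as intervals
#'
#' @param path Path to a tab-separated, headerless BED file.
#' @return `GRanges`; columns 4 and 5, when present, become `name` and
#'   `score` metadata columns.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield < 3L)
  if (length(bad)) {
    stop(sprintf("%s: line %d has %d fields, expected >= 3", path, bad[1L], nfield[bad[1L]]))
  }
  gr <- genomic_intervals(
    vapply(fields, `[`, "", 1L),
    as.numeric(vapply(fields, `[`, "", 2L)),
    as.numeric(vapply(fields, `[`, "", 3L))
  )
  if (all(nfield >= 4L)) S4Vectors::mcols(gr)$name <- vapply(fields, `[`, "", 4L)
  if (all(nfield >= 5L)) {
    S4Vectors::mcols(gr)$score <- as.numeric(vapply(fields, `[`, "", 5L))
  }
  gr
}

#' Write intervals as a BED file
#'
#' Tab-separated, no header, LF line endings; coordinates written 0-based
#' half-open. Metadata columns (or `extra`) are appended after chrom, start,
#' end.
#'
#' @param x `GRanges` or BED-style data frame (`chrom`, `start`, `end`, ...).
#' @param path Output path.
#' @param columns Optional character vector selecting/ordering the extra
#'   columns to write after the first three.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, columns = NULL) {
  df <- if (methods::is(x, "GRanges")) as_bed_frame(x) else as.data.frame(x)
  stopifnot(all(c("chrom", "start", "end") %in% colnames(df)))
  extra <- setdiff(colnames(df), c("chrom", "start", "end"))
  if (!is.null(columns)) extra <- columns
  df <- df[, c("chrom", "start", "end", extra), drop = FALSE]
  fmt <- function(v) {
    if (is.numeric(v)) {
      ifelse(v == floor(v) & is.finite(v), sprintf("%.0f", v), as.character(v))
    } else {
      as.character(v)
    }
  }
  cols <- lapply(df, fmt)
  lines <- do.call(paste, c(cols, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sample sheet describing peak files
#'
#' @param path Tab-separated file with a header row and columns `path`,
#'   `marker`, `format`, `experiment`, `replicate`, `cell_line`, `tissue`.
#' @return `data.frame` with those columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("path", "marker", "format", "experiment", "replicate", "cell_line", "tissue")
  missing <- setdiff(req, colnames(df))
  if (length(missing)) {
    stop(sprintf("sample sheet %s is missing column(s): %s", path, paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(df$marker), c("H3K4me1", "H3K4me3", "H3K27ac"))
  if (length(bad)) {
    stop(sprintf("sample sheet %s has unknown marker(s): %s", path, paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(df$format), c("narrow", "broad"))
  if (length(bad)) {
    stop(sprintf("sample sheet %s has unknown format(s): %s", path, paste(bad, collapse = ", ")))
  }
  df
}

#' Load the peaks referenced by a sample sheet
#'
#' Reads every file listed in the sheet and binds the per-file peak tables
#' with the sheet's metadata columns attached.
#'
#' @param sheet Sample sheet data frame from [read_sample_sheet()], or a path.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved (defaults to the sheet's own directory when `sheet` is a path).
#' @return `data.frame` of peaks with metadata columns `marker`,
#'   `peak_format`, `experiment_id`, `replicate_id`, `cell_line`, `tissue`.
#' @export
load_sample_sheet_peaks <- function(sheet, base_dir = NULL) {
  if (is.character(sheet)) {
    if (is.null(base_dir)) base_dir <- dirname(sheet)
    sheet <- read_sample_sheet(sheet)
  }
  if (is.null(base_dir)) base_dir <- "."
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, p)
    pk <- read_peaks(p, peak_format = sheet$format[i])
    pk <- pk[, c("chrom", "start", "end", "neg_log10_p"), drop = FALSE]
    if (nrow(pk)) {
      pk$marker <- sheet$marker[i]
      pk$peak_format <- sheet$format[i]
      pk$experiment_id <- as.character(sheet$experiment[i])
      pk$replicate_id <- as.character(sheet$replicate[i])
      pk$cell_line <- sheet$cell_line[i]
      pk$tissue <- sheet$tissue[i]
    }
    pk
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (!length(out)) {
    return(data.frame(
      chrom = character(), start = numeric(), end = numeric(),
      neg_log10_p = numeric(), marker = character(), peak_format = character(),
      experiment_id = character(), replicate_id = character(),
      cell_line = character(), tissue = character(), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
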
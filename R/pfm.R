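DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix object
#'
#' @param matrix Numeric l x 4 matrix of counts or probabilities, columns
#'   A, C, G, T (column names optional but, when given, must be ACGT order
#'   or reorderable).
#' @param id Motif identifier.
#' @param pseudocount Weight added to every cell before row normalization;
#'   must be > 0 whenever a row contains zeros.
#' @param n_sequences Number of binding sites the matrix was built from;
#'   when `NULL` it is taken as the rounded sum of the first row of counts.
#' @param source_db Provenance label.
#' @return Object of class `pfm` with fields `id`, `matrix` (row-normalized
#'   probabilities, all entries > 0), `length`, `n_sequences`, `source_db`.
#' @export
pfm <- function(matrix, id = "pfm", pseudocount = 1, n_sequences = NULL,
                source_db = "unknown") {
  m <- as.matrix(matrix)
  if (ncol(m) != 4L) stop("PFM matrix must have 4 columns (A, C, G, T)")
  if (!is.null(colnames(m))) {
    if (!setequal(colnames(m), DNA_BASES)) stop("PFM columns must be named A, C, G, T")
    m <- m[, DNA_BASES, drop = FALSE]
  } else {
    colnames(m) <- DNA_BASES
  }
  if (nrow(m) < 1L) stop("PFM must have at least one position")
  if (any(m < 0) || any(!is.finite(m))) stop("PFM entries must be finite and non-negative")
  if (is.null(n_sequences)) n_sequences <- as.integer(round(sum(m[1L, ])))
  m <- m + pseudocount
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop(sprintf(
      "PFM '%s' row %d sums to zero and no pseudocount was applied",
      id, which(rs <= 0)[1L]
    ))
  }
  m <- m / rs
  if (any(m <= 0)) {
    stop(sprintf("PFM '%s' has zero probabilities; use a positive pseudocount", id))
  }
  out <- list(
    id = id, matrix = m, length = nrow(m),
    n_sequences = as.integer(n_sequences), source_db = source_db
  )
  class(out) <- "pfm"
  out
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf(
    "PFM %s: %d positions, %d sites, %.1f bits (%s)\n",
    x$id, x$length, x$n_sequences, pfm_information(x), x$source_db
  ))
  invisible(x)
}

#' Total information content of a PFM in bits
#'
#' Sum over positions of \eqn{2 + \sum_n p \log_2 p}.
#'
#' @param x A [pfm()].
#' @return Numeric scalar (bits).
#' @export
pfm_information <- function(x) {
  stopifnot(inherits(x, "pfm"))
  sum(2 + rowSums(x$matrix * log2(x$matrix)))
}

#' Consensus (argmax) sequence of a PFM
#'
#' @param x A [pfm()].
#' @return Character string of length `x$length`.
#' @export
pfm_consensus <- function(x) {
  stopifnot(inherits(x, "pfm"))
  paste(DNA_BASES[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Parse PFM files in JASPAR or TRANSFAC text dialects
#'
#' JASPAR: a `>id [name]` header followed by four rows `A [ counts ]` etc.
#' (brackets optional). TRANSFAC flat file: records delimited by `//` with
#' an `AC`/`ID` accession and numbered position rows between the `P0` header
#' and the next tag. Counts are converted to probabilities by adding
#' `pseudocount` to every cell and normalizing each row; `n_sequences` is
#' the rounded total of the first count row.
#'
#' @param path File path.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param pseudocount Weight added per cell before normalization.
#' @return List of [pfm()] objects (empty, with a warning, for an empty file).
#' @export
parse_pfm <- function(path, dialect = c("jaspar", "transfac"), pseudocount = 1) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning(sprintf("%s: empty PFM file", path))
    return(list())
  }
  if (dialect == "jaspar") .parse_jaspar(lines, path, pseudocount) else .parse_transfac(lines, path, pseudocount)
}

.parse_jaspar <- function(lines, path, pseudocount) {
  heads <- grep("^>", lines)
  if (!length(heads)) stop(sprintf("%s: no '>' header found; not JASPAR format", path))
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[k]])
    id <- strsplit(id, "\\s+")[[1L]][1L]
    body <- lines[seq(heads[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(body) != 4L) {
      stop(sprintf("%s: motif '%s' has %d base rows, expected 4", path, id, length(body)))
    }
    rows <- lapply(body, function(l) {
      base <- toupper(substr(l, 1L, 1L))
      nums <- gsub("[][]", " ", sub("^[ACGTacgt]\\s*", "", l))
      v <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1L]]))
      if (anyNA(v)) stop(sprintf("%s: motif '%s' has a non-numeric count row", path, id))
      list(base = base, counts = v)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES)) {
      stop(sprintf("%s: motif '%s' rows must be labelled A, C, G, T", path, id))
    }
    lens <- vapply(rows, function(r) length(r$counts), 1L)
    if (length(unique(lens)) != 1L) {
      stop(sprintf("%s: motif '%s' has ragged count rows", path, id))
    }
    m <- do.call(cbind, lapply(rows, `[[`, "counts"))
    colnames(m) <- bases
    out[[k]] <- pfm(m[, DNA_BASES, drop = FALSE],
      id = id,
      pseudocount = pseudocount, source_db = "jaspar"
    )
  }
  out
}

.parse_transfac <- function(lines, path, pseudocount) {
  recs <- split(lines, cumsum(c(TRUE, utils::head(lines, -1L) == "//")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "//"]
    if (!length(rec)) next
    tag <- sub("\\s.*$", "", rec)
    id <- NA_character_
    if (any(tag == "AC")) id <- trimws(sub("^AC\\s+", "", rec[tag == "AC"][1L]))
    if (is.na(id) && any(tag == "ID")) id <- trimws(sub("^ID\\s+", "", rec[tag == "ID"][1L]))
    p0 <- which(tag == "P0" | tag == "PO")
    if (!length(p0)) next
    if (is.na(id)) stop(sprintf("%s: TRANSFAC record without AC/ID accession", path))
    hdr <- strsplit(rec[p0[1L]], "\\s+")[[1L]][-1L]
    hdr <- toupper(hdr)
    if (!setequal(hdr[1:4], DNA_BASES)) {
      stop(sprintf("%s: motif '%s' P0 header must name A, C, G, T", path, id))
    }
    i <- p0[1L] + 1L
    m <- NULL
    while (i <= length(rec) && grepl("^\\d+", rec[i])) {
      v <- strsplit(rec[i], "\\s+")[[1L]]
      counts <- suppressWarnings(as.numeric(v[2:5]))
      if (anyNA(counts)) stop(sprintf("%s: motif '%s' has a non-numeric count row", path, id))
      m <- rbind(m, counts)
      i <- i + 1L
    }
    if (is.null(m)) stop(sprintf("%s: motif '%s' has no position rows", path, id))
    colnames(m) <- hdr[1:4]
    out[[length(out) + 1L]] <- pfm(m[, DNA_BASES, drop = FALSE],
      id = id,
      pseudocount = pseudocount, source_db = "transfac"
    )
  }
  if (!length(out)) warning(sprintf("%s: no TRANSFAC matrices found", path))
  out
}

#' Write PFMs in JASPAR text format
#'
#' Counts are written as given in `counts` attribute-free form: the stored
#' probability matrix is scaled by `n_sequences` and rounded.
#'
#' @param pfms List of [pfm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in pfms) {
    counts <- round(p$matrix * p$n_sequences)
    writeLines(sprintf(">%s", p$id), con, sep = "\n")
    for (b in DNA_BASES) {
      writeLines(sprintf("%s [ %s ]", b, paste(counts[, b], collapse = " ")), con, sep = "\n")
    }
  }
  invisible(path)
}

#' Background nucleotide model
#'
#' @param probs Numeric length-4 vector of A, C, G, T probabilities; must be
#'   positive and sum to 1 (within 1e-9).
#' @return Named numeric vector of class `background_model`.
#' @export
background_model <- function(probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  probs <- as.numeric(probs)
  stopifnot(length(probs) == 4L, all(probs > 0), abs(sum(probs) - 1) < 1e-9)
  names(probs) <- DNA_BASES
  class(probs) <- "background_model"
  probs
}

#' Background model from genome composition
#'
#' @param genome A `DNAStringSet`.
#' @return A [background_model()] with the genome's A/C/G/T frequencies.
#' @export
genome_background <- function(genome) {
  freq <- colSums(Biostrings::letterFrequency(genome, DNA_BASES))
  background_model(freq / sum(freq))
}

#' Build a sharply peaked PFM around a consensus sequence
#'
#' Count matrix with `n_sites * p_consensus` counts on the consensus base
#' and the remainder split evenly across the other three bases at every
#' position; useful for planted-signal simulations (a 10-mer at the default
#' settings carries well over 10 bits).
#'
#' @param consensus Consensus sequence (ACGT string).
#' @param n_sites Total sites per position (defaults to 100).
#' @param p_consensus Fraction of sites showing the consensus base.
#' @param id Motif identifier.
#' @param pseudocount Passed to [pfm()].
#' @return A [pfm()].
#' @export
sharp_pfm <- function(consensus, n_sites = 100L, p_consensus = 0.97,
                      id = paste0("sharp_", consensus), pseudocount = 1) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  stopifnot(all(bases %in% DNA_BASES))
  m <- matrix(n_sites * (1 - p_consensus) / 3,
    nrow = length(bases), ncol = 4L,
    dimnames = list(NULL, DNA_BASES)
  )
  m[cbind(seq_along(bases), match(bases, DNA_BASES))] <- n_sites * p_consensus
  pfm(m, id = id, pseudocount = pseudocount, n_sequences = n_sites, source_db = "synthetic")
}

#' Uniform (information-free) PFM
#'
#' @param l Motif length.
#' @param id Motif identifier.
#' @return A [pfm()] with all probabilities exactly 0.25.
#' @export
uniform_pfm <- function(l, id = "uniform") {
  m <- matrix(0.25, nrow = l, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  pfm(m, id = id, pseudocount = 0, n_sequences = 0L, source_db = "synthetic")
}
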
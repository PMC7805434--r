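#' Capture of curated TF->target edges by TBA annotations
#'
#' An edge (tf, target) is captured when some region whose nearest gene is
#' `target` enriches (at `cutoff`) a PFM mapped to `tf`. TFs absent from
#' `pfm_to_tf` cannot be captured and are counted separately.
#'
#' @param edges Data frame with columns `tf` and `target`; (tf, target)
#'   pairs must be unique.
#' @param tba_table Data frame with columns `cre_id`, `pfm_id`,
#'   `p_value_bin` (see [annotate_cres_with_tba()]).
#' @param cre_to_gene Named character vector: region id -> nearest gene.
#' @param pfm_to_tf Named character vector: PFM id -> TF name.
#' @param cutoff P-value cutoff defining enrichment.
#' @return List of class `capture_result` with `n_edges`, `n_captured`,
#'   `fraction_captured`, `n_not_capturable`, `cutoff` and the internal
#'   captured-pair key set used by [rewire_null()].
#' @export
captured_edges <- function(edges, tba_table, cre_to_gene, pfm_to_tf,
                           cutoff = 1e-05) {
  stopifnot(all(c("tf", "target") %in% colnames(edges)))
  if (anyDuplicated(paste(edges$tf, edges$target, sep = "\r"))) {
    stop("(tf, target) pairs must be unique")
  }
  sig <- tba_table[significant_at(tba_table$p_value_bin, cutoff), , drop = FALSE]
  tf_of <- unname(pfm_to_tf[sig$pfm_id])
  gene_of <- unname(cre_to_gene[sig$cre_id])
  ok <- !is.na(tf_of) & !is.na(gene_of)
  pair_keys <- unique(paste(tf_of[ok], gene_of[ok], sep = "\r"))
  capturable <- edges$tf %in% unname(pfm_to_tf)
  captured <- paste(edges$tf, edges$target, sep = "\r") %in% pair_keys
  out <- list(
    n_edges = nrow(edges),
    n_captured = sum(captured),
    fraction_captured = if (nrow(edges)) sum(captured) / nrow(edges) else 0,
    n_not_capturable = sum(!capturable),
    cutoff = cutoff,
    pair_keys = pair_keys,
    perm_p = NA_real_,
    n_permutations = 0L
  )
  class(out) <- "capture_result"
  out
}

#' @export
print.capture_result <- function(x, ...) {
  cat(sprintf(
    "captured %d / %d edges (%.1f%%); %d edge(s) not capturable%s\n",
    x$n_captured, x$n_edges, 100 * x$fraction_captured, x$n_not_capturable,
    if (!is.na(x$perm_p)) sprintf("; rewiring p = %.4g (%d permutations)", x$perm_p, x$n_permutations) else ""
  ))
  invisible(x)
}

#' Degree-preserving rewiring null for edge capture
#'
#' Permutes the target column of the edge list against the tf column
#' (preserving every TF's out-degree and the target multiset) and recomputes
#' the capture count under each permutation. The permutation p-value uses
#' the add-one estimator \eqn{(1 + \#\{captured_{perm} \ge captured_{obs}\})
#' / (1 + n_{perm})}, bounded below by \eqn{1/(n_{perm}+1)}.
#'
#' @param edges The same edge list passed to [captured_edges()].
#' @param observed The [captured_edges()] result.
#' @param n_permutations Number of rewirings (default 1000).
#' @param seed Integer seed.
#' @return `observed` with `perm_p`, `n_permutations` and
#'   `perm_captures` (the permutation capture counts) filled in.
#' @export
rewire_null <- function(edges, observed, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(observed, "capture_result"))
  if (length(unique(edges$tf)) < 2L || length(unique(edges$target)) < 2L) {
    stop("degenerate network: need >= 2 distinct TFs and >= 2 distinct targets")
  }
  n <- nrow(edges)
  # integer-coded pair membership for fast lookup
  keys <- strsplit(observed$pair_keys, "\r", fixed = TRUE)
  key_tf <- vapply(keys, `[`, "", 1L)
  key_tg <- vapply(keys, function(k) paste(k[-1L], collapse = "\r"), "")
  tf_lev <- unique(c(edges$tf, key_tf))
  tg_lev <- unique(c(edges$target, key_tg))
  hit <- matrix(FALSE, nrow = length(tf_lev), ncol = length(tg_lev))
  hit[cbind(match(key_tf, tf_lev), match(key_tg, tg_lev))] <- TRUE
  tf_code <- match(edges$tf, tf_lev)
  tg_code <- match(edges$target, tg_lev)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      sum(hit[cbind(tf_code, tg_code[sample.int(n)])])
    }, 0L)
  })
  observed$perm_p <- (1 + sum(counts >= observed$n_captured)) / (1 + n_permutations)
  observed$n_permutations <- as.integer(n_permutations)
  observed$perm_captures <- counts
  observed
}

#' Read a two-column TF->target edge list
#'
#' @param path Tab-separated file with columns `tf` and `target` (header
#'   optional; detected when the first line is exactly `tf<TAB>target`).
#' @return Data frame with columns `tf`, `target`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1L]), "tf\ttarget")) lines <- lines[-1L]
  if (!length(lines)) {
    return(data.frame(tf = character(), target = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop(sprintf("%s: line %d has fewer than 2 fields", path, bad[1L]))
  data.frame(
    tf = vapply(fields, `[`, "", 1L),
    target = vapply(fields, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}
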
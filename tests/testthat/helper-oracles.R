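# Brute-force oracles, kept deliberately independent of the package's
# GenomicRanges-based implementations: intervals become explicit per-base
# string sets, TBA becomes a direct double loop over windows and positions.

bed <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

# set of covered bases, one "chrom:pos" string per 0-based base
oracle_bases <- function(df) {
  if (is.null(df) || !nrow(df)) return(character())
  unique(unlist(lapply(seq_len(nrow(df)), function(i) {
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1))
  })))
}

gr_bases <- function(gr) oracle_bases(as_bed_frame(gr))

# per-base count of how many tracks (each a BED frame) cover a base
oracle_track_counts <- function(tracks) {
  table(unlist(lapply(tracks, oracle_bases)))
}

# full-extent union oracle: all bases of input intervals containing >= 1
# base covered by >= min_labels tracks
oracle_full_extent <- function(tracks, min_labels = 2) {
  counts <- oracle_track_counts(tracks)
  seeds <- names(counts)[counts >= min_labels]
  kept <- character()
  for (df in tracks) {
    for (i in seq_len(nrow(df))) {
      b <- oracle_bases(df[i, , drop = FALSE])
      if (any(b %in% seeds)) kept <- c(kept, b)
    }
  }
  unique(kept)
}

# fast integer-keyed variants of the base-set oracles (for the large random
# property loops): base (chrom, pos) -> match(chrom, chroms) * 2^16 + pos
oracle_keys <- function(df, chroms = c("chrA", "chrB")) {
  if (is.null(df) || !nrow(df)) return(integer())
  code <- match(df$chrom, chroms) * 65536L
  unique(unlist(lapply(seq_len(nrow(df)), function(i) {
    code[i] + seq.int(df$start[i], df$end[i] - 1L)
  })))
}

gr_keys <- function(gr, chroms = c("chrA", "chrB")) {
  oracle_keys(as_bed_frame(gr), chroms)
}

oracle_key_counts <- function(tracks, chroms = c("chrA", "chrB")) {
  table(unlist(lapply(tracks, oracle_keys, chroms = chroms)))
}

oracle_full_extent_keys <- function(tracks, min_labels = 2, chroms = c("chrA", "chrB")) {
  counts <- oracle_key_counts(tracks, chroms)
  seeds <- as.integer(names(counts)[counts >= min_labels])
  kept <- integer()
  for (df in tracks) {
    for (i in seq_len(nrow(df))) {
      b <- oracle_keys(df[i, , drop = FALSE], chroms)
      if (any(b %in% seeds)) kept <- c(kept, b)
    }
  }
  unique(kept)
}

random_interval_set <- function(n, chroms = c("chrA", "chrB"), max_coord = 10000,
                                max_len = 400) {
  start <- sample.int(max_coord - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  bed(sample(chroms, n, replace = TRUE), start, start + len)
}

# direct product evaluation of the TBA equation, no log space
tba_oracle <- function(seq, pfm, bg = background_model()) {
  bases <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  l <- pfm$length
  L <- length(bases)
  ratio <- function(b, j) if (b == "N") 1 else pfm$matrix[j, b] / bg[[b]]
  total <- 0
  for (i in seq_len(L - l + 1)) {
    f <- 1
    r <- 1
    for (j in seq_len(l)) {
      b <- bases[i + j - 1]
      f <- f * ratio(b, j)
      r <- r * ratio(comp[[b]], l - j + 1)
    }
    total <- total + max(f, r)
  }
  total
}

random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")

random_pfm <- function(l, id = "rand") {
  m <- matrix(stats::rexp(4 * l) + 0.05, ncol = 4)
  pfm(m, id = id, pseudocount = 0.5)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

expect_sorted_disjoint <- function(gr) {
  df <- as_bed_frame(gr)
  if (nrow(df) < 2) return(invisible(TRUE))
  o <- order(df$chrom, df$start)
  expect_identical(o, seq_len(nrow(df)))
  same <- df$chrom[-1] == df$chrom[-nrow(df)]
  expect_true(all(!same | df$start[-1] > df$end[-nrow(df)]))
  invisible(TRUE)
}
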
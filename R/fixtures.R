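#' Specification of a self-contained synthetic dataset
#'
#' Describes a small diploid-cohort study: an i.i.d. random genome, planted
#' regulatory elements covered by histone-mark peaks in chosen cell lines,
#' planted motif consensus sites, and a phased cohort. The default layout is
#' desk-scale: two 500 kb chromosomes, three cell lines from two tissues and
#' 50 individuals; every generator is a pure function of (spec, seed).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param base_composition A [background_model()] for i.i.d. genome bases.
#' @param cell_lines Data frame with columns `cell_line`, `tissue`.
#' @param planted_elements Data frame with columns `element_class`
#'   (`promoter`, `enhancer` or `active_enhancer`), `chrom`, `start`, `end`
#'   (0-based half-open) and `cell_lines` (comma-separated cell-line names).
#' @param planted_motifs `NULL` or data frame with columns `pfm_id`,
#'   `chrom`, `start` (0-based), `strand` (`+`/`-`), `consensus` (the
#'   sequence written into the genome).
#' @param n_individuals Cohort size (haplotypes = 2x this).
#' @param tss_window Promoter window half-width used to validate that
#'   planted enhancers are far enough from TSSs.
#' @param seed Integer seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                         base_composition = background_model(),
                         cell_lines = data.frame(
                           cell_line = c("CL1", "CL2", "CL3"),
                           tissue = c("tissueA", "tissueA", "tissueB"),
                           stringsAsFactors = FALSE
                         ),
                         planted_elements = default_planted_elements(),
                         planted_motifs = NULL,
                         n_individuals = 50L,
                         tss_window = 1000L,
                         seed = 1L) {
  stopifnot(
    all(chrom_lengths >= 1000), !is.null(names(chrom_lengths)),
    inherits(base_composition, "background_model"),
    all(c("cell_line", "tissue") %in% colnames(cell_lines)),
    all(c("element_class", "chrom", "start", "end", "cell_lines") %in% colnames(planted_elements))
  )
  pe <- planted_elements
  stopifnot(
    all(pe$element_class %in% c("promoter", "enhancer", "active_enhancer")),
    all(pe$chrom %in% names(chrom_lengths)),
    all(pe$start >= 0), all(pe$end > pe$start),
    all(pe$end <= chrom_lengths[pe$chrom])
  )
  unknown <- setdiff(unlist(strsplit(pe$cell_lines, ",")), cell_lines$cell_line)
  if (length(unknown)) {
    stop(sprintf("planted elements reference unknown cell line(s): %s", paste(unknown, collapse = ", ")))
  }
  # enhancers must sit strictly outside every TSS window (TSS = promoter center)
  tss_pos <- .fixture_tss_positions(pe)
  enh <- pe[pe$element_class != "promoter", , drop = FALSE]
  for (i in seq_len(nrow(enh))) {
    near <- tss_pos$chrom == enh$chrom[i] &
      tss_pos$pos + tss_window > enh$start[i] &
      tss_pos$pos - tss_window < enh$end[i]
    if (any(near)) {
      stop(sprintf(
        "planted %s at %s:%d-%d lies within %d bp of a planted TSS",
        enh$element_class[i], enh$chrom[i], enh$start[i], enh$end[i], tss_window
      ))
    }
  }
  # same-class planted elements must be separated (> 0 bp gap) so that the
  # expected consensus equals the planted intervals verbatim
  for (cls in unique(pe$element_class)) {
    sub <- pe[pe$element_class == cls | (cls == "enhancer" & pe$element_class == "active_enhancer"), , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
    if (nrow(sub) > 1L) {
      same <- sub$chrom[-1L] == sub$chrom[-nrow(sub)]
      touch <- sub$start[-1L] <= sub$end[-nrow(sub)]
      if (any(same & touch)) stop(sprintf("planted %s elements overlap or are book-ended", cls))
    }
  }
  if (!is.null(planted_motifs)) {
    pm <- planted_motifs
    stopifnot(all(c("pfm_id", "chrom", "start", "strand", "consensus") %in% colnames(pm)))
    pm$end <- pm$start + nchar(pm$consensus)
    stopifnot(all(pm$chrom %in% names(chrom_lengths)), all(pm$end <= chrom_lengths[pm$chrom]))
    for (st in c("+", "-")) {
      sub <- pm[pm$strand == st, , drop = FALSE]
      sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
      if (nrow(sub) > 1L) {
        same <- sub$chrom[-1L] == sub$chrom[-nrow(sub)]
        ovl <- sub$start[-1L] < sub$end[-nrow(sub)]
        if (any(same & ovl)) stop("planted motifs overlap on the same strand")
      }
    }
  }
  out <- list(
    chrom_lengths = stats::setNames(as.integer(chrom_lengths), names(chrom_lengths)),
    base_composition = base_composition,
    cell_lines = cell_lines,
    planted_elements = pe,
    planted_motifs = planted_motifs,
    n_individuals = as.integer(n_individuals),
    tss_window = as.integer(tss_window),
    seed = as.integer(seed)
  )
  class(out) <- "fixture_spec"
  out
}

#' Default planted-element layout
#'
#' Three promoters, two plain enhancers and two active enhancers spread over
#' two chromosomes: most elements are shared by at least two cell lines, one
#' enhancer exists in a single cell line only (so it must be absent from
#' tissue and global consensuses).
#'
#' @return Data frame accepted by [fixture_spec()].
#' @export
default_planted_elements <- function() {
  data.frame(
    element_class = c(
      "promoter", "promoter", "promoter",
      "enhancer", "enhancer",
      "active_enhancer", "active_enhancer"
    ),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr2", "chr1", "chr2"),
    start = c(10000, 60000, 20000, 120000, 80000, 200000, 150000),
    end = c(11000, 60800, 21200, 121500, 81000, 201000, 151200),
    cell_lines = c(
      "CL1,CL2,CL3", "CL1,CL2", "CL1,CL2,CL3",
      "CL1,CL2", "CL2", # second enhancer: single cell line
      "CL1,CL2,CL3", "CL1,CL3"
    ),
    stringsAsFactors = FALSE
  )
}

.fixture_tss_positions <- function(planted_elements) {
  pr <- planted_elements[planted_elements$element_class == "promoter", , drop = FALSE]
  if (!nrow(pr)) {
    return(data.frame(chrom = character(), pos = numeric(), gene = character()))
  }
  data.frame(
    chrom = pr$chrom,
    pos = floor((pr$start + pr$end) / 2),
    gene = sprintf("GENE%03d", seq_len(nrow(pr))),
    stringsAsFactors = FALSE
  )
}

#' Generate the synthetic genome
#'
#' I.i.d. bases from the spec's composition, with planted motif consensus
#' sequences written at their intervals (reverse-complemented on `-`).
#'
#' @param spec A [fixture_spec()].
#' @return Named `DNAStringSet`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  seqs <- withr::with_seed(spec$seed, {
    lapply(names(spec$chrom_lengths), function(chr) {
      paste(
        sample(DNA_BASES, spec$chrom_lengths[[chr]],
          replace = TRUE,
          prob = as.numeric(spec$base_composition)
        ),
        collapse = ""
      )
    })
  })
  names(seqs) <- names(spec$chrom_lengths)
  if (!is.null(spec$planted_motifs)) {
    pm <- spec$planted_motifs
    for (i in seq_len(nrow(pm))) {
      s <- toupper(pm$consensus[i])
      if (pm$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      chr <- pm$chrom[i]
      substr(seqs[[chr]], pm$start[i] + 1L, pm$start[i] + nchar(s)) <- s
    }
  }
  Biostrings::DNAStringSet(unlist(seqs))
}

#' TSS annotations of the planted promoters
#'
#' One high-confidence TSS (score 20) at the center of every planted
#' promoter, with synthetic gene names; optionally a set of low-score decoy
#' TSSs that the score filter must remove.
#'
#' @param spec A [fixture_spec()].
#' @param decoy_tss Optional data frame `chrom`, `pos`, `score` of extra
#'   (typically sub-threshold) TSSs.
#' @return Data frame with columns `chrom`, `start`, `end`, `gene`, `score`.
#' @export
make_tss <- function(spec, decoy_tss = NULL) {
  tp <- .fixture_tss_positions(spec$planted_elements)
  df <- data.frame(
    chrom = tp$chrom, start = tp$pos, end = tp$pos + 1,
    gene = tp$gene, score = 20, stringsAsFactors = FALSE
  )
  if (!is.null(decoy_tss) && nrow(decoy_tss)) {
    df <- rbind(df, data.frame(
      chrom = decoy_tss$chrom, start = decoy_tss$pos, end = decoy_tss$pos + 1,
      gene = sprintf("DECOY%03d", seq_len(nrow(decoy_tss))),
      score = decoy_tss$score, stringsAsFactors = FALSE
    ))
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.marker_intervals <- function(spec, cell_line, marker) {
  pe <- spec$planted_elements
  carried <- vapply(strsplit(pe$cell_lines, ","), function(cls) cell_line %in% cls, TRUE)
  use <- switch(marker,
    H3K4me3 = pe$element_class == "promoter",
    H3K4me1 = pe$element_class %in% c("enhancer", "active_enhancer"),
    H3K27ac = pe$element_class == "active_enhancer"
  )
  pe[carried & use, c("chrom", "start", "end"), drop = FALSE]
}

#' Emit per-replicate peak files and a sample sheet
#'
#' For every (cell line, marker) with planted elements, writes one
#' narrowPeak/broadPeak file per experiment and replicate. Noise knobs:
#' `jitter_sd` perturbs boundaries (Gaussian, rounded), `dropout` drops each
#' planted peak from a replicate independently, and `decoy_elements` places
#' extra peaks that exist in a single named experiment only.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created).
#' @param peak_format `"narrow"` or `"broad"`.
#' @param n_experiments,n_replicates Experiments per (cell line, marker) and
#'   replicates per experiment.
#' @param noise List with `jitter_sd` (bp) and `dropout` (probability).
#' @param decoy_elements Optional data frame `chrom`, `start`, `end`,
#'   `cell_line`, `marker`, `experiment` of single-experiment decoy peaks.
#' @return Path to the written sample sheet (`sample_sheet.tsv` in `dir`).
#' @export
make_peaks <- function(spec, dir, peak_format = c("narrow", "broad"),
                       n_experiments = 2L, n_replicates = 2L,
                       noise = list(jitter_sd = 0, dropout = 0),
                       decoy_elements = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  peak_format <- match.arg(peak_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jitter_sd <- if (is.null(noise$jitter_sd)) 0 else noise$jitter_sd
  dropout <- if (is.null(noise$dropout)) 0 else noise$dropout
  sheet <- list()
  withr::with_seed(spec$seed + 1L, {
    for (cl in spec$cell_lines$cell_line) {
      tissue <- spec$cell_lines$tissue[spec$cell_lines$cell_line == cl]
      for (mk in c("H3K4me1", "H3K4me3", "H3K27ac")) {
        base <- .marker_intervals(spec, cl, mk)
        decoys <- if (is.null(decoy_elements)) NULL else {
          decoy_elements[decoy_elements$cell_line == cl & decoy_elements$marker == mk, , drop = FALSE]
        }
        if (!nrow(base) && (is.null(decoys) || !nrow(decoys))) next
        for (ex in seq_len(n_experiments)) {
          for (rp in seq_len(n_replicates)) {
            df <- base
            if (nrow(df) && dropout > 0) {
              df <- df[stats::runif(nrow(df)) >= dropout, , drop = FALSE]
            }
            if (nrow(df) && jitter_sd > 0) {
              df$start <- pmax(0, df$start + round(stats::rnorm(nrow(df), 0, jitter_sd)))
              df$end <- pmax(df$start + 50, df$end + round(stats::rnorm(nrow(df), 0, jitter_sd)))
            }
            if (!is.null(decoys) && nrow(decoys)) {
              mine <- decoys[decoys$experiment == ex, c("chrom", "start", "end"), drop = FALSE]
              if (nrow(mine)) df <- rbind(df, mine)
            }
            if (!nrow(df)) next
            df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
            out <- data.frame(
              chrom = df$chrom, start = df$start, end = df$end,
              name = sprintf("%s_%s_e%d_r%d_%03d", cl, mk, ex, rp, seq_len(nrow(df))),
              score = 1000, strand = ".",
              signal = 5.0, p = 30.0, q = 20.0,
              stringsAsFactors = FALSE
            )
            if (peak_format == "narrow") out$peak <- floor((df$end - df$start) / 2)
            fn <- sprintf("%s_%s_e%d_r%d.%sPeak", cl, mk, ex, rp, peak_format)
            write_bed(out, file.path(dir, fn))
            sheet[[length(sheet) + 1L]] <- data.frame(
              path = fn, marker = mk, format = peak_format,
              experiment = sprintf("e%d", ex), replicate = sprintf("r%d", rp),
              cell_line = cl, tissue = tissue, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  })
  sheet <- do.call(rbind, sheet)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, eol = "\n"
  )
  sheet_path
}

#' Ground-truth consensus tracks of a fixture
#'
#' Computes, directly from the planted layout (never by running the
#' pipeline), the consensus regions a zero-noise run must produce: at the
#' cell-line level every planted element of each carried class; at tissue
#' and global levels every element carried by at least `min_cell_lines` of
#' the level's cell lines, with support equal to that carrier count.
#'
#' @param spec A [fixture_spec()].
#' @param peak_format Format label for the output rows.
#' @param n_experiments Experiments emitted per track (cell-line level
#'   support equals this when >= 2, else 1).
#' @param min_cell_lines Carrier threshold for tissue/global membership.
#' @return Data frame in the exact shape of [run_consensus_pipeline()] output.
#' @export
fixture_truth <- function(spec, peak_format = "narrow", n_experiments = 2L,
                          min_cell_lines = 2L) {
  pe <- spec$planted_elements
  carriers <- strsplit(pe$cell_lines, ",")
  class_of <- function(cls) {
    if (cls == "enhancer") which(pe$element_class %in% c("enhancer", "active_enhancer")) else which(pe$element_class == cls)
  }
  rows <- list()
  add <- function(idx, support, level, label, cls) {
    if (!length(idx)) return()
    gr <- genomic_intervals(pe$chrom[idx], pe$start[idx], pe$end[idx])
    S4Vectors::mcols(gr)$n_support <- as.integer(support)
    gr <- .sort_intervals(gr)
    df <- as_bed_frame(gr)
    df$name <- .region_names(level, label, cls, nrow(df))
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, label = label, element_class = cls,
      peak_format = peak_format,
      df[, c("chrom", "start", "end", "name")], n_support = df$n_support,
      stringsAsFactors = FALSE
    )
  }
  cl_support <- if (n_experiments >= 2L) n_experiments else 1L
  for (cl in spec$cell_lines$cell_line) {
    for (cls in c("promoter", "enhancer", "active_enhancer")) {
      idx <- intersect(class_of(cls), which(vapply(carriers, function(x) cl %in% x, TRUE)))
      add(idx, rep(cl_support, length(idx)), "cell_line", cl, cls)
    }
  }
  groups <- c(
    stats::setNames(
      lapply(unique(spec$cell_lines$tissue), function(ts) {
        spec$cell_lines$cell_line[spec$cell_lines$tissue == ts]
      }),
      unique(spec$cell_lines$tissue)
    ),
    list(global = spec$cell_lines$cell_line)
  )
  for (g in names(groups)) {
    level <- if (g == "global") "global" else "tissue"
    for (cls in c("promoter", "enhancer", "active_enhancer")) {
      idx <- class_of(cls)
      n_car <- vapply(carriers[idx], function(x) length(intersect(x, groups[[g]])), 1L)
      keep <- n_car >= min_cell_lines
      add(idx[keep], n_car[keep], level, g, cls)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a phased diploid SNP VCF with planted allele fractions
#'
#' Each planted SNP is placed on `round(hap_fraction * 2N)` haplotypes
#' (chosen at random but reproducibly from the spec seed); an exact zero
#' haplotype count is an error. SNPs sharing a value in an optional
#' `ld_group` column are placed on the same carrier haplotypes (perfect
#' linkage), which is how multi-SNP haplotype alleles are emulated.
#'
#' @param spec A [fixture_spec()].
#' @param genome The [make_genome()] output (for REF bases).
#' @param planted_snps Data frame with columns `chrom`, `pos` (1-based),
#'   `alt`, `hap_fraction`, and optionally `ld_group`.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
make_vcf <- function(spec, genome, planted_snps, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_hap <- 2L * spec$n_individuals
  samples <- sprintf("IND%04d", seq_len(spec$n_individuals))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cretba_fixture",
    sprintf(
      "##contig=<ID=%s,length=%d>",
      names(spec$chrom_lengths), spec$chrom_lengths
    ),
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  snps <- planted_snps
  if (!"ld_group" %in% colnames(snps)) snps$ld_group <- seq_len(nrow(snps))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  body <- withr::with_seed(spec$seed + 2L, {
    carriers <- list()
    for (g in unique(snps$ld_group)) {
      frac <- unique(snps$hap_fraction[snps$ld_group == g])
      if (length(frac) != 1L) {
        stop(sprintf("SNPs of ld_group '%s' must share one hap_fraction", g))
      }
      cnt <- round(frac * n_hap)
      if (cnt < 1L) {
        stop(sprintf(
          "planted SNP group '%s' rounds to zero haplotypes (fraction %g of %d)",
          g, frac, n_hap
        ))
      }
      carriers[[as.character(g)]] <- sample.int(n_hap, cnt)
    }
    vapply(seq_len(nrow(snps)), function(i) {
      ref <- as.character(Biostrings::subseq(genome[[snps$chrom[i]]], snps$pos[i], snps$pos[i]))
      if (identical(ref, toupper(snps$alt[i]))) {
        stop(sprintf("planted ALT equals REF at %s:%d", snps$chrom[i], snps$pos[i]))
      }
      car <- carriers[[as.character(snps$ld_group[i])]]
      hap <- rep(0L, n_hap)
      hap[car] <- 1L
      gt <- paste(hap[seq(1L, n_hap, by = 2L)], hap[seq(2L, n_hap, by = 2L)], sep = "|")
      paste(c(
        snps$chrom[i], snps$pos[i], sprintf("snp%03d", i), ref,
        toupper(snps$alt[i]), ".", "PASS",
        sprintf("AC=%d;AN=%d;AF=%.6g", length(car), n_hap, length(car) / n_hap),
        "GT", gt
      ), collapse = "\t")
    }, "")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Materialize a complete fixture on disk
#'
#' Writes the genome FASTA, the TSS BED, per-replicate peak files with a
#' sample sheet, and the ground-truth consensus BEDs under `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param peak_format,n_experiments,n_replicates,noise,decoy_elements Passed
#'   to [make_peaks()] / [fixture_truth()].
#' @return List with paths: `genome`, `tss`, `sample_sheet`, `truth_dir`.
#' @export
write_fixture <- function(spec, dir, peak_format = "narrow",
                          n_experiments = 2L, n_replicates = 2L,
                          noise = list(jitter_sd = 0, dropout = 0),
                          decoy_elements = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(spec)
  genome_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_path)
  tss <- make_tss(spec)
  tss_path <- file.path(dir, "tss.bed")
  write_bed(tss[, c("chrom", "start", "end", "gene", "score")], tss_path)
  sheet_path <- make_peaks(spec, dir,
    peak_format = peak_format,
    n_experiments = n_experiments, n_replicates = n_replicates,
    noise = noise, decoy_elements = decoy_elements
  )
  truth <- fixture_truth(spec,
    peak_format = peak_format,
    n_experiments = n_experiments
  )
  truth_dir <- file.path(dir, "truth")
  write_consensus_tracks(truth, truth_dir)
  list(
    genome = genome_path, tss = tss_path, sample_sheet = sheet_path,
    truth_dir = truth_dir
  )
}
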
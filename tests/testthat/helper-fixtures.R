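# Small in-code fixtures shared across test files.

write_lines_tsv <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

# a tiny i.i.d. genome as DNAStringSet
tiny_genome <- function(lengths = c(chr1 = 20000L), seed = 42L,
                        probs = rep(0.25, 4)) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs), collapse = "")
    }, "")
  })
  Biostrings::DNAStringSet(seqs)
}

narrowpeak_line <- function(chrom, start, end, name = "pk", nlp = 5) {
  sprintf("%s\t%d\t%d\t%s\t1000\t.\t4.5\t%s\t3.2\t10", chrom, start, end, name, nlp)
}

broadpeak_line <- function(chrom, start, end, name = "pk", nlp = 5) {
  sprintf("%s\t%d\t%d\t%s\t1000\t.\t4.5\t%s\t3.2", chrom, start, end, name, nlp)
}

# a 12-position sharp motif used wherever a high-information PFM is needed;
# long enough that chance consensus matches in a few hundred bp are rare
SHARP_CONSENSUS <- "ACGTTGCAGTAC"
sharp12 <- function() sharp_pfm(SHARP_CONSENSUS, id = "sharp12")

# positions used when a fixture needs a motif copy that is convincingly dead
# on the reference haplotype: four mismatches put the broken site's affinity
# at background level, far below any chance single-mismatch site that shapes
# the upper tail of a null TBA distribution
BREAK_POSITIONS <- c(2L, 5L, 8L, 11L)

break_motif <- function(consensus, positions = BREAK_POSITIONS) {
  for (p in positions) {
    substr(consensus, p, p) <- setdiff(c("A", "C", "G", "T"), substr(consensus, p, p))[1]
  }
  consensus
}

# write a broken motif copy into a genome at a 1-based offset and return the
# SNP table (one ld_group) whose ALT alleles restore the consensus
plant_allelic_motif <- function(genome, chrom, at, consensus = SHARP_CONSENSUS,
                                positions = BREAK_POSITIONS, hap_fraction = 0.5) {
  s <- as.character(genome[[chrom]])
  substr(s, at, at + nchar(consensus) - 1L) <- break_motif(consensus, positions)
  genome[[chrom]] <- Biostrings::DNAString(s)
  snps <- data.frame(
    chrom = chrom, pos = at + positions - 1L,
    alt = vapply(positions, function(p) substr(consensus, p, p), ""),
    hap_fraction = hap_fraction, ld_group = "restore",
    stringsAsFactors = FALSE
  )
  list(genome = genome, snps = snps)
}
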
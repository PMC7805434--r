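Package: cretba
Title: Consensus Regulatory Elements and Total Binding Affinity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds consensus regulatory elements (promoters, enhancers and
    active enhancers) from histone-mark ChIP-seq peak tracks (H3K4me1,
    H3K4me3, H3K27ac) at cell-line, tissue and global abstraction levels;
    scores transcription-factor total binding affinity (TBA) on each element
    with permutation-calibrated empirical significance against background
    genomic regions; quantifies the fraction of common haplotype alleles
    (from phased SNP genotypes) supporting each TBA enrichment; and evaluates
    concordance of the annotations with curated transcription-factor target
    networks under a degree-preserving rewiring null. Ships a synthetic
    fixture generator (genome, peaks, TSS, PFMs, phased VCF, edge lists) so
    the whole workflow runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
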
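---
title: "Consensus regulatory elements and total binding affinity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus regulatory elements and total binding affinity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cretba` turns per-replicate histone-mark ChIP-seq peak tracks into
*consensus regulatory elements* (CREs) at three abstraction levels, scores
every element's affinity for transcription-factor (TF) motifs with a
cutoff-free *total binding affinity* (TBA) statistic, calibrates that
statistic empirically against random genomic background, and asks two
follow-up questions: which fraction of common haplotype alleles in a phased
cohort supports each enrichment, and how much of a curated TF–target network
the annotations can explain. This vignette describes the model behind each
stage, the parameters that matter, and the numerical and design choices the
implementation makes.

## Consensus regulatory elements

The input is a collection of ENCODE-style narrowPeak/broadPeak files for the
markers H3K4me1, H3K4me3 and H3K27ac, organized by cell line, experiment and
replicate (narrow and broad collections are always processed separately).
The aggregation ladder is deliberately asymmetric, moving from conservative
to permissive as evidence accumulates:

* **Replicates → experiment:** exact basepair *intersection* of all
  replicate tracks. A base must be called in every replicate. With more than
  two replicates we intersect all of them — the most conservative reading of
  replicate agreement.
* **Experiments → cell line:** bases covered by **at least two** distinct
  experiments are kept, and maximal runs of such bases are merged. With a
  single experiment the track passes through with support 1 rather than
  being discarded, so sparsely assayed cell lines are still represented.
* **Cell lines → tissue / global:** bases covered by at least two cell
  lines seed the consensus, and every input region touching a seed is
  retained at its *full extent* (union). The union acknowledges that peak
  boundaries are noisy at this level; the seed rule still demands
  independent support. The segment-only alternative is available via
  `run_config(full_extent_union = FALSE)` because the choice between "merge
  of overlaps" and "union of overlapping regions" is a genuine modeling
  fork; full-extent is the default.

Element classes are assigned per cell line from the marker tracks:

* **Promoters** are whole H3K4me3 consensus regions that overlap (by at
  least 1 bp) a window of ±1 kb around a retained TSS (TSS score ≥ 10 by
  default). We keep the whole region, not its intersection with the window:
  H3K4me3 occupancy is treated as region-level evidence.
* **Enhancers** are H3K4me1 consensus regions basepair-depleted of all
  H3K4me3 regions *and* of all TSS windows. Because depletion is performed
  at basepair resolution, promoter and enhancer tracks are disjoint by
  construction, and every retained enhancer base is > 1 kb from a TSS
  (bases exactly at the window edge, i.e. at distance 1 kb, fall outside
  the half-open window and are retained).
* **Active enhancers** are enhancer regions overlapped by ≥ 1 bp of
  H3K27ac, retained whole — H3K27ac acts as a flag, not a mask.

A cell line missing a marker simply does not emit the classes that need it
(H3K4me3 only → promoters only). Broad peaks are pre-filtered to reported
p-value strictly below 0.01; narrow peaks are not filtered. A broad peak
whose p-value column holds the `-1` "not reported" sentinel is an error when
filtering is requested — silently keeping or dropping such peaks would both
be defensible, so the package refuses to guess.

All interval algebra follows BEDTools semantics with default parameters
(book-ended intervals merge; strand is ignored, histone marks being
unstranded). Coordinates are BED-convention 0-based half-open in every file
read or written; internally regions live in `GRanges`. Every public
operation is validated in the test suite against brute-force per-base set
oracles on thousands of random instances.

## Total binding affinity

For a motif given as an l-position frequency matrix (PFM) $w$ and a sequence
$r$ of length $L$, the TBA is

$$a_{rw} = \sum_{i=1}^{L-l+1} \max\!\left(\prod_{j=1}^{l}
\frac{P(w_j, r_{i+j-1})}{P(b, r_{i+j-1})},\;
\prod_{j=1}^{l}\frac{P(w_{l-j+1}, r'_{i+j-1})}{P(b, r'_{i+j-1})}\right)$$

where $r'$ is the complementary base and $P(b,\cdot)$ a background model.
Every window contributes its better strand's likelihood ratio — no site
cutoff is applied, so weak sites accumulate. Parameters:

* **Pseudocount** (default 1.0 per count cell, before row normalization):
  zero probabilities would send a single mismatching window to ratio 0 and
  are disallowed; the pseudocount is the standard Laplace regularization.
* **Background** (default uniform 0.25): configurable, e.g. from genome
  composition via `genome_background()`.
* **N bases** contribute ratio exactly 1 on both strands — neutral, so
  regions spanning assembly gaps are scored rather than dropped.

Raw TBA is a sum over $L-l+1$ windows and therefore grows linearly with
sequence length; scores are compared across regions only after division by
the window count (`normalize_tba()`), i.e. as the mean per-window affinity.

Numerically, each window's product is accumulated as a sum of log ratios and
re-exponentiated per window; the window terms are then sorted ascending and
summed with R's long-double accumulator. Sorting makes the outer sum
independent of window order, which has a useful consequence: the set of
per-window values of a sequence and of its reverse complement are identical
by construction (the reverse-strand scan is implemented as a forward scan of
the reverse-complemented matrix, with the accumulation order arranged to
follow the identical floating-point path), so `tba(s) == tba(revcomp(s))`
holds *bit-exactly*, not merely approximately. The implementation is checked
against a direct product-evaluation oracle to relative error below 1e-9.

## Empirical significance

Because normalized TBA has no closed-form null, each PFM gets a reference
distribution: `n_regions` random genomic regions (default 100,000; the test
and example profile uses 5,000) are sampled uniformly over the genome with
lengths drawn from a user-supplied sampler — by default resampled from the
observed CRE length distribution, since calibration is marginal over the
same length mix that will be scored. Thresholds for the cutoffs 5e-02,
1e-02, 1e-03, 1e-04 and 1e-05 are pre-computed as upper empirical quantiles
using the $(k+1)/(n+1)$ plotting convention, so a fresh null region exceeds
the threshold at cutoff $\alpha$ with probability at most (approximately)
$\alpha$ — a conservative convention chosen because the sample maximum alone
would otherwise anchor the extreme cutoffs. A score exactly at a threshold
is significant at that cutoff. Note that with $n$ background regions the
thresholds below $1/n$ all collapse onto the top order statistics: a 5,000
region reference resolves 1e-03 properly but reports the same threshold for
1e-04 and 1e-05. The full 100,000-region default resolves 1e-05 as intended;
the suite's calibration test verifies that fresh-null exceedance matches
$\alpha$ at 0.05, 0.01 and 0.001 within binomial tolerance.

Two quality filters mirror common practice for heterogeneous PFM
collections: motifs built from fewer than 50 binding sites are dropped, and
motifs enriched in more than 50% of the scored regions at the active cutoff
are dropped as promiscuous (both configurable). No multiple-testing
correction is applied beyond reporting the stringent 1e-05 bin.

## Allele-specific TBA

Given phased diploid SNP genotypes, each haplotype's sequence over a region
is reconstructed by substituting its alleles into the reference; identical
sequences are grouped into *alleles* whose frequency is the haplotype count
over $2N$. Alleles are whole-haplotype sequences, so SNPs in linkage form
combined alleles rather than being treated marginally. Only *common* alleles
— frequency strictly greater than 1% — are retained, and the reported
statistic is the fraction of common alleles whose normalized TBA is
significant at the chosen cutoff. Since alleles differ from the reference
only by SNPs, all share its length, and the same PFM-specific reference
distribution applies. Indels and other non-SNP records are skipped with a
counted warning; unphased genotypes are an error by default (configurable to
skip); multi-allelic SNPs are substituted per haplotype.

## Network capture and the rewiring null

To relate TBA annotations to curated TF→target edges, each region is
assigned its nearest gene (gap distance, ties to the smaller (chrom, start)
— the tie direction is arbitrary but fixed for determinism). An edge is
*captured* when some region whose nearest gene is the target enriches a PFM
of the TF at the cutoff. Significance of the captured fraction comes from a
degree-preserving rewiring null: the target column is permuted against the
TF column (which preserves both marginal degree multisets — permuting
regulators instead, or both, yields the same capture distribution), and the
p-value uses the add-one estimator $(1 + \#\{perm \ge obs\})/(1 + n)$,
bounded below by $1/(n+1)$ so 1000 permutations can report at best
"P < 0.001".

## The synthetic data generator

`fixture_spec()` + `make_genome()`/`make_peaks()`/`make_tss()`/`make_vcf()`
produce a fully self-contained study: an i.i.d. random genome (default two
500 kb chromosomes, uniform composition) with motif consensus sequences
optionally written in; planted regulatory elements covered by per-replicate
peak files across three cell lines from two tissues; one high-confidence TSS
per planted promoter; and a phased cohort (default 50 individuals) in which
planted SNPs sit on an exact rounded fraction of haplotypes — SNPs sharing
an `ld_group` ride on the same haplotypes, which is how a multi-SNP
allele-specific motif is planted. Noise knobs add boundary jitter, replicate
dropout and single-experiment decoy peaks. Every generator is a pure
function of (spec, seed), and ground-truth consensus BEDs are emitted
alongside so tests assert recovery rather than re-derivation.

What the generator does *not* emulate matters for interpreting green tests:
real peak-caller boundary bias, correlated replicate noise, linkage
structure beyond the planted groups, GC/composition heterogeneity, and
repeat-driven motif clustering are all absent. Passing the round-trip and
calibration suites therefore demonstrates algorithmic correctness under the
stated model, not robustness to every artifact of real ENCODE or cohort
data.

## Validation design notes

A few sizes and constructions in the validation suite are deliberate:

* Property tests run the interval oracles on ≥ 1,000 random instances with
  coordinates below 10,000 and up to 6 tracks — small enough for explicit
  per-base sets, large enough to hit book-ended, nested and multi-chromosome
  edge cases.
* Null calibration uses a 1 Mb i.i.d. genome, a 5,000-region reference and
  2,000 fresh regions; exceedance at $\alpha$ is accepted within
  $3\sqrt{\alpha(1-\alpha)/2000}$.
* Planted-signal checks use sharp motifs of 12–16 positions (16–21 bits).
  The length is chosen so that *chance* consensus occurrences are rare
  relative to the 1e-03 cutoff: a 10-position motif appears exactly by
  chance at rate ≈ 1e-3 per 500 bp region — at the decision boundary
  itself. Where the background genome is regenerated per run (the
  acceptance script), 16 positions are used so that the genome itself is
  consensus-free at any seed (≈ 5e-4 occurrences per Mb); with 12 positions
  roughly one seed in ten would plant a chance site into the genome, and
  the many background regions covering that one locus would drag the 1e-03
  threshold up to consensus level, contaminating the null.
* Allele-specific fixtures break the planted motif at four positions and
  restore it with four SNPs in perfect linkage. A single-mismatch "broken"
  site retains 1/49th of consensus affinity — the same value class as the
  chance single-mismatch sites that populate the null distribution's upper
  tail — whereas a four-mismatch site sits at background level, giving the
  supporting-fraction assertion an order-of-magnitude margin on both sides.

## Limitations

The package scores motifs and regions as given: it performs no peak calling,
no liftOver, no motif discovery, no imputation or phasing, and no
structural-variant handling. Reference distributions assume the scored
regions and the background are drawn from the same genome and length mix;
scoring regions much longer than anything in the sampler extrapolates the
normalization linearly. TBA treats windows independently — cooperative or
competitive binding between sites, and any strand-specific biology, are
outside the model.
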
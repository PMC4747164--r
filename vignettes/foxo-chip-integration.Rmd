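---
title: "FoxoChIP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FoxoChIP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

FoxoChIP implements the downstream integration of transcription-factor
ChIP-seq with matched RNA-seq, modelled on endogenous DAF-16/FOXO
profiling across three *C. elegans* conditions: wild type, the
low-insulin-signalling `daf2` mutant (where DAF-16 enters the nucleus
and binds chromatin), and the `daf16daf2` double mutant (no factor —
the specificity control). This vignette documents the statistical
model of each stage, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the
methodology left them open.

## Coordinates

Internally everything is 1-based, closed-interval `GRanges`, the
Bioconductor convention. Conversions happen only at I/O boundaries:
BED and narrowPeak are read/written as 0-based half-open, GFF3 and
wiggle as 1-based. All distances and offsets are differences of
positions and therefore convention-free.

## Summit metaprofiles

The pipeline order is fixed and enforced by a stage flag on every
`BinTrack`: shift → bin → per-million → input-subtract →
quantile-normalize → (summit matrix | rank transform). Calling a step
out of order is an error, not a warning.

* **Shift.** Single-end reads are shifted 3' by `round(f/2)`, `f`
  being the library mean fragment size (an input, never estimated; the
  original libraries were 171/158/200 bp for WT / `daf2` /
  `daf16daf2`). Half-fragment shifting is the standard single-end
  convention that moves a read end to the fragment midpoint;
  full-fragment shifting is available as a switch. Shifted positions
  are clamped to chromosome bounds.
* **Bin and scale.** 25-bp non-overlapping bins; values scaled by
  10⁶ / (total uniquely mapped reads). The 10⁶ constant is a
  convention — any positive constant cancels in the rank and quantile
  steps that follow.
* **Input subtraction** is elementwise on the per-million scale.
  Negative bins are retained (clipping is an option) because quantile
  normalization follows and clipping would distort the lower tail.
* **Quantile normalization** is classic mean-order-statistic
  normalization over the concatenated genome-wide bin vector
  (delegated to `limma::normalizeQuantiles(ties = TRUE)`): after it,
  every sample has an identical sorted vector; ties receive the mean
  of the replacement values they span.
* **Summit matrix.** The bin containing each summit plus 20 flanking
  bins each side (±500 bp) forms one row; rows are ranked by the
  summit-bin value. Windows crossing a chromosome edge are dropped
  (with a logged count) rather than padded — padding would fabricate
  signal. Column means are the mean read density (MRD) profile.
* **Rank transform.** Genome-wide fractional ranks in (0, 1], mean
  rank for ties. The construction of "ranked normalized reads" was
  underdetermined; fractional genome-wide ranks are this package's
  choice and are invariant under monotone transforms of the input.

One deliberate deviation: the MRD peakedness and flatness statistics
reported by `runPipeline` (summit/edge ratio of the enriched
condition; max/min flatness of the factor-null condition) are computed
on the per-million tracks. Input-subtracted tracks have genome-wide
mean ≈ 0, so ratios of near-zero column means are numerically
meaningless; the subtracted and quantile-normalized tracks are still
produced, stage-checked and exported for cross-sample comparison.

## Peak annotation

Summits are assigned to the closest TSS (over coding and non-coding
genes alike), distance signed in transcription orientation (upstream
negative). The promoter window is −2500 … +300 bp; peaks outside it
are kept with a flag, because the full distance distribution is itself
of interest. Equidistant ties break lexicographically by gene id and
are counted. For cross-condition comparison, peaks are paired when
intervals intersect by ≥ 1 bp, greedily by maximal overlap, each peak
used once — the identity rule is not dictated by the methodology, so
the simplest deterministic one was chosen; summit shifts of common
pairs are signed by the assigned gene's strand.

## Differential expression

RPKM uses the per-sample *total mapped reads*, which the `CountTable`
carries separately from the column sums (the analyzed genes need not
be the whole transcriptome). The two-group test treats each
replicate's count as a proportion of its library total:

* group estimate: the library-size-weighted (pooled) proportion
  p̂ = Σx / Σn — the inverse-variance combination under binomial
  sampling;
* group variance: binomial within-replicate variance p̂(1−p̂)/Σn plus a
  between-replicate component τ² Σn²/(Σn)², with τ² estimated by
  moments from the spread of replicate proportions and truncated at
  zero;
* reference distribution: t with Satterthwaite degrees of freedom,
  where a group whose τ̂² is zero contributes infinite df (its variance
  is then the known binomial one). With single replicates the test
  reduces exactly to the unpooled two-proportion z-test, which pins its
  closed form; its null behaviour is pinned by a 2000-gene, 3 vs 3
  calibration simulation.

"DAF-16-dependent" is operationalized as significance *and* fold in
both contrasts — `daf2` vs WT and `daf2` vs `daf16daf2` — at raw
p ≤ 0.05 and fold ≥ 2 (the classification rule is defined on raw
p-values; Benjamini–Hochberg is available and off by default). Fold changes are ratios of mean RPKM. A gene is "expressed"
when RPKM > 0 in every `daf2` and `daf16daf2` sample.

## Integration statistics

The representation score R is the bound fraction of the DE set over
the bound fraction of the expressed set; the companion overlap test is
the upper-tail hypergeometric probability. The universe is the
expressed-gene set by default (configurable to all genes) — the choice
was open, and expressed genes are the set actually eligible for DE
calls. Stratified fold changes are averaged on the linear scale (log
scale optional). Profile comparisons between expression classes use
two-sided Mann–Whitney U on summit-bin values (exact for small
samples, normal approximation with tie correction otherwise, via
`wilcox.test`), and a degenerate-safe paired Wilcoxon signed-rank
wrapper is provided for paired cross-condition comparisons.

## Motif scanning

PSSMs carry a 0.25 pseudocount per cell before column normalization.
The weight score of a window is Σᵢ log₂ fᵢ(bᵢ) − log₂ P_bg(bᵢ | ctx)
in bits (bits rather than nats — the base was unstated). The
background is an order-m Markov model (default m = 2, trained on the
analyzed genome with +1 pseudocounts per context cell). Within a
window, each base is conditioned on the preceding bases *of the same
window*, the first m bases falling back to the marginal composition —
this makes the score a function of the window content alone and
exactly matches the null model used for p-values.

Match p-values are computed on an integer grid of 0.01-bit steps. For
order 0 the null distribution of the discretized score is exact, by
dynamic-programming convolution of the per-column score distributions;
it is pinned against full enumeration for a length-4 matrix. For
order ≥ 1 the null is a seeded Monte-Carlo draw of 10⁶ window
sequences from the Markov chain started at its stationary context
distribution; p-values below 10⁻⁶ are reported as 0 (below the
resolution of the draw). Scanning is best-match-per-sequence by
default (at most one true site per sequence was the stated
assumption); ties break to the leftmost center, then the + strand.
Windows containing N are skipped.

Enrichment compares best-hit frequencies in peak windows
(summit ± 250 bp) against the same number of random promoter windows
sampled from the same annotation (seeded; 250–1250 bp upstream of
random TSSs): r is the ratio at the p ≤ 10⁻⁵ match threshold, the
curve is reported on a 0.5-bit threshold grid, and an unpaired t-test
compares the two frequency profiles. Inter-motif distances are
differences of match central coordinates, signed by the promoter's
strand, histogrammed in 10-bp bins.

**Motif width.** The planted defaults are 10-mers: `TTGTAAACAA`
(the DBE core `GTAAACAA` with its TT flank) and `ACTGATAAGA` (a
GATA-type co-motif). The core consensus alone is 8 bp, and an 8-bp
window has a hard p-value floor — the probability of the single most
favourable window under the background, ≈ 3.5 × 10⁻⁵ at 36% GC —
that lies *above* the fixed 10⁻⁵ match threshold, so no 8-column
matrix can ever yield a significant match. Scanned matrices in
practice are de-novo discovered PSSMs wider than the core; the 10-mer
defaults represent that while keeping the published core intact. Any
consensus remains configurable.

## The synthetic-data generator

`simulationConfig()` defines the study the tests run against; all
randomness flows from one seed and outputs are byte-reproducible.

* **Genome and genes.** I.i.d. bases at 36% GC (the *C. elegans*
  average); 300 gene models of 1.5 kb (two exons) tiled at ≥ 5 kb
  spacing on 2 × 0.8 Mb chromosomes, random strand.
* **Binding.** 30% of genes are "bound": a motif instance is planted
  with its center at 250 or 750 bp upstream of the TSS (cycling),
  random strand; 60% of bound promoters also get the co-motif 35 bp
  downstream of the primary motif center in promoter orientation. The
  planted center is the ground-truth summit.
* **ChIP reads.** Enriched fragment midpoints ~ Normal(summit,
  fragment/4), background uniform; each fragment is reported as one
  36-bp single-end read from a uniformly chosen end. Enrichment is
  10× local coverage in `daf2`, half the excess in WT, and forced to
  1 (background only) in `daf16daf2`. Matched input libraries are
  uniform. Emitted peaks carry the planted summit and the enrichment
  as height.
* **Expression.** Per-gene lognormal baselines (median 100 counts,
  sdlog 0.8); counts are negative binomial with dispersion 0.02;
  activated genes ×4 in `daf2` only, repressed ×1/4, everything at
  baseline in WT and the factor-null. 80% of bound genes are
  activated, 5% of unbound genes are activated (indirect targets),
  and 10% of the remaining unbound genes are repressed — so repression
  is decoupled from binding, as observed for this activator. Library
  totals are fixed at 2 × 10⁶ (the genes are a transcriptome subset);
  letting totals equal the 300-gene column sums would make ~27% of
  counts differential and compress every measured fold change by the
  resulting compositional shift. The dispersion default (0.02, tight
  isogenic replicates) is the value at which the generator's own
  planted fold-4 effect is recoverable at ≥ 90% under the fold ≥ 2,
  p ≤ 0.05 rule with 3 replicates; at 0.05 the same design has only
  ~84% per-contrast power.

What the generator does **not** emulate: mappability and repeat
structure, sequencing error, fragment-size variation between
libraries, GC bias, peak-width heterogeneity, correlated gene
expression, isoforms, and batch effects. Passing tests therefore
demonstrate correctness of the statistical machinery on data matching
its assumptions, not robustness to the full messiness of real
libraries.

## Problem sizes and determinism

The default study (300 genes, 90 peaks, 6 × 2 × 10⁵ ChIP/input reads,
9 RNA-seq libraries) runs end to end in well under a minute and is
the size used by the end-to-end tests and the acceptance script;
Monte-Carlo nulls use 10⁶ draws. Two runs with the same config and
seed produce byte-identical summary JSON — every stage derives its
seed from the config seed.

## Known limitations

* The exact Baggerley software was not reproduced; the test is
  reconstructed from its description (weighted beta-binomial t) and
  pinned by its single-replicate closed form and null calibration.
* Monte-Carlo match p-values for order ≥ 1 backgrounds have draw-count
  resolution (10⁻⁶); exact DP is order-0 only.
* The cross-condition peak identity rule (≥ 1 bp overlap, greedy) and
  the hypergeometric universe are package choices where the
  methodology was silent; both are configurable or documented above.
* BAM input is out of scope; reads come as BED6 (or SAM text, mapped
  primary records only).
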
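# FoxoChIP

Integrated downstream analysis of transcription-factor ChIP-seq with
matched RNA-seq, built around the genome-wide recruitment of endogenous
DAF-16/FOXO in *C. elegans* insulin/IGF-1-signalling (IIS) mutants.
The package is for computational biologists who have called peaks and
counted reads and now want the integration layer: where does the factor
sit relative to transcription start sites, which genes respond, how
strongly does proximity of binding predict the transcriptional
response, and is the binding motif really there?

All of it runs on synthetic data with planted ground truth, generated
by the package itself, so every stage can be validated end to end.

## What it computes

**Summit metaprofiles.** Single-end reads are shifted 3' by half the
library's mean fragment size, counted in 25-bp bins, scaled to reads
per million, input-subtracted and quantile-normalized across samples.
For each peak summit the surrounding ±20 bins form one row of a
summit-centered matrix; the column means are the mean read density
(MRD) profile:

```
MRD(k) = (1/P) Σ_p  x_p(summit_bin + k),   k = -20 … 20
```

**Peak annotation.** Each summit is assigned to the gene minimizing
|summit − TSS|, with distances signed in transcription orientation; a
peak is promoter-associated when −2500 ≤ d ≤ +300 bp. Distances are
banded at 500 bp for stratified analyses.

**Differential expression.** RPKM = count · 10⁹ / (exon length ·
library total). Per-gene proportions p̂ = Σx / Σn are compared between
conditions with a beta-binomial (Baggerley-style) test: group variance
is the binomial within-replicate variance plus a moment-estimated
between-replicate component, and

```
t = (p̂_a − p̂_b) / sqrt(V_a + V_b)
```

is referred to a t distribution with Satterthwaite-style degrees of
freedom (a two-proportion z-test when each group has one replicate).
A gene is *activated* when it rises ≥ 2-fold (p ≤ 0.05) in the
low-IIS mutant both against wild type and against the factor-null
double mutant — i.e. the response is DAF-16-dependent; *repressed*
mirrors this.

**Integration.** With DEG the differentially expressed genes and DDEG
those that additionally carry a promoter-window peak, the
representation score is

```
R = (n_DDEG / n_DEG) / (n_bound,expressed / n_expressed)
```

with an upper-tail hypergeometric p-value for the overlap, plus
distance-stratified mean fold changes and Mann–Whitney comparisons of
binding profiles between expression classes.

**Motif analysis.** PSSMs are scored as log₂ likelihood ratios against
an order-m Markov background; match p-values come from an exact
dynamic program over the discretized column-score distribution (order
0) or a seeded Monte-Carlo draw (order ≥ 1). Peak windows (summit
± 250 bp) are scanned best-match-per-sequence at p ≤ 10⁻⁵; enrichment
r is the match frequency in peaks over that in matched random promoter
windows; co-occurring motifs get strand-aware inter-motif distance
histograms.

## Worked example

```r
library(FoxoChIP)

config <- simulationConfig(seed = 1)   # 300 genes, 30% bound, fold-4 activation
run <- runPipeline(config)
str(run$summary[c("n_peaks", "n_activated", "n_direct_targets",
                  "representation_score_activated", "hypergeom_p_activated",
                  "mrd_center_edge_ratio", "motif_enrichment_r",
                  "intermotif_mode")])
```

prints

```
List of 8
 $ n_peaks                       : int 90
 $ n_activated                   : int 80
 $ n_direct_targets              : int 70
 $ representation_score_activated: num 2.91
 $ hypergeom_p_activated         : num 1.33e-38
 $ mrd_center_edge_ratio         : num 15.3
 $ motif_enrichment_r            : num 12.9
 $ intermotif_mode               : num 35
```

Reading: the 90 planted peaks are recovered; 80 genes are called
DAF-16-dependently activated, 70 of them direct targets (activated
*and* promoter-bound), an almost 3-fold enrichment over chance
(R = 2.91, hypergeometric p ≈ 10⁻³⁸). The MRD profile at summits is
15-fold above its ±500 bp edges, the planted motif is 13-fold enriched
in peak windows over random promoters, and the co-motif sits at the
planted +35 bp spacing. Repressed genes show no binding overlap
(`run$summary$hypergeom_p_repressed` is 1), mirroring the biology of
an activator.

A command-line wrapper is installed at
`system.file("scripts", "fci", package = "FoxoChIP")` with
`simulate | profile | annotate | de | scan | integrate | run | validate`
subcommands driven by a YAML config.

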
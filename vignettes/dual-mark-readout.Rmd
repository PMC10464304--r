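---
title: "Quantifying double-histone-mark readout: models, pipeline and design choices"
author: "dualmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying double-histone-mark readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmark)
```

# The scientific problem

Chromatin reader domains are usually characterised against single histone
marks, but some readers respond to *combinations*.  The motivating case is
the UHRF1 Tandem-Tudor domain (TTD): a classical H3K9me2/3 reader that
binds H3 tails carrying K4me1 *together with* K9me2/3 more strongly than
K9me2/3 alone.  Establishing such a double-mark readout needs two very
different kinds of quantitative evidence, and this package implements
both:

1. **Solution binding**: equilibrium dissociation constants from
   fluorescence-anisotropy (FA) titrations of labelled peptides, for a
   wild-type reader and a panel of binding-pocket mutants, summarised as
   preference ratios (single-mark K~D~ / double-mark K~D~) and
   mutation-effect ratios (K~D~^WT^ / K~D~^mut^).
2. **Genome-wide co-occurrence**: given coverage tracks for the reader
   and the two marks, show that the reader follows one mark
   (H3K4me1) *conditionally* on the other (H3K9me2) — via
   decile-conditioned correlation, mononucleosome-scale fragmentation
   with clustering, and shuffle-null interval enrichment — and connect
   the double mark to gene regulation through a differential-expression
   stage.

Everything runs against a seeded synthetic-genome generator, so the full
chain is testable end to end without external downloads.

# Binding models

## Hyperbolic isotherm

For a titration of labelled peptide (concentration $c_{pep}$) with
protein at total concentration $c$, when $c_{pep} \ll K_D$ the anisotropy
change follows the binary equilibrium hyperbola

$$\Delta r = BL + F \frac{c}{c + K_D},$$

with baseline $BL$ and amplitude $F$ (`model_simple()`).  The fraction of
peptide bound is $\Theta = (\Delta r - BL)/F$, which equals $1/2$ exactly
at $c = K_D$.

## Ligand-depletion isotherm

When $K_D$ is comparable to or below $c_{pep}$ (here: fits below 100 nM
at the 100 nM labelled-peptide concentration of the FA assay), bound
peptide depletes the free-protein pool and the hyperbola is biased
upward by roughly $c_{pep}/2$.  The exact mass balance for
$P + L \rightleftharpoons PL$ gives a quadratic in $\Theta$ whose
physical root is

$$\Theta = A - \sqrt{A^2 - c/c_{pep}}, \qquad
  A = \frac{K_D + c_{pep} + c}{2\,c_{pep}},$$

implemented in `model_depletion()`.  The typeset form of this equation
in common sources is easily garbled; we therefore validate the
implementation against an independent bisection root-finder on the
complex concentration (see `test-binding.R`), and against the hyperbola
in the $c_{pep}/K_D \to 0$ limit (relative deviation $< 10^{-3}$ at
$c_{pep} = 10^{-4} K_D$).

## Fitting and the auto rule

`fit_curve()` estimates $(K_D, BL, F)$ by Levenberg–Marquardt nonlinear
least squares (via \pkg{minpack.lm}), with $K_D$ parameterised on the
log scale and multi-start initialisation ($K_D$ at the minimum,
geometric mean and maximum of the concentration grid; $BL$ at the first
point; $F$ at the observed span).  The multi-start matters for the
depletion model, whose objective can have shallow local minima.
Convergence tolerance is $10^{-8}$ on the relative parameter change.

In `"auto"` mode the hyperbola is fitted first; if the fitted $K_D$
falls below 100 nM the curve is refitted with the depletion model and
that fit is reported — a literal implementation of the assay
convention.  One consequence worth knowing: a true $K_D$ near
$c_{pep}/2$ sits at the decision boundary (its hyperbolic apparent
$K_D \approx K_D + c_{pep}/2 \approx 100$ nM), so either model may be
chosen under noise.  Flat curves (response range at numerical zero) are
rejected as degenerate rather than fitted.

## Replicate pooling and its confidence intervals

`pool_replicates()` reproduces the spreadsheet convention used in
wet-lab practice: the pooled value is the arithmetic mean, and the 95%
half-width is `CONFIDENCE.NORM`, i.e.
$z_{0.975}\,\hat\sigma_{pop}/\sqrt{n}$ with the *population*
(divide-by-$n$) standard deviation.  We implement this convention
faithfully because it is what published K~D~ tables report — but it is
worth being explicit about its statistical behaviour: with $n = 2$
replicates a $z$-interval with a plug-in SD is far narrower than a
proper $t$-interval (whose $n = 2$ critical value is 12.7, not 1.96).
Writing the interval's coverage condition in terms of the sum and
difference of the two replicate errors shows the true coverage is
$\tfrac{2}{\pi}\arctan(1.386) \approx 60\%$, independent of the noise
scale.  The package's coverage simulation (500 replicate pairs at true
$K_D = 680$ nM, anisotropy noise calibrated to a 5% per-fit CV)
measures exactly this and lands near 57–63%, not at the nominal 95%.
We report the convention as used, and the measured coverage as a known
property of it.

The anisotropy noise level for that simulation, `noise_sd = 0.0013`
(with $F = 0.1$, $BL = 0.05$, a 12-point 0–10 µM scheme), was fixed
once by calibrating the per-fit K~D~ CV to 5% and is not revisited.

## Ratio display

`preference_ratio()` and `mutation_effect()` compute unrounded
internally; `display_round()` applies the reporting convention of
published affinity panels — two significant figures, one below 0.1.
Published ratio columns for a few extreme-affinity mutants (D142N,
E153A, E153Q) are not exactly reproducible from their printed rounded
K~D~ values; the package always derives ratios from its own unrounded
numbers.

# The synthetic genome

`generate_tracks()` emulates the *structure* of the real data rather
than the sequencing process: it emits normalised coverage (bedGraph),
not reads — no fragment-length, GC or read-noise modelling.  The
default study conditions are:

* **Genome**: 2 chromosomes × 2.5 Mb at 10 bp track resolution —
  5,000 one-kb analysis bins, large enough for stable decile
  statistics, small enough for seconds-scale tests.
* **H3K9me2**: broad domains, widths uniform in 0.2–0.6 Mb (the
  megabase-block character of the mark, scaled to the toy genome),
  covering 40% of the genome — the mark is the most abundant H3
  methylation and forms very broad blocks in real chromatin.
* **H3K4me1**: 0.5–2 kb peaks covering 4% of the genome, half of them
  placed inside K9me2 domains (parameter `k4me1_in_domain`), the rest
  outside — the double-mark and single-mark feature classes.
* **H3K9me3**: 10–50 kb blocks covering 8%.
* **Feature signal**: a masked moving-average of the feature indicator
  (5 bins) times the mark's level, so edges taper *inside* the feature
  and the signal support equals the truth intervals exactly; plus
  background 0.2 and Gaussian noise (SD 0.3).
* **Reader coupling** (`coupling_spec()`): the TTD-like track is
  $\alpha\,\mathrm{K4me1}\cdot\mathbf 1[\mathrm{K9me2\ dom}] +
  \gamma\,\mathrm{K4me1}\cdot\mathbf 1[\mathrm{K9me3\ dom}] +
  \beta\,\mathrm{K9me2} + \varepsilon$, floored at zero, with defaults
  $\alpha = 1$, $\beta = 0.1$, $\gamma = 0.5$ — the inferred binding
  rule: the reader follows K4me1 where a broad K9me2/3 context is
  present, with a weak K9me2-alone component.

All randomness flows from the single `genome_spec()` seed through fixed
per-track substreams, so any fixture is reproducible bit for bit.

What passing tests on this generator do **not** show: robustness to
mappability artifacts, copy-number variation, antibody efficiency
differences between tracks, or the read-depth-dependent noise of real
ChIP/CIDOP data.  The pipeline consumes any bedGraph, but the
acceptance-level guarantees are statements about the planted structure.

`generate_annotations()` paints a gap-free chromatin-state partition
(Quiescent background, Heterochromatin over the K9me2 domains,
FlankingTSS around sampled TSSs, Enhancer last and therefore with
priority), places enhancers over planted K4me1 peaks with probability
`fidelity` (default 0.9), and assigns each enhancer to a gene.
`generate_expression()` simulates the two-channel rescue design:
probe-level log2 fold changes versus mock for a wild-type rescue and a
reader-dead (TTD*) rescue, a planted set of genes (default 115) that
are WT-non-responsive but upregulated (default 2-fold) under TTD*, a
disjoint WT-responsive set, and a $+\delta$ SD K4me1 shift (default 2)
on the planted genes' enhancers.

# The co-occurrence pipeline

All interval logic is 0-based half-open on disk and 1-based closed
internally (GenomicRanges); adjacency is never an overlap.  Specific
conventions, chosen where upstream tools disagree:

* **Binning** (`bin_genome()`): tiles from 0, keeps the trailing short
  bin, and *removes* (does not clip) any bin touching the blacklist, so
  retained bins have uniform width.  `quantile_split()` additionally
  drops trailing bins shorter than half the modal width before
  grouping, to avoid short-bin mean artifacts; both behaviours are
  configurable.
* **Decile split**: stable descending sort by the ranking mark, ties
  broken by genomic order, group sizes differing by at most one with
  the larger groups first; group 1 is the highest-signal decile.
  `conditional_correlation()` then computes Pearson r per group — raw
  bin means, no log transform (log2 ratio tracks go through
  `log2_ratio_track()` explicitly when wanted).
* **Fragmentation** (`fragment_peaks()`): genome-aligned 150 bp tiles
  kept iff they overlap the peak union by $\ge$ 50% of the tile
  (inclusive at exactly 75 bp) — mononucleosome-sized fragments, so
  co-occurring signal on one fragment indicates both marks on one
  nucleosome.
* **Clustering** (`cluster_fragments()`): k-means on per-track fragment
  means with columns standardised (track scales differ), 10 restarts
  under a fixed seed, clusters renumbered by decreasing mean of the
  ordering track so "cluster 1" is always the strongest.
* **Shuffle null** (`shuffle_intervals()`): conserves the length
  multiset exactly, places uniformly (chromosomes weighted by the
  number of valid starts), avoids the blacklist by rejection, and
  allows shuffled intervals to overlap each other — the behaviour of
  the standard shuffle tool.  Enrichment ratios are count-based
  (regions touched by $\ge$ 1 bp), and empirical p-values use the
  add-one estimator $(1 + \#\{null \ge obs\})/(1 + n)$ so no p is
  exactly zero at small permutation counts.
* **Region matrices** (`region_matrix()`): midpoint ± flank split into
  equal windows, base-weighted means per cell, out-of-chromosome
  windows as missing values, rows ordered by decreasing row mean of a
  caller-chosen track.

On the default synthetic genome the chain reproduces the planted
qualitative pattern: the TTD–K4me1 correlation is near 1 in the top
K9me2 decile and near 0 in the bottom (gap well above 0.3); 3-means on
the fragments recovers the planted classes (K4me1-in-domain,
K9me2-only, K4me1-only) with adjusted Rand index above 0.9; and the
highest-TTD cluster is the double-mark class.

# The expression stage

`gene_medians()` collapses probes to per-gene medians (merging
duplicate symbols).  `call_drgs()` applies the 1.5-fold threshold on
the linear scale via $|\log_2 FC| \ge \log_2 1.5$, boundary inclusive —
the inputs are log2-scale fold changes while the published threshold is
linear, and whether the original boundary was strict is not stated; we
use $\ge$ and say so.  The three sets (up, down, non-responder)
partition the gene universe.  `ttd_dependent_set()` is the WT
non-responders intersected with the TTD* up-set, in that order: a gene
that responds to the functional rescue is excluded regardless of its
TTD* behaviour.

`mark_association()` compares enhancer mark levels between gene groups
with the classical equal-variance one-way ANOVA (a Welch option exists
but the classical F mirrors the stated method) and
Bonferroni-multiplied pairwise t-tests.  With two groups the F
statistic is exactly the squared pooled t statistic — asserted in the
tests.  Under a null with no planted shift its p-value is uniform
(Kolmogorov–Smirnov check over 1000 simulated designs), and at the
planted $+2$ SD shift with 100 enhancers per group it rejects at
$p \le 0.05$ essentially always.

`expression_ratio_bins()` implements the two-cell-type filter
(ratio $\ge 2$ or $\le 1/2$ in either direction AND $\ge 1000$
expression units in at least one cell type) and the ascending-ratio
split into five near-equal bins, ties broken by gene name.

# Problem sizes and determinism

The test-suite and acceptance computations use: a 5-Mb toy genome
(5,000 1-kb bins, ~14,000 150-bp fragments), 500 replicate pairs for
the CI-coverage simulation, 200 shuffles for null calibration, 100
simulated designs for association power and 1000 for null uniformity.
These sizes give stable Monte-Carlo statistics at seconds-to-a-minute
runtimes.  Every stochastic step takes an explicit seed; the pipeline
driver (`run_pipeline()`) records parameters, seed and output digests
in a provenance file, and identical configurations produce
byte-identical reports.

# Known limitations

* Coverage tracks are held base-resolution in memory (run-length
  encoded); desk-scale genomes up to tens of Mb are comfortable, a full
  mammalian genome at 10 bp resolution is not the target.
* No peak calling: peaks are consumed as intervals (BED), matching the
  division of labour in the original workflow.
* No normalisation of raw arrays or read data: the expression stage
  consumes pre-processed log2 fold changes, and the genome stage
  consumes normalised coverage.
* The ligand-depletion model assumes one binding site and no
  cooperativity; no global multi-curve fitting across replicates.
* The published genome-scale numbers (genome-wide r values, enhancer
  overlap percentages, per-decile bin counts, the real 115-gene list)
  depend on specific reference data and are represented here by the
  planted-structure substitutes described above, not reproduced.
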
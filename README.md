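# dualmark

Analysis toolkit for **double-histone-mark readout** by chromatin reader
domains, modelled on the UHRF1 Tandem-Tudor domain (TTD), which binds H3
tails carrying **K4me1 together with K9me2/3** more strongly than
K9me2/3 alone.

The package implements the two quantitative layers such a claim rests
on, plus a synthetic-data generator so the whole chain runs and is
tested without external downloads:

1. **Equilibrium binding** — fluorescence-anisotropy titration fitting
   with the hyperbolic isotherm
   `Δr = BL + F·c/(c + K_D)`
   and the exact ligand-depletion isotherm
   `Θ = A − √(A² − c/c_pep)`, `A = (K_D + c_pep + c)/(2·c_pep)`
   (used when the fitted K_D falls below 100 nM at 100 nM labelled
   peptide), replicate pooling with the spreadsheet CI convention
   (`CONFIDENCE.NORM` / `STDEV.P`), and the preference
   (K_D^single / K_D^double) and mutation-effect (K_D^WT / K_D^mut)
   ratio panels.
2. **Genome-wide co-occurrence** — coverage tracks as run-length-encoded
   per-base vectors; fixed-width binning excluding a blacklist;
   decile-conditioned Pearson correlation (does the reader follow
   H3K4me1 *only where* H3K9me2 is high?); 150-bp mononucleosome-scale
   peak fragmentation with k-means clustering; shuffle-null
   chromatin-state and peak-overlap enrichment; region-centred signal
   matrices.
3. **Expression stage** — probe-to-gene medians, differential-regulation
   calling at |FC| ≥ 1.5, the reader-dependent gene set
   (WT-non-responders ∩ reader-dead-rescue-upregulated), and the
   enhancer-mark association test (one-way ANOVA with Bonferroni
   pairwise comparisons).

Built on GenomicRanges/IRanges for interval arithmetic and minpack.lm
for nonlinear least squares.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_binding_panel.R
Rscript analysis/02_simulate_genome.R
Rscript analysis/03_cooccurrence.R
Rscript analysis/04_expression_stage.R
```

`01_binding_panel.R` simulates two replicate titrations per
peptide/variant at the published affinities, fits them with the auto
model rule and prints the pooled panel:

```
Fitted 12 replicate curves; 2 used the ligand-depletion model
Preference ratios (KD single / KD double), display-rounded:
 variant_id  KD_single  KD_double ratio_disp
         WT   732.4306 299.741925        2.4
      E153A 14585.0123   2.416368     6000.0
      R207E   267.6098 336.425895        0.8
```

The wild-type ratio near 3 is the double-mark stimulation; E153A's
enormous ratio reflects its collapse of single-mark binding with
retained double-mark binding; R207E (ratio < 1) has lost the
preference.  (The fitted single-mark K_D values sit ~50 nM above the
generating truth because these curves are fitted with the hyperbola at
100 nM peptide — exactly the regime the depletion model corrects when
the auto rule triggers it.)

`03_cooccurrence.R` then shows the genomic signature of the same
readout on the simulated 5-Mb genome:

```
r(TTD, K4me1): 0.99 in the top K9me2 decile, 0.05 in the bottom
genome-wide 2-kb r: TTD-K4me1 0.65, TTD-K9me2 0.39
Cluster centres (TTD order):
    TTD K4me1 K9me2
1 10.47  9.92  5.20
2  0.53  0.27  5.20
3  0.38  9.86  0.25
Enhancer-state enrichment ratio: 12.0 (p = 0.020)
```

The reader correlates with H3K4me1 almost perfectly inside
H3K9me2-rich deciles and not at all outside them, and the
strongest-reader fragment cluster (1) is the class carrying *both*
marks — clusters 2 and 3 carry one mark each and little reader signal.

`04_expression_stage.R` closes the loop with gene regulation:

```
1800 WT non-responders; 115 of them upregulated under the reader-dead rescue
Recovered 115 of 115 planted genes
Enhancer K4me1, reader-dependent vs non-responders: F = 489.4, p = 4.15e-96
```

## Layout

```
R/                  package code (binding, tracks, genome, synthetic
                    generator, expression, io, pipeline driver)
analysis/           numbered narrative drivers (see worked example)
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, conventions, design choices
```
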
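Package: dualmark
Title: Histone Double-Mark Readout: Binding Isotherms and Genome-Wide
    Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for studying chromatin reader domains that
    recognise two histone marks at once, modelled on the UHRF1 Tandem-Tudor
    domain reading H3K4me1 together with H3K9me2/3.  Provides equilibrium
    binding-model fitting of fluorescence-anisotropy titrations (simple
    hyperbolic and exact ligand-depletion isotherms, replicate pooling with
    spreadsheet-convention confidence intervals, preference and
    mutation-effect ratio panels), a genome-wide co-occurrence pipeline over
    coverage tracks (binning, pooling, decile-conditioned Pearson
    correlation, mononucleosome-scale peak fragmentation with k-means
    clustering, shuffle-null interval enrichment, region-centred signal
    matrices), a microarray differential-regulation stage with
    enhancer-mark association testing, and a seeded synthetic-genome
    generator so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    data.table,
    minpack.lm,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
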
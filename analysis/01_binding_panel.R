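#!/usr/bin/env Rscript
# Equilibrium binding layer: simulate anisotropy titrations for a small
# panel of reader-domain variants at their published affinities, fit
# each replicate with the auto model rule (hyperbolic first, exact
# ligand-depletion refit when the fitted KD drops below 100 nM at
# 100 nM labelled peptide), pool replicates, and derive the
# double-vs-single preference and mutation-effect ratios.
#
# Writes results/binding/{fits,panel}.tsv

suppressPackageStartupMessages(library(dualmark))
outdir <- "results/binding"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

# published mean KDs (nM) used as generating truth for the simulation
panel_truth <- list(
  WT    = c(single = 680,   double = 240),
  E153A = c(single = 16000, double = 2),
  R207E = c(single = 220,   double = 270))

rows <- list()
for (variant in names(panel_truth)) {
  for (pep in c("single", "double")) {
    pid <- if (pep == "single") "H3K9me3" else "H3K4me1-K9me3"
    for (r in 1:2) {
      cv <- simulate_titration(
        binding_params(panel_truth[[variant]][[pep]], BL = 0.05, F = 0.10),
        c_pep = 100, conc_scheme = titration_scheme(),
        noise_sd = 0.0013, model = "depletion",
        seed = seed + 7L * nchar(variant) + 13L * nchar(pid) + r,
        peptide_id = pid, variant_id = variant,
        replicate_id = paste0("rep", r))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = paste0("rep", r), peptide_id = pid,
        variant_id = variant, peptide_conc_nM = 100,
        protein_conc_nM = cv$protein_conc, anisotropy = cv$anisotropy)
    }
  }
}
curves <- do.call(rbind, rows)

fits <- fit_titration_table(curves, model = "auto")
write_tsv_report(fits, file.path(outdir, "fits.tsv"))

panel <- preference_panel(fits, wt = "WT", single = "H3K9me3",
                          double = "H3K4me1-K9me3")
write_tsv_report(panel, file.path(outdir, "panel.tsv"))

cat("Fitted", nrow(fits), "replicate curves;",
    sum(fits$model == "depletion"), "used the ligand-depletion model\n")
cat("Preference ratios (KD single / KD double), display-rounded:\n")
print(panel[, c("variant_id", "KD_single", "KD_double", "ratio_disp")],
      row.names = FALSE)
cat("The wild-type double-mark preference lands near the published",
    "threefold stimulation; R207E loses it (ratio < 1).\n")
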
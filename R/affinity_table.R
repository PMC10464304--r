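#' Published UHRF1-TTD affinity panel
#'
#' The published equilibrium dissociation constants (mean and 95% CI, nM)
#' of the UHRF1 Tandem-Tudor domain and its binding-pocket mutants for
#' H3(1-19) peptides carrying K9me3 alone or the K4me1-K9me3 double mark,
#' measured by fluorescence anisotropy.  These printed values are inputs to
#' the ratio arithmetic ([preference_ratio()], [mutation_effect()]); the
#' package's own fits on synthetic titrations live in [preference_panel()].
#'
#' @return Data frame with columns `variant_id`, `KD_single`, `CI_single`,
#'   `KD_double`, `CI_double` (nM).
#' @examples
#' tab <- ttd_affinity_table()
#' with(tab[tab$variant_id == "WT", ],
#'      preference_ratio(KD_single, KD_double, display = TRUE))
#' @export
ttd_affinity_table <- function() {
  data.frame(
    variant_id = c("WT", "D142A", "D142E", "D142N", "E153A", "E153D",
                   "E153Q", "R207A", "R207L", "R207Q", "R207H", "R207E",
                   "A208G", "M224A", "F278A"),
    KD_single  = c(680, 4900, 980, 4500, 16000, 640, 13000, 900, 900,
                   1600, 9700, 220, 9500, 1400, 7900),
    CI_single  = c(18, 300, 120, 200, 490, 40, 4600, 110, 130, 230, 1150,
                   20, 1600, 270, 1600),
    KD_double  = c(240, 2700, 580, 2, 2, 50, 250, 370, 440, 390, 460, 270,
                   2400, 430, 3900),
    CI_double  = c(50, 220, 4, 0.1, 1, 19, 55, 52, 14, 70, 10, 36, 180,
                   45, 710))
}

#' Published reference affinities for the LIG1 comparison
#'
#' Printed dissociation constants for TTD binding the LIG1-K126me3 peptide
#' (9 nM) versus the H3K9me3 peptide (1600 nM, literature value used for
#' that comparison), whose ratio quantifies the >100-fold stronger binding
#' of the LIG1 peptide.
#'
#' @return Named numeric vector (nM): `LIG1K126me3`, `H3K9me3`.
#' @export
lig1_reference_kds <- function() {
  c(LIG1K126me3 = 9, H3K9me3 = 1600)
}
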
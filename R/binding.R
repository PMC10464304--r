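#' Binding model parameters
#'
#' Container for the three parameters of the equilibrium binding isotherms:
#' the dissociation constant `KD` (nM), the baseline anisotropy `BL`
#' (arbitrary units), and the signal amplitude factor `F` (arbitrary units,
#' the anisotropy change at saturation).
#'
#' @param KD Dissociation constant in nM; must be > 0.
#' @param BL Baseline anisotropy.
#' @param F Signal factor; any sign, but exactly 0 is rejected as degenerate.
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(KD = 680, BL = 0.05, F = 0.10)
#' @export
binding_params <- function(KD, BL = 0, F = 1) {
  if (!is.numeric(KD) || length(KD) != 1L || !is.finite(KD) || KD <= 0)
    stop("invalid parameter: KD must be a single finite value > 0")
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F) || F == 0)
    stop("invalid parameter: F must be a single finite nonzero value")
  if (!is.numeric(BL) || length(BL) != 1L || !is.finite(BL))
    stop("invalid parameter: BL must be a single finite value")
  structure(list(KD = KD, BL = BL, F = F), class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("<binding_params> KD = %.4g nM, BL = %.4g, F = %.4g\n",
              x$KD, x$BL, x$F))
  invisible(x)
}

#' Simple binary equilibrium binding isotherm
#'
#' Hyperbolic (no ligand depletion) model of the anisotropy change in a
#' fluorescence-anisotropy titration:
#' \deqn{\Delta r = BL + F \cdot \frac{c_{prot}}{c_{prot} + K_D}}
#' Valid when the labelled peptide concentration is small relative to
#' `KD`, so that free and total protein concentration coincide.
#'
#' @param c_protein Total protein concentration(s) in nM; non-negative.
#' @param params A [binding_params()] object.
#' @return Anisotropy change, same length as `c_protein`.
#' @seealso [model_depletion()] for the exact mass-balance isotherm.
#' @examples
#' model_simple(720, binding_params(KD = 240))  # fraction bound 0.75
#' @export
model_simple <- function(c_protein, params) {
  params <- as_binding_params(params)
  if (any(!is.finite(c_protein)) || any(c_protein < 0))
    stop("invalid parameter: c_protein must be finite and >= 0")
  params$BL + params$F * c_protein / (c_protein + params$KD)
}

#' Ligand-depletion (exact two-component) binding isotherm
#'
#' Exact solution of the binary equilibrium mass balance
#' P + L <-> PL at total concentrations `c_protein` and `c_pep`.  The
#' fraction of peptide bound is the root of the quadratic
#' \eqn{\Theta^2 - 2A\Theta + c_{prot}/c_{pep} = 0} that lies in [0, 1):
#' \deqn{\Theta = A - \sqrt{A^2 - c_{prot}/c_{pep}}, \quad
#'       A = \frac{K_D + c_{pep} + c_{prot}}{2\,c_{pep}}}
#' and the signal is `BL + F * Theta`.  Required when `KD` is comparable
#' to or below the labelled-peptide concentration (here, fits with
#' KD < 100 nM at 100 nM peptide), where the hyperbolic model is biased.
#'
#' @inheritParams model_simple
#' @param c_pep Total labelled peptide concentration in nM; > 0.
#' @return Anisotropy change, same length as `c_protein`.
#' @examples
#' p <- binding_params(KD = 9)
#' model_depletion(100, c_pep = 100, p)
#' @export
model_depletion <- function(c_protein, c_pep, params) {
  params <- as_binding_params(params)
  if (!is.numeric(c_pep) || length(c_pep) != 1L || !is.finite(c_pep) ||
      c_pep <= 0)
    stop("invalid parameter: c_pep must be a single finite value > 0")
  if (any(!is.finite(c_protein)) || any(c_protein < 0))
    stop("invalid parameter: c_protein must be finite and >= 0")
  params$BL + params$F * fraction_bound(c_protein, c_pep, params$KD)
}

# Exact fraction of peptide bound from the mass-balance quadratic.
fraction_bound <- function(c_protein, c_pep, KD) {
  A <- (KD + c_pep + c_protein) / (2 * c_pep)
  rad <- A^2 - c_protein / c_pep
  # exact radicand is >= (KD/(2 c_pep))^2 > 0; tolerate rounding only
  if (any(rad < -1e-8))
    stop("internal consistency error: negative radicand in depletion model")
  pmax(A - sqrt(pmax(rad, 0)), 0)
}

as_binding_params <- function(params) {
  if (inherits(params, "binding_params")) return(params)
  if (is.list(params) && all(c("KD", "BL", "F") %in% names(params)))
    return(binding_params(params$KD, params$BL, params$F))
  stop("invalid parameter: expected a binding_params object")
}

#' Construct a titration curve
#'
#' One replicate's titration of a labelled peptide with a reader-domain
#' protein: ordered (protein concentration, anisotropy change) pairs, with
#' identifying labels and the fixed labelled-peptide concentration.
#'
#' @param protein_conc Protein concentrations in nM; non-negative, strictly
#'   increasing, length >= 5 for fitting.
#' @param anisotropy Anisotropy change at each concentration.
#' @param peptide_id,variant_id,replicate_id Labels (e.g. "H3K9me3", "WT",
#'   "rep1").
#' @param peptide_conc Labelled peptide concentration in nM (instrument
#'   default 100).
#' @return A `titration_curve` object (a data.frame with attributes).
#' @export
titration_curve <- function(protein_conc, anisotropy,
                            peptide_id = "peptide", variant_id = "WT",
                            replicate_id = "rep1", peptide_conc = 100) {
  if (length(protein_conc) != length(anisotropy))
    stop("invalid input: protein_conc and anisotropy lengths differ")
  if (any(!is.finite(protein_conc)) || any(protein_conc < 0))
    stop("invalid input: protein_conc must be finite and >= 0")
  if (is.unsorted(protein_conc, strictly = TRUE))
    stop("invalid input: protein_conc must be strictly increasing")
  if (!is.numeric(peptide_conc) || peptide_conc <= 0)
    stop("invalid input: peptide_conc must be > 0")
  structure(
    data.frame(protein_conc = protein_conc, anisotropy = anisotropy),
    peptide_id = peptide_id, variant_id = variant_id,
    replicate_id = replicate_id, peptide_conc = peptide_conc,
    class = c("titration_curve", "data.frame"))
}

#' Fit a binding isotherm to a titration curve
#'
#' Nonlinear least squares (Levenberg–Marquardt via \pkg{minpack.lm}) with
#' multi-start initialisation: `KD` started at the minimum positive,
#' geometric-mean and maximum concentrations of the grid, `BL` at the first
#' point, `F` at the observed span.  In `"auto"` mode the simple hyperbolic
#' model is fitted first and, if its fitted KD falls below `depletion_kd`
#' (100 nM by default, the regime where peptide depletion at 100 nM labelled
#' peptide biases the hyperbola), the curve is refitted with the exact
#' ligand-depletion model and that fit is reported.
#'
#' @param curve A [titration_curve()].
#' @param model `"auto"`, `"simple"` or `"depletion"`.
#' @param depletion_kd KD threshold (nM) that triggers the depletion refit
#'   in auto mode.
#' @param control List with `tol` (relative convergence tolerance) and
#'   `maxiter` (iterations per start).
#' @return A `binding_fit` list: `params` ([binding_params()]), `model`
#'   (tag of the model used), `rss`, `converged`, `fitted`, `curve`.
#' @examples
#' cv <- simulate_titration(binding_params(680, 0.05, 0.10),
#'                          conc_scheme = titration_scheme(), noise_sd = 0,
#'                          seed = 1, model = "simple")
#' fit_curve(cv, model = "simple")$params$KD
#' @export
fit_curve <- function(curve, model = c("auto", "simple", "depletion"),
                      depletion_kd = 100,
                      control = list(tol = 1e-8, maxiter = 1000)) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "titration_curve"))
  if (nrow(curve) < 5L)
    stop("invalid input: at least 5 titration points are required")
  y <- curve$anisotropy
  span <- diff(range(y))
  # degenerate curve: response range indistinguishable from zero
  if (span <= max(1e-12, 1e-8 * max(abs(y), 1)))
    stop("degenerate curve: flat signal, no binding information")
  c_pep <- attr(curve, "peptide_conc")

  if (model == "auto") {
    fit <- fit_one_model(curve, "simple", control)
    if (fit$params$KD < depletion_kd) {
      fit <- fit_one_model(curve, "depletion", control, c_pep)
      fit$auto_selected <- TRUE
    } else {
      fit$auto_selected <- FALSE
    }
    return(fit)
  }
  fit_one_model(curve, model, control,
                if (model == "depletion") c_pep else NULL)
}

fit_one_model <- function(curve, model, control, c_pep = NULL) {
  x <- curve$protein_conc
  y <- curve$anisotropy
  pos <- x[x > 0]
  kd_starts <- unique(c(min(pos), exp(mean(log(pos))), max(pos)))
  bl0 <- y[1L]
  f0 <- y[length(y)] - y[1L]
  if (f0 == 0) f0 <- diff(range(y))
  predictor <- if (model == "simple") {
    function(lkd, BL, F) BL + F * x / (x + exp(lkd))
  } else {
    function(lkd, BL, F) BL + F * fraction_bound(x, c_pep, exp(lkd))
  }
  best <- NULL
  for (kd0 in kd_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ predictor(lkd, BL, F),
        start = list(lkd = log(kd0), BL = bl0, F = f0),
        control = minpack.lm::nls.lm.control(
          ptol = control$tol, ftol = control$tol,
          maxiter = min(control$maxiter, 1024))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("fitting failure: no start converged for model '", model, "'")
  cf <- stats::coef(best$fit)
  structure(list(
    params = binding_params(exp(unname(cf["lkd"])), unname(cf["BL"]),
                            unname(cf["F"])),
    model = model,
    rss = best$rss,
    converged = best$fit$convInfo$isConv %||% TRUE,
    fitted = stats::fitted(best$fit),
    curve = curve), class = "binding_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> model = %s, KD = %.4g nM, BL = %.4g, F = %.4g, RSS = %.3g\n",
              x$model, x$params$KD, x$params$BL, x$params$F, x$rss))
  invisible(x)
}

#' Pool replicate dissociation constants
#'
#' Arithmetic mean of per-replicate KD values with a 95% confidence
#' half-width computed by the spreadsheet convention used in wet-lab
#' practice: `CI95 = z[0.975] * sigma_pop / sqrt(n)` where `sigma_pop` is
#' the population (divide-by-n) standard deviation, i.e. Excel
#' `CONFIDENCE.NORM(0.05, STDEV.P(x), n)`.
#'
#' @param kds Numeric vector of per-replicate KD values (nM); length >= 2.
#' @return List with `mean`, `ci95` (half-width), `n`.
#' @examples
#' pool_replicates(c(660, 700))  # mean 680, ci95 ~ 27.7
#' @export
pool_replicates <- function(kds) {
  kds <- as.numeric(kds)
  if (length(kds) < 2L)
    stop("insufficient replicates: n >= 2 required for pooling")
  if (any(!is.finite(kds)))
    stop("invalid input: non-finite KD values")
  n <- length(kds)
  sigma_pop <- sqrt(mean((kds - mean(kds))^2))
  list(mean = mean(kds),
       ci95 = stats::qnorm(0.975) * sigma_pop / sqrt(n),
       n = n)
}

#' Preference ratio for a double over a single mark
#'
#' Fold-preference of a reader for the double-modified peptide:
#' `KD_single / KD_double`; values > 1 mean the double mark is bound more
#' strongly.
#'
#' @param KD_single,KD_double Dissociation constants (nM); > 0.
#' @param display If `TRUE`, round for reporting (two significant figures,
#'   one below 0.1); internal computation is never rounded.
#' @return The fold ratio.
#' @examples
#' preference_ratio(680, 240)  # ~2.8-fold preference
#' @export
preference_ratio <- function(KD_single, KD_double, display = FALSE) {
  check_positive(KD_single, "KD_single")
  check_positive(KD_double, "KD_double")
  r <- KD_single / KD_double
  if (display) display_round(r) else r
}

#' Relative effect of a mutation on binding
#'
#' `KD_WT / KD_mut` for one peptide; values > 1 mean the mutant binds that
#' peptide more strongly than wild type.
#'
#' @param KD_WT,KD_mut Dissociation constants (nM); > 0.
#' @inheritParams preference_ratio
#' @return The fold ratio.
#' @examples
#' mutation_effect(680, 220)  # mutant binds ~3.1x more strongly
#' @export
mutation_effect <- function(KD_WT, KD_mut, display = FALSE) {
  check_positive(KD_WT, "KD_WT")
  check_positive(KD_mut, "KD_mut")
  r <- KD_WT / KD_mut
  if (display) display_round(r) else r
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("invalid parameter: ", name, " must be finite and > 0")
}

#' Display rounding for affinity ratios
#'
#' Two significant figures, one significant figure for values below 0.1 —
#' the convention of published affinity-panel tables.
#'
#' @param x Numeric vector.
#' @return Rounded values.
#' @export
display_round <- function(x) {
  ifelse(abs(x) < 0.1, signif(x, 1), signif(x, 2))
}

#' Default titration concentration scheme
#'
#' Twelve protein concentrations spanning 0–10 µM (in nM), roughly
#' geometric above zero, matching a typical anisotropy titration layout.
#'
#' @param max_nM Top concentration (default 10000 nM = 10 µM).
#' @param n Number of points (default 12, including zero).
#' @return Strictly increasing concentration vector (nM).
#' @export
titration_scheme <- function(max_nM = 10000, n = 12) {
  stopifnot(n >= 5, max_nM > 0)
  c(0, max_nM * (1 / 2)^((n - 2):0))
}

#' Simulate a titration curve
#'
#' Model curve plus i.i.d. Gaussian noise, fully determined by `seed`.
#' The exact ligand-depletion model is the default generator since it is
#' the true physics at any KD; the hyperbolic model is available for
#' constructing depletion-free test cases.
#'
#' @param params [binding_params()] of the generating model.
#' @param c_pep Labelled peptide concentration (nM), used by the depletion
#'   model and recorded on the curve.
#' @param conc_scheme Strictly increasing protein concentrations (nM).
#' @param noise_sd Gaussian noise SD in anisotropy units; >= 0.
#' @param seed Integer seed; identical seeds give identical curves.
#' @param model `"depletion"` (default) or `"simple"`.
#' @inheritParams titration_curve
#' @return A [titration_curve()].
#' @export
simulate_titration <- function(params, c_pep = 100,
                               conc_scheme = titration_scheme(),
                               noise_sd = 0, seed = 1,
                               model = c("depletion", "simple"),
                               peptide_id = "peptide", variant_id = "WT",
                               replicate_id = "rep1") {
  model <- match.arg(model)
  params <- as_binding_params(params)
  if (length(conc_scheme) == 0L)
    stop("invalid input: empty concentration scheme")
  if (is.unsorted(conc_scheme, strictly = TRUE))
    stop("invalid input: conc_scheme must be strictly increasing")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid input: noise_sd must be >= 0")
  mu <- if (model == "simple") model_simple(conc_scheme, params)
        else model_depletion(conc_scheme, c_pep, params)
  noise <- with_seed(seed, stats::rnorm(length(mu), 0, noise_sd))
  titration_curve(conc_scheme, mu + noise,
                  peptide_id = peptide_id, variant_id = variant_id,
                  replicate_id = replicate_id, peptide_conc = c_pep)
}

# Run code under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit a table of titration curves
#'
#' Fits every replicate curve in a long-format table (columns
#' `replicate_id`, `peptide_id`, `variant_id`, `peptide_conc_nM`,
#' `protein_conc_nM`, `anisotropy`) and returns one row per replicate fit.
#'
#' @param curves Data frame in the long titration format.
#' @param model Passed to [fit_curve()].
#' @return Data frame with per-replicate fitted `KD`, `BL`, `F`, `model`,
#'   `rss`, `converged`.
#' @export
fit_titration_table <- function(curves, model = "auto") {
  req <- c("replicate_id", "peptide_id", "variant_id", "peptide_conc_nM",
           "protein_conc_nM", "anisotropy")
  if (!all(req %in% names(curves)))
    stop("missing columns: ", paste(setdiff(req, names(curves)),
                                    collapse = ", "))
  keys <- unique(curves[, c("peptide_id", "variant_id", "replicate_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- curves[curves$peptide_id == k$peptide_id &
                  curves$variant_id == k$variant_id &
                  curves$replicate_id == k$replicate_id, ]
    sub <- sub[order(sub$protein_conc_nM), ]
    cv <- titration_curve(sub$protein_conc_nM, sub$anisotropy,
                          peptide_id = k$peptide_id,
                          variant_id = k$variant_id,
                          replicate_id = k$replicate_id,
                          peptide_conc = sub$peptide_conc_nM[1L])
    fit <- fit_curve(cv, model = model)
    data.frame(peptide_id = k$peptide_id, variant_id = k$variant_id,
               replicate_id = k$replicate_id, KD = fit$params$KD,
               BL = fit$params$BL, F = fit$params$F, model = fit$model,
               rss = fit$rss, converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Preference panel from per-replicate fits
#'
#' Pools replicate KD values per (variant, peptide), then derives the
#' double-vs-single preference ratio per variant and the relative effect of
#' each mutation against wild type, mirroring a published affinity-panel
#' table.  Ratios are computed from the unrounded pooled means; the
#' `*_disp` columns carry the display rounding.
#'
#' @param fits Data frame from [fit_titration_table()] (or any table with
#'   `variant_id`, `peptide_id`, `KD`).
#' @param wt Label of the wild-type variant.
#' @param single,double Peptide labels of the single- and double-modified
#'   peptides.
#' @return Data frame with one row per variant: pooled KDs and CI95s,
#'   `ratio`, `rel_effect_single`, `rel_effect_double` (the wild-type row
#'   has `NA` rel-effects), plus display-rounded companions.
#' @export
preference_panel <- function(fits, wt = "WT", single = "H3K9me3",
                             double = "H3K4me1-K9me3") {
  pool_for <- function(variant, peptide) {
    kds <- fits$KD[fits$variant_id == variant & fits$peptide_id == peptide]
    if (length(kds) == 0L)
      stop("no fits for variant ", variant, ", peptide ", peptide)
    if (length(kds) == 1L) list(mean = kds, ci95 = NA_real_, n = 1L)
    else pool_replicates(kds)
  }
  variants <- unique(fits$variant_id)
  variants <- c(wt, setdiff(variants, wt))
  rows <- lapply(variants, function(v) {
    ps <- pool_for(v, single)
    pd <- pool_for(v, double)
    data.frame(variant_id = v,
               KD_single = ps$mean, CI95_single = ps$ci95, n_single = ps$n,
               KD_double = pd$mean, CI95_double = pd$ci95, n_double = pd$n,
               ratio = preference_ratio(ps$mean, pd$mean))
  })
  panel <- do.call(rbind, rows)
  wt_row <- panel[panel$variant_id == wt, ]
  panel$rel_effect_single <- ifelse(
    panel$variant_id == wt, NA_real_,
    mutation_effect(wt_row$KD_single, panel$KD_single))
  panel$rel_effect_double <- ifelse(
    panel$variant_id == wt, NA_real_,
    mutation_effect(wt_row$KD_double, panel$KD_double))
  panel$ratio_disp <- display_round(panel$ratio)
  panel$rel_effect_single_disp <- display_round(panel$rel_effect_single)
  panel$rel_effect_double_disp <- display_round(panel$rel_effect_double)
  panel
}
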
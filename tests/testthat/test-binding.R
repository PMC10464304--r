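# Equilibrium binding models, curve fitting and replicate pooling.

test_that("simple isotherm satisfies its closed-form identities", {
  p <- binding_params(KD = 240, BL = 0.05, F = 0.10)
  expect_identical(model_simple(0, p), 0.05)
  # half-saturation: fraction bound is exactly 1/2 at c = KD
  expect_equal(model_simple(240, p), 0.05 + 0.10 / 2)
  # direct arithmetic: 720 / (720 + 240) = 0.75
  expect_equal(model_simple(720, binding_params(240, 0, 1)), 0.75)
  expect_error(binding_params(KD = -1), "KD")
  expect_error(binding_params(KD = 10, F = 0), "F")
})

test_that("depletion isotherm matches a bisection oracle on the mass balance", {
  # oracle: solve for complex concentration [PL] in
  #   ([P]t - PL)([L]t - PL) = KD * PL  by bisection
  bisect_theta <- function(c_prot, c_pep, KD) {
    f <- function(pl) (c_prot - pl) * (c_pep - pl) - KD * pl
    lo <- 0; hi <- min(c_prot, c_pep)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    ((lo + hi) / 2) / c_pep
  }
  p <- binding_params(KD = 9, BL = 0, F = 1)
  got <- model_depletion(100, c_pep = 100, p)
  expect_equal(got, bisect_theta(100, 100, 9), tolerance = 1e-9)
  # a second regime: strong depletion, excess protein
  p2 <- binding_params(KD = 50, BL = 0, F = 1)
  expect_equal(model_depletion(400, c_pep = 150, p2),
               bisect_theta(400, 150, 50), tolerance = 1e-9)
  # no protein, no complex
  expect_identical(model_depletion(0, 100, binding_params(9, 0.02, 1)), 0.02)
  expect_error(model_depletion(10, c_pep = 0, p), "c_pep")
})

test_that("depletion model converges to the simple model as c_pep -> 0", {
  p <- binding_params(KD = 500, BL = 0.01, F = 0.2)
  grid <- c(10, 50, 200, 500, 2000, 10000)
  s <- model_simple(grid, p)
  d4 <- model_depletion(grid, c_pep = 500 * 1e-4, p)
  expect_lt(max(abs(d4 - s) / abs(s)), 1e-3)
  d6 <- model_depletion(grid, c_pep = 500 * 1e-6, p)
  expect_lt(max(abs(d6 - s) / abs(s)), 1e-4)
})

test_that("fraction bound stays within [0, 1) under both models", {
  for (kd in c(2, 68, 680, 16000)) {
    p <- binding_params(kd, BL = 0.3, F = 0.7)
    grid <- seq(0, 2e4, length.out = 41)
    th_s <- (model_simple(grid, p) - p$BL) / p$F
    th_d <- (model_depletion(grid, 100, p) - p$BL) / p$F
    expect_true(all(th_s >= 0 & th_s < 1))
    expect_true(all(th_d >= 0 & th_d < 1))
  }
})

test_that("fitting recovers generating parameters on noiseless curves", {
  p <- binding_params(KD = 680, BL = 0.05, F = 0.10)
  cv <- simulate_titration(p, conc_scheme = titration_scheme(),
                           noise_sd = 0, seed = 1, model = "simple")
  fit <- fit_curve(cv, model = "simple")
  expect_lt(abs(fit$params$KD - 680) / 680, 0.001)
  expect_equal(fit$params$BL, 0.05, tolerance = 1e-4)
  expect_equal(fit$params$F, 0.10, tolerance = 1e-4)

  # auto mode: high-affinity curve must trigger the depletion refit
  p9 <- binding_params(KD = 9, BL = 0.05, F = 0.10)
  cv9 <- simulate_titration(p9, c_pep = 100,
                            conc_scheme = titration_scheme(2000, 12),
                            noise_sd = 0, seed = 2)
  fit9 <- fit_curve(cv9, model = "auto")
  expect_identical(fit9$model, "depletion")
  expect_lt(abs(fit9$params$KD - 9) / 9, 0.01)
})

test_that("fit is invariant to uniform rescaling of anisotropy units", {
  p <- binding_params(KD = 680, BL = 0.05, F = 0.10)
  cv <- simulate_titration(p, conc_scheme = titration_scheme(),
                           noise_sd = 0, seed = 3, model = "simple")
  sc <- titration_curve(cv$protein_conc, cv$anisotropy * 37)
  f1 <- fit_curve(cv, model = "simple")
  f2 <- fit_curve(sc, model = "simple")
  expect_equal(f2$params$KD, f1$params$KD, tolerance = 1e-6)
  expect_equal(f2$params$BL, 37 * f1$params$BL, tolerance = 1e-6)
  expect_equal(f2$params$F, 37 * f1$params$F, tolerance = 1e-6)
})

test_that("degenerate and invalid curves are rejected", {
  flat <- titration_curve(c(0, 10, 100, 1000, 10000), rep(0.05, 5))
  expect_error(fit_curve(flat), "degenerate")
  expect_error(titration_curve(c(0, 10, 10, 100, 1000), rep(1:5)),
               "strictly increasing")
  short <- titration_curve(c(0, 10, 100, 1000), c(0, .1, .2, .3))
  expect_error(fit_curve(short), "5")
})

test_that("replicate pooling follows the spreadsheet CI convention", {
  expect_equal(pool_replicates(c(680, 680)),
               list(mean = 680, ci95 = 0, n = 2L))
  # CONFIDENCE.NORM(0.05, STDEV.P({660,700}), 2) = 1.959964 * 20 / sqrt(2)
  pr <- pool_replicates(c(660, 700))
  expect_equal(pr$mean, 680)
  expect_equal(pr$ci95, stats::qnorm(0.975) * 20 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(pool_replicates(c(2, 2, 2))$ci95, 0)
  expect_error(pool_replicates(680), "n >= 2")
})

test_that("ratio helpers compute and display-round as published panels do", {
  expect_equal(preference_ratio(5, 5), 1)
  expect_equal(mutation_effect(7, 7), 1)
  expect_equal(preference_ratio(680, 240, display = TRUE), 2.8)
  expect_equal(mutation_effect(240, 2700, display = TRUE), 0.09)
  expect_error(preference_ratio(-1, 5), "invalid")
  expect_error(mutation_effect(5, 0), "invalid")
})

test_that("simulated titrations are seeded, exact when noiseless, unbiased", {
  p <- binding_params(KD = 680, BL = 0.05, F = 0.10)
  a <- simulate_titration(p, noise_sd = 0.01, seed = 42)
  b <- simulate_titration(p, noise_sd = 0.01, seed = 42)
  expect_identical(a, b)
  clean <- simulate_titration(p, noise_sd = 0, seed = 1)
  expect_equal(clean$anisotropy,
               model_depletion(clean$protein_conc, 100, p))
  # law of large numbers on the noise: 1e4 points, sd 0.002
  grid <- seq(0, 9999)
  big <- simulate_titration(p, conc_scheme = grid, noise_sd = 0.002,
                            seed = 5)
  resid <- big$anisotropy - model_depletion(grid, 100, p)
  expect_lt(abs(mean(resid)), 3 * 0.002 / 100)
  expect_error(simulate_titration(p, conc_scheme = numeric(0)), "empty")
})

test_that("titration tables fit per replicate and pool into a panel", {
  p_wt_s <- binding_params(680, 0.05, 0.10)
  p_wt_d <- binding_params(240, 0.05, 0.10)
  rows <- list()
  for (rep_id in c("r1", "r2")) {
    for (cfg in list(list(p = p_wt_s, pep = "H3K9me3"),
                     list(p = p_wt_d, pep = "H3K4me1-K9me3"))) {
      cv <- simulate_titration(cfg$p, conc_scheme = titration_scheme(),
                               noise_sd = 0.0005, model = "simple",
                               seed = 100 + nchar(cfg$pep) +
                                 match(rep_id, c("r1", "r2")))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = rep_id, peptide_id = cfg$pep, variant_id = "WT",
        peptide_conc_nM = 100, protein_conc_nM = cv$protein_conc,
        anisotropy = cv$anisotropy)
    }
  }
  tab <- do.call(rbind, rows)
  fits <- fit_titration_table(tab, model = "auto")
  expect_equal(nrow(fits), 4L)
  panel <- preference_panel(fits)
  expect_equal(panel$n_single, 2L)
  expect_equal(panel$KD_single, 680, tolerance = 0.05)
  expect_equal(panel$ratio, 680 / 240, tolerance = 0.1)
  expect_true(is.na(panel$rel_effect_single[panel$variant_id == "WT"]))
})
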
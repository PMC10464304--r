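# Probe-to-gene medians, DRG calling, the reader-dependent set, the
# enhancer-mark association test and expression-ratio binning.

probe_table <- function(genes, wt, td, probes_per = 1) {
  n <- length(genes) * probes_per
  data.frame(probe_id = sprintf("p%04d", seq_len(n)),
             gene = rep(genes, each = probes_per),
             WT = rep(wt, each = probes_per),
             TTDstar = rep(td, each = probes_per))
}

test_that("gene medians equal the sort-based oracle", {
  t1 <- probe_table(c("a", "b"), c(0.1, 0.2), c(1, 2))
  expect_equal(gene_medians(t1)$WT, c(0.1, 0.2))

  t2 <- data.frame(probe_id = c("p1", "p2", "p3"), gene = "g",
                   WT = c(0.5, 1.5, 2.5), TTDstar = 0)
  expect_equal(gene_medians(t2)$WT, 1.5)

  set.seed(1)
  genes <- sample(sprintf("g%02d", 1:20), 200, replace = TRUE)
  t3 <- data.frame(probe_id = sprintf("p%03d", 1:200), gene = genes,
                   WT = stats::rnorm(200), TTDstar = stats::rnorm(200))
  gm <- gene_medians(t3)
  for (g in unique(genes)) {
    v <- sort(t3$WT[t3$gene == g])
    n <- length(v)
    oracle <- if (n %% 2) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
    expect_equal(gm$WT[gm$gene == g], oracle)
  }
})

test_that("DRG calling thresholds inclusively and partitions the universe", {
  genes <- data.frame(gene = c("a", "b", "c", "d"),
                      WT = log2(c(1.5, 1.49, 1 / 1.5, 1)),
                      TTDstar = 0)
  drg <- call_drgs(genes, "WT")
  expect_equal(drg$up, "a")            # exactly 1.5-fold: inclusive
  expect_equal(drg$down, "c")
  expect_setequal(drg$non_responder, c("b", "d"))
  expect_setequal(c(drg$up, drg$down, drg$non_responder), genes$gene)
  # raising the threshold shrinks the responder sets
  strict <- call_drgs(genes, "WT", fc_threshold = 2)
  expect_true(all(strict$up %in% drg$up))
  expect_true(all(strict$down %in% drg$down))
  expect_error(call_drgs(genes, "nope"), "missing condition")
  expect_error(call_drgs(genes, "WT", fc_threshold = 1), "> 1")
})

test_that("the reader-dependent set applies the WT filter first", {
  genes <- data.frame(
    gene = c("dep", "wt_and_td", "td_only_weak", "silent"),
    WT = c(0, 1, 0, 0),
    TTDstar = c(log2(1.6), 1, log2(1.4), 0))
  dep <- ttd_dependent_set(call_drgs(genes, "WT"),
                           call_drgs(genes, "TTDstar"))
  expect_equal(dep, "dep")   # WT-responsive and sub-threshold excluded
})

test_that("planted expression designs are recovered exactly at zero noise", {
  spec <- expression_spec(n_genes = 800, n_planted = 115,
                          n_wt_responsive = 100, noise_sd = 0,
                          probes_per_gene = c(1, 3))
  out <- generate_expression(spec, seed = 4)
  gm <- gene_medians(out$probes)
  dep <- ttd_dependent_set(call_drgs(gm, "WT"), call_drgs(gm, "TTDstar"))
  expect_setequal(dep, out$truth$planted)
  expect_equal(length(dep), 115L)
})

test_that("mark association reduces to the classical tests", {
  # identical distributions: F = 0, p = 1
  marks <- data.frame(gene = c("a", "b", "c", "d"), K4me1 = c(1, 2, 1, 2))
  ma <- mark_association(list(g1 = c("a", "b"), g2 = c("c", "d")), marks)
  expect_equal(ma$anova$F, 0)
  expect_equal(ma$anova$p, 1)

  # two groups: ANOVA p identical to the pooled two-sided t-test (F = t^2)
  set.seed(7)
  marks2 <- data.frame(gene = sprintf("g%03d", 1:60),
                       K4me1 = c(stats::rnorm(30, 0), stats::rnorm(30, 1)))
  grp <- list(lo = marks2$gene[1:30], hi = marks2$gene[31:60])
  ma2 <- mark_association(grp, marks2)
  tt <- stats::t.test(marks2$K4me1[31:60], marks2$K4me1[1:30],
                      var.equal = TRUE)
  expect_equal(ma2$anova$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ma2$anova$F, unname(tt$statistic)^2, tolerance = 1e-10)
  # Bonferroni pairwise p present and within [0, 1]
  expect_true(all(ma2$pairwise >= 0 & ma2$pairwise <= 1, na.rm = TRUE))
  # degenerate: all groups constant at the same value
  md <- mark_association(list(g1 = c("a", "b"), g2 = c("c", "d")),
                         data.frame(gene = c("a", "b", "c", "d"),
                                    K4me1 = 5))
  expect_true(md$degenerate)
})

test_that("expression-ratio binning filters and orders correctly", {
  genes <- data.frame(
    gene = sprintf("g%02d", 1:20),
    hepg2 = c(2000, 1800, rep(3000, 8), rep(100, 10)),
    liver = c(900, 1000, rep(400, 8), rep(1200, 10)),
    sig = 1:20)
  # g01: ratio 2.22, level ok -> passes.  g02: ratio 1.8 -> filtered.
  out <- expression_ratio_bins(genes, "hepg2", "liver", signal = "sig",
                               min_level = 1000, min_fold = 2, k = 5)
  expect_true("g01" %in% out$genes$gene)
  expect_false("g02" %in% out$genes$gene)
  # low-expressed genes (max level 1200 >= 1000, ratio 1/12) pass the
  # down-direction filter
  expect_true("g11" %in% out$genes$gene)
  expect_equal(as.integer(table(out$genes$bin)),
               rep(nrow(out$genes) %/% 5, 5) +
                 c(rep(1L, nrow(out$genes) %% 5),
                   rep(0L, 5 - nrow(out$genes) %% 5)))
  # bins ordered by increasing ratio
  med <- out$summary$median_ratio
  expect_true(all(diff(med) >= 0))

  # monotone coupling between ratio and signal -> monotone bin medians
  set.seed(8)
  n <- 100
  ratio_up <- exp(seq(log(2), log(20), length.out = n))
  tab <- data.frame(gene = sprintf("m%03d", 1:n),
                    a = 2000 * ratio_up, b = 2000,
                    sig = seq_len(n))
  res <- expression_ratio_bins(tab, "a", "b", signal = "sig", k = 5)
  expect_true(all(diff(res$summary$median) > 0))
})
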
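# Decile split, conditional correlation, fragmentation, clustering,
# shuffle-null enrichment and region matrices.

test_that("quantile_split partitions bins with deterministic tie-breaks", {
  bins <- bin_genome(c(c1 = 100000), 1000)
  set.seed(1)
  S4Vectors::mcols(bins)$sig <- sample(seq_len(100))
  q <- quantile_split(bins, "sig", k = 10)
  grp <- S4Vectors::mcols(q)$group
  expect_equal(as.integer(table(grp)), rep(10L, 10))
  # group 1 holds the ten largest values
  expect_setequal(S4Vectors::mcols(q)$sig[grp == 1], 91:100)
  # per-group mean of the ranking track is non-increasing
  m <- tapply(S4Vectors::mcols(q)$sig, grp, mean)
  expect_true(all(diff(m) <= 0))

  # all-equal values: groups are genomic-order blocks
  S4Vectors::mcols(bins)$sig <- 1
  qt <- quantile_split(bins, "sig", k = 4)
  expect_equal(S4Vectors::mcols(qt)$group, rep(1:4, each = 25))

  # uneven split: sizes differ by at most one, larger groups first
  bins5 <- bin_genome(c(c1 = 23000), 1000)
  S4Vectors::mcols(bins5)$sig <- rev(seq_len(23))
  q5 <- quantile_split(bins5, "sig", k = 5)
  expect_equal(as.integer(table(S4Vectors::mcols(q5)$group)),
               c(5L, 5L, 5L, 4L, 4L))
})

test_that("short trailing bins are excluded from the split by default", {
  bins <- bin_genome(c(c1 = 10300), 1000)   # trailing 300 bp bin
  S4Vectors::mcols(bins)$sig <- seq_along(bins)
  q <- quantile_split(bins, "sig", k = 2)
  expect_equal(length(q), 10L)
  q_all <- quantile_split(bins, "sig", k = 2, min_width_frac = 0)
  expect_equal(length(q_all), 11L)
})

test_that("conditional correlation behaves at the identity and the null", {
  bins <- bin_genome(c(c1 = 100000), 1000)
  set.seed(2)
  x <- stats::rnorm(100)
  S4Vectors::mcols(bins)$rank_sig <- seq_len(100)
  S4Vectors::mcols(bins)$x <- x
  S4Vectors::mcols(bins)$y <- x
  q <- quantile_split(bins, "rank_sig", k = 4)
  cc <- conditional_correlation(q, "x", "y")
  expect_equal(cc$r, rep(1, 4))

  # independent noise: |r| < 3/sqrt(n) in the vast majority of draws
  hits <- 0L; total <- 0L
  for (s in 1:12) {
    set.seed(100 + s)
    S4Vectors::mcols(q)$y <- stats::rnorm(100)
    rr <- conditional_correlation(q, "x", "y")$r
    hits <- hits + sum(abs(rr) < 3 / sqrt(25)); total <- total + length(rr)
  }
  expect_gte(hits / total, 0.9)
})

test_that("fragmentation enforces the inclusive retention rule", {
  cs <- c(c1 = 3000)
  expect_equal(
    as.data.frame(fragment_peaks(gr_of("c1", 0, 450), cs))[, c("start", "end")],
    data.frame(start = c(1L, 151L, 301L), end = c(150L, 300L, 450L)))
  # 75 bp overlap (exactly 50%) kept; 74 bp dropped
  kept <- fragment_peaks(gr_of("c1", 150, 225), cs)    # tile [150,300)
  expect_equal(length(kept), 1L)
  dropped <- fragment_peaks(gr_of("c1", 150, 224), cs)
  expect_equal(length(dropped), 0L)

  # brute-force verification on a random peak set
  set.seed(3)
  st <- sort(sample(0:2700, 8))
  peaks <- GenomicRanges::reduce(gr_of("c1", st, st + sample(60:400, 8,
                                                             replace = TRUE)))
  fr <- fragment_peaks(peaks, cs, 150, 0.5)
  cov_vec <- rep(0L, 3000)
  for (i in seq_along(peaks))
    cov_vec[GenomicRanges::start(peaks)[i]:GenomicRanges::end(peaks)[i]] <- 1L
  for (i in seq_along(fr)) {
    ov <- sum(cov_vec[GenomicRanges::start(fr)[i]:GenomicRanges::end(fr)[i]])
    expect_gte(ov, 75)
  }
  # and no retained-eligible tile was missed
  tiles <- bin_genome(cs, 150)
  ovs <- vapply(seq_along(tiles), function(i)
    sum(cov_vec[GenomicRanges::start(tiles)[i]:GenomicRanges::end(tiles)[i]]),
    numeric(1))
  expect_equal(length(fr), sum(ovs >= 75))
})

test_that("fragment clustering orders clusters and handles edge cases", {
  cs <- c(c1 = 100000)
  fr <- bin_genome(cs, 150)[1:60]
  # three planted classes in signal space
  set.seed(4)
  lab <- rep(1:3, each = 20)
  S4Vectors::mcols(fr)$A <- c(10, 5, 0.2)[lab] + stats::rnorm(60, 0, 0.2)
  S4Vectors::mcols(fr)$B <- c(8, 0.2, 6)[lab] + stats::rnorm(60, 0, 0.2)
  out <- cluster_fragments(fr, k = 3, order_by = "A", seed = 7)
  cl <- S4Vectors::mcols(out)$cluster
  expect_gte(mclust::adjustedRandIndex(lab, cl), 0.99)
  # cluster 1 must have the highest mean of the ordering track
  cm <- tapply(S4Vectors::mcols(out)$A, cl, mean)
  expect_equal(order(-cm), 1:3)

  one <- cluster_fragments(fr, k = 1, seed = 1)
  expect_true(all(S4Vectors::mcols(one)$cluster == 1L))

  # duplicated rows co-assign
  S4Vectors::mcols(fr)$A <- rep(c(1, 5, 9), 20)
  S4Vectors::mcols(fr)$B <- rep(c(1, 5, 9), 20)
  dup <- cluster_fragments(fr, k = 3, order_by = "A", seed = 1)
  expect_equal(length(unique(tapply(S4Vectors::mcols(dup)$cluster,
                                    rep(c(1, 5, 9), 20), unique))), 3L)
  expect_error(cluster_fragments(fr, k = 4, seed = 1), "degenerate")
})

test_that("shuffling conserves lengths, avoids the blacklist, stays uniform", {
  cs <- c(c1 = 50000, c2 = 30000)
  tmpl <- c(gr_of("c1", c(0, 1000, 5000), c(500, 1800, 5100)),
            gr_of("c2", 2000, 2600))
  sh <- shuffle_intervals(tmpl, cs, seed = 1)
  expect_equal(sort(width(sh)), sort(width(tmpl)))
  expect_identical(shuffle_intervals(tmpl, cs, seed = 5),
                   shuffle_intervals(tmpl, cs, seed = 5))

  # uniform placement: expected base fraction in a 30%-cover region
  region <- gr_of("c1", 0, 24000)    # 24k of 80k = 30%
  fr <- vapply(1:60, function(s) {
    sh <- shuffle_intervals(tmpl, cs, seed = s)
    hit <- GenomicRanges::intersect(sh, region)
    sum(width(hit)) / sum(width(sh))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.30), 0.05)

  # blacklist covering everything except one admissible slot
  bl <- c(gr_of("c1", 500, 50000), gr_of("c2", 0, 30000))
  forced <- shuffle_intervals(gr_of("c1", 0, 100), c(c1 = 50000, c2 = 30000),
                              blacklist = bl, seed = 2, max_tries = 5000)
  expect_lte(end(forced), 500)
  expect_error(
    shuffle_intervals(gr_of("c1", 0, 100), cs,
                      blacklist = c(gr_of("c1", 0, 50000),
                                    gr_of("c2", 0, 30000)),
                      seed = 1, max_tries = 50),
    "infeasible")
})

test_that("state enrichment flags self-enrichment and true zeros", {
  cs <- c(c1 = 20000)
  states <- c(gr_of("c1", c(0, 5000, 10000), c(5000, 10000, 20000),
                    state = c("A", "B", "C")))
  # peaks identical to state A regions
  peaks <- gr_of("c1", 0, 5000)
  enr <- state_enrichment(peaks, states, cs, n_shuffles = 50, seed = 1)
  a <- enr[enr$state == "A", ]
  expect_true(a$ratio == max(enr$ratio) && a$ratio > 1)
  # a state disjoint from all peaks observes zero
  d <- enr[enr$state == "C", ]
  expect_equal(d$observed, 0L)
  expect_equal(d$ratio, 0)
  expect_true(all(enr$p_value > 0 & enr$p_value <= 1))
})

test_that("peak overlap enrichment covers containment and disjointness", {
  cs <- c(c1 = 50000, c2 = 50000)
  B <- gr_of("c1", c(0, 20000), c(10000, 30000))
  A_in <- gr_of("c1", c(100, 20500), c(200, 20600))
  expect_equal(peak_overlap_enrichment(A_in, B, cs, seed = 1)$overlap_pct,
               100)
  A_far <- gr_of("c2", c(100, 300), c(200, 400))
  r <- peak_overlap_enrichment(A_far, B, cs, seed = 1)
  expect_equal(r$overlap_pct, 0)
  expect_equal(r$fold, 0)
})

test_that("region matrices are centred, ordered and consistent with means", {
  cs <- c(c1 = 100000)
  tr <- flat_track(cs, 2)
  regions <- gr_of("c1", c(10000, 30000, 60000), c(10400, 30600, 60200))
  rm <- region_matrix(tr, regions, flank = 1000, n_columns = 10)
  expect_true(all(rm$matrix == 2))

  # delta-like peak at a midpoint lands in the central columns
  mid <- 30300
  delta <- track_from_runs(list(list("c1", mid - 6, mid + 5, 50)), cs)
  rd <- region_matrix(delta, regions[2], flank = 1000, n_columns = 11)
  expect_equal(which.max(rd$matrix[1, ]), 6L)

  # row means equal mean_signal over the expanded window
  rt <- random_track(c(c1 = 100000), seg = 53, seed = 12)
  rr <- region_matrix(rt, regions, flank = 1000, n_columns = 10)
  mids <- floor((start(regions) + end(regions)) / 2)
  expanded <- gr_of("c1", mids - 1001, mids + 999)  # matrix window support
  oracle <- sort(mean_signal(rt, expanded), decreasing = TRUE)
  expect_equal(unname(rowMeans(rr$matrix)), oracle, tolerance = 1e-10)

  # regions whose window leaves the chromosome yield NA edge cells
  edge <- gr_of("c1", 0, 100)
  re <- region_matrix(rt, edge, flank = 1000, n_columns = 10)
  expect_true(anyNA(re$matrix))
})
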
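#' Rank bins by a track and split into quantile groups
#'
#' Bins are stable-sorted by descending ranking signal (ties broken by
#' genomic order, so the split is deterministic) and divided into `k`
#' groups whose sizes differ by at most one; group 1 holds the highest
#' signal.  This is the decile construction used to condition one
#' correlation on a third mark, and (with `k = 5`) the expression-ratio
#' quintile split.  Trailing genome bins shorter than `min_width_frac`
#' of the modal bin width are excluded before grouping to avoid
#' short-bin mean-signal artifacts (set `min_width_frac = 0` to keep
#' them).
#'
#' @param bins `GRanges` with per-bin signal metadata columns (see
#'   [bin_signal()]).
#' @param ranking_track Name of the metadata column to rank by.
#' @param k Number of groups, >= 2.
#' @param min_width_frac Fraction of the modal bin width below which
#'   trailing bins are dropped (default 0.5).
#' @return `bins` (possibly without short trailing bins) with an integer
#'   `group` metadata column in 1..k, still in genomic order.
#' @export
quantile_split <- function(bins, ranking_track, k = 10,
                           min_width_frac = 0.5) {
  if (k < 2L) stop("k must be >= 2")
  if (!ranking_track %in% names(S4Vectors::mcols(bins)))
    stop("ranking track '", ranking_track, "' not found in bins")
  if (min_width_frac > 0) {
    w <- GenomicRanges::width(bins)
    modal <- as.numeric(names(sort(table(w), decreasing = TRUE))[1L])
    bins <- bins[w >= min_width_frac * modal]
  }
  n <- length(bins)
  if (n < k) stop("fewer bins (", n, ") than groups (", k, ")")
  s <- S4Vectors::mcols(bins)[[ranking_track]]
  ord <- order(-s, seq_len(n))        # stable: ties keep genomic order
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  grp <- integer(n)
  grp[ord] <- rep(seq_len(k), times = sizes)
  S4Vectors::mcols(bins)$group <- grp
  bins
}

#' Per-group distribution summary of a signal
#'
#' Median, quartiles and 5th/95th percentiles of one signal column per
#' quantile group — the numbers behind the box-and-whisker summaries of
#' the decile analysis.
#'
#' @param bins Output of [quantile_split()].
#' @param track Name of the signal column to summarise.
#' @return Data frame with one row per group.
#' @export
group_summary <- function(bins, track) {
  grp <- S4Vectors::mcols(bins)$group
  if (is.null(grp)) stop("bins carry no group column; run quantile_split")
  s <- S4Vectors::mcols(bins)[[track]]
  if (is.null(s)) stop("track '", track, "' not found in bins")
  out <- lapply(sort(unique(grp)), function(g) {
    q <- stats::quantile(s[grp == g], c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE)
    data.frame(group = g, n = sum(grp == g), p5 = q[1], p25 = q[2],
               median = q[3], p75 = q[4], p95 = q[5])
  })
  do.call(rbind, out)
}

#' Conditional (per-group) Pearson correlation
#'
#' Pearson r between two signal columns computed separately within each
#' quantile group, quantifying how the co-variation of two marks depends
#' on the level of the ranking mark.
#'
#' @param bins Output of [quantile_split()] with signal columns.
#' @param trackX,trackY Names of the two signal columns.
#' @return Data frame with `group`, `n`, `r` (`NA` with a warning for a
#'   zero-variance group).
#' @export
conditional_correlation <- function(bins, trackX, trackY) {
  grp <- S4Vectors::mcols(bins)$group
  if (is.null(grp)) stop("bins carry no group column; run quantile_split")
  x <- S4Vectors::mcols(bins)[[trackX]]
  y <- S4Vectors::mcols(bins)[[trackY]]
  if (is.null(x) || is.null(y)) stop("signal column not found in bins")
  out <- lapply(sort(unique(grp)), function(g) {
    xi <- x[grp == g]; yi <- y[grp == g]
    if (length(xi) < 3L) stop("group ", g, " has fewer than 3 bins")
    r <- if (stats::sd(xi) == 0 || stats::sd(yi) == 0) {
      warning("undefined correlation in group ", g, " (zero variance)")
      NA_real_
    } else stats::cor(xi, yi)
    data.frame(group = g, n = length(xi), r = r)
  })
  do.call(rbind, out)
}

#' Fragment peaks into fixed-size genome-aligned windows
#'
#' The genome is tiled from 0 in `fragment_size` steps and a tile is
#' retained iff its overlap with the union of the peaks is at least
#' `retention * fragment_size` bases (inclusive).  At the default 150 bp
#' and 50% this selects mononucleosome-sized fragments lying mostly
#' inside peaks.
#'
#' @param peaks `GRanges` of source peaks.
#' @inheritParams bin_genome
#' @param fragment_size Tile width in bp (default 150).
#' @param retention Minimum kept overlap as a fraction of the tile width,
#'   in (0, 1] (default 0.5).
#' @return Sorted `GRanges` of retained fragments.
#' @export
fragment_peaks <- function(peaks, chrom_sizes, fragment_size = 150,
                           retention = 0.5) {
  if (fragment_size <= 0) stop("fragment_size must be > 0")
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  tiles <- bin_genome(chrom_sizes, fragment_size)
  pk <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
  GenomeInfoDb::seqlevels(pk) <- GenomeInfoDb::seqlevels(tiles)
  ov <- GenomicRanges::findOverlaps(tiles, pk, ignore.strand = TRUE)
  if (!length(ov)) return(tiles[0])
  w <- GenomicRanges::width(IRanges::pintersect(
    tiles[S4Vectors::queryHits(ov)], pk[S4Vectors::subjectHits(ov)]))
  tot <- tapply(w, S4Vectors::queryHits(ov), sum)
  keep <- as.integer(names(tot))[
    tot >= retention * GenomicRanges::width(tiles)[as.integer(names(tot))]]
  tiles[sort(keep)]
}

#' k-means clustering of peak fragments
#'
#' Clusters fragments on their per-track mean signals (columns
#' standardised to zero mean / unit variance since track scales differ),
#' with multiple restarts under a fixed seed.  Cluster labels are then
#' renumbered in decreasing order of the ordering track's cluster mean,
#' so cluster 1 always carries the strongest signal.
#'
#' @param fragments `GRanges` with signal metadata columns (see
#'   [bin_signal()]).
#' @param k Number of clusters, >= 1.
#' @param order_by Name of the signal column used to order clusters
#'   (default: first column).
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts (default 10).
#' @return `fragments` with an integer `cluster` column, plus attributes
#'   `centers` (ordered cluster centres, original scale) and `sizes`.
#' @export
cluster_fragments <- function(fragments, k, order_by = NULL, seed = 1,
                              n_init = 10) {
  mc <- S4Vectors::mcols(fragments)
  num <- vapply(seq_len(ncol(mc)), function(j) is.numeric(mc[[j]]),
                logical(1))
  m <- as.matrix(as.data.frame(mc[, num, drop = FALSE]))
  if (k < 1L) stop("k must be >= 1")
  if (nrow(m) < k) stop("fewer fragments than clusters")
  if (nrow(unique(m)) < k)
    stop("degenerate clustering: fewer distinct rows than clusters")
  if (is.null(order_by)) order_by <- colnames(m)[1L]
  if (!order_by %in% colnames(m))
    stop("ordering track '", order_by, "' not found")
  sds <- apply(m, 2, stats::sd)
  ms <- scale(m, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  km <- with_seed(seed, stats::kmeans(ms, centers = k, nstart = n_init,
                                      iter.max = 100))
  cl_means <- tapply(m[, order_by], km$cluster, mean)
  relabel <- integer(k)
  relabel[order(-cl_means)] <- seq_len(k)
  cluster <- relabel[km$cluster]
  S4Vectors::mcols(fragments)$cluster <- cluster
  centers <- apply(m, 2, function(col) tapply(col, cluster, mean))
  attr(fragments, "centers") <- centers
  attr(fragments, "sizes") <- as.integer(table(cluster))
  fragments
}

#' Shuffle intervals across the genome
#'
#' Re-places every interval uniformly at random on the genome, conserving
#' the interval-length multiset exactly, avoiding the blacklist, and
#' allowing the shuffled intervals to overlap one another (the behaviour
#' of `bedtools shuffle` without `-noOverlapping`).  Chromosomes are
#' chosen with probability proportional to the number of valid start
#' positions for each length.
#'
#' @param template `GRanges` whose lengths are conserved.
#' @inheritParams bin_genome
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling retries per interval before
#'   giving up.
#' @return Sorted `GRanges` of shuffled intervals.
#' @export
shuffle_intervals <- function(template, chrom_sizes, blacklist = NULL,
                              seed = 1, max_tries = 1000) {
  check_chrom_sizes(chrom_sizes)
  lens <- GenomicRanges::width(template)
  n <- length(lens)
  slots_for <- function(L) pmax(chrom_sizes - L + 1, 0)
  bad <- vapply(unique(lens), function(L) sum(slots_for(L)) == 0,
                logical(1))
  if (any(bad))
    stop("infeasible placement: no chromosome can hold length ",
         unique(lens)[bad][1L])
  with_seed(seed, {
    chrs <- character(n); starts <- integer(n)
    todo <- seq_len(n)
    for (round in seq_len(max_tries)) {
      if (!length(todo)) break
      # batch-propose one placement per pending interval
      for (i in todo) {
        slots <- slots_for(lens[i])
        chr <- sample(names(chrom_sizes), 1L, prob = slots)
        chrs[i] <- chr
        starts[i] <- sample.int(slots[[chr]], 1L)   # 1-based start
      }
      if (is.null(blacklist) || !length(blacklist)) {
        todo <- integer(0)
      } else {
        cand <- GenomicRanges::GRanges(
          chrs[todo], IRanges::IRanges(starts[todo],
                                       width = lens[todo]))
        hit <- IRanges::overlapsAny(cand, blacklist,
                                    ignore.strand = TRUE)
        todo <- todo[hit]
      }
    }
    if (length(todo))
      stop("infeasible placement after ", max_tries,
           " tries for interval of length ", lens[todo[1L]])
    GenomicRanges::sort(GenomicRanges::GRanges(
      chrs, IRanges::IRanges(starts, width = lens)))
  })
}

#' Chromatin-state enrichment of peaks against a shuffle null
#'
#' For every state label: the observed number of state regions touched by
#' at least one peak (>= 1 bp), the expectation under `n_shuffles`
#' genome-wide random re-placements of the peaks, their ratio, and an
#' add-one empirical p-value `(1 + #{null >= obs}) / (1 + n_shuffles)`.
#'
#' @param peaks `GRanges` of peaks.
#' @param states `GRanges` with a `state` (or `name`) metadata column of
#'   labels.
#' @inheritParams shuffle_intervals
#' @param n_shuffles Number of null draws, >= 1.
#' @return Data frame with one row per state: `state`, `n_regions`,
#'   `observed`, `expected`, `ratio`, `sd_null` (SD of the null counts),
#'   `overlap_pct`, `p_value`, `n_shuffles`.
#' @export
state_enrichment <- function(peaks, states, chrom_sizes,
                             blacklist = NULL, n_shuffles = 10, seed = 1) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  lab <- S4Vectors::mcols(states)$state %||% S4Vectors::mcols(states)$name
  if (is.null(lab)) stop("states need a 'state' or 'name' column")
  lab <- as.character(lab)
  count_by_state <- function(pk) {
    hit <- GenomicRanges::countOverlaps(states, pk,
                                        ignore.strand = TRUE) > 0
    tapply(hit, lab, sum)
  }
  obs <- count_by_state(peaks)
  null <- matrix(0, nrow = n_shuffles, ncol = length(obs),
                 dimnames = list(NULL, names(obs)))
  for (s in seq_len(n_shuffles)) {
    shuf <- shuffle_intervals(peaks, chrom_sizes, blacklist,
                              seed = seed + s)
    null[s, ] <- count_by_state(shuf)[names(obs)]
  }
  nreg <- tapply(rep(1L, length(lab)), lab, sum)
  keep <- nreg > 0
  if (any(!keep)) warning("state(s) with zero regions omitted")
  expected <- colMeans(null)
  data.frame(
    state = names(obs)[keep],
    n_regions = as.integer(nreg[keep]),
    observed = as.integer(obs[keep]),
    expected = expected[keep],
    ratio = ifelse(expected[keep] > 0, obs[keep] / expected[keep],
                   ifelse(obs[keep] > 0, Inf, 0)),
    sd_null = apply(null, 2, stats::sd)[keep],
    overlap_pct = 100 * obs[keep] / nreg[keep],
    p_value = vapply(seq_along(obs), function(j)
      (1 + sum(null[, j] >= obs[j])) / (1 + n_shuffles), numeric(1))[keep],
    n_shuffles = n_shuffles,
    row.names = NULL)
}

#' Peak-set overlap enrichment against a shuffle null
#'
#' Percentage of peaks in `peaksA` overlapping (>= 1 bp) any peak in
#' `peaksB`, with fold enrichment relative to `n_permutations` random
#' re-placements of `peaksA`, and an add-one empirical p-value.
#'
#' @param peaksA,peaksB Non-empty `GRanges`.
#' @inheritParams shuffle_intervals
#' @param n_permutations Number of null draws (default 10).
#' @return One-row data frame: `n_A`, `observed`, `overlap_pct`,
#'   `expected`, `fold`, `p_value`, `n_permutations`.
#' @export
peak_overlap_enrichment <- function(peaksA, peaksB, chrom_sizes,
                                    blacklist = NULL, n_permutations = 10,
                                    seed = 1) {
  if (!length(peaksA) || !length(peaksB))
    stop("both peak sets must be non-empty")
  n_hit <- function(a) sum(GenomicRanges::countOverlaps(
    a, peaksB, ignore.strand = TRUE) > 0)
  obs <- n_hit(peaksA)
  null <- vapply(seq_len(n_permutations), function(s)
    n_hit(shuffle_intervals(peaksA, chrom_sizes, blacklist,
                            seed = seed + s)), numeric(1))
  expected <- mean(null)
  data.frame(
    n_A = length(peaksA),
    observed = obs,
    overlap_pct = 100 * obs / length(peaksA),
    expected = expected,
    fold = if (expected > 0) obs / expected else if (obs > 0) Inf else 0,
    p_value = (1 + sum(null >= obs)) / (1 + n_permutations),
    n_permutations = n_permutations)
}

#' Region-centred signal matrix
#'
#' Each region is represented by its midpoint +/- `flank`, divided into
#' `n_columns` equal windows; each cell is the base-weighted mean signal
#' in its window.  Windows reaching beyond a chromosome end are
#' missing-value cells.  Rows are ordered by decreasing row mean of
#' `order_track` (default: the plotted track itself), the layout of
#' signal heatmaps centred on peaks, TSSs or enhancers.
#'
#' @param track Coverage track (`RleList`).
#' @param regions `GRanges` of regions to centre on.
#' @param flank Half-width of the window in bp, > 0.
#' @param n_columns Number of columns, >= 1.
#' @param order_track Optional second track whose row means define the
#'   row order.
#' @return List: `matrix` (regions x columns), `regions` (reordered
#'   `GRanges`), `col_means` (column means over rows, NA-aware).
#' @export
region_matrix <- function(track, regions, flank, n_columns = 50,
                          order_track = NULL) {
  if (flank <= 0) stop("flank must be > 0")
  if (n_columns < 1L) stop("n_columns must be >= 1")
  cs <- track_chrom_sizes(track)
  mids <- floor((GenomicRanges::start(regions) +
                 GenomicRanges::end(regions)) / 2)
  chrs <- as.character(GenomicRanges::seqnames(regions))
  ok <- chrs %in% names(cs) & mids >= 1 & mids <= cs[chrs]
  if (any(!ok)) {
    warning(sum(!ok), " region(s) with off-chromosome midpoint dropped")
    regions <- regions[ok]; mids <- mids[ok]; chrs <- chrs[ok]
  }
  edges <- round(seq(-flank, flank, length.out = n_columns + 1L))
  fill <- function(tr) {
    m <- matrix(NA_real_, nrow = length(regions), ncol = n_columns)
    for (i in seq_along(regions)) {
      lo <- mids[i] + edges[-length(edges)]       # 1-based starts
      hi <- mids[i] + edges[-1L] - 1L             # inclusive ends
      inb <- lo >= 1 & hi <= cs[chrs[i]]
      if (!any(inb)) next
      v <- IRanges::Views(tr[[chrs[i]]],
                          IRanges::IRanges(lo[inb], hi[inb]))
      m[i, inb] <- IRanges::viewMeans(v)
    }
    m
  }
  m <- fill(track)
  om <- if (is.null(order_track)) m else fill(order_track)
  ord <- order(-rowMeans(om, na.rm = TRUE))
  list(matrix = m[ord, , drop = FALSE],
       regions = regions[ord],
       col_means = colMeans(m, na.rm = TRUE))
}
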
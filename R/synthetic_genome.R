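#' Synthetic genome specification
#'
#' Defines the toy genome over which synthetic coverage tracks and
#' annotations are generated: chromosome sizes, the resolution of the
#' emitted piecewise-constant tracks, and the master seed from which all
#' per-track substreams are derived.  The default two 2.5-Mb chromosomes
#' give thousands of 1-kb analysis bins while keeping every pipeline
#' stage at seconds scale.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param resolution Track resolution in bp (default 10, matching
#'   coverage quantified in 10-bp bins).
#' @param seed Master seed.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(chrom_sizes = c(chrS1 = 2.5e6, chrS2 = 2.5e6),
                        resolution = 10, seed = 1) {
  check_chrom_sizes(chrom_sizes)
  if (resolution <= 0) stop("resolution must be > 0")
  structure(list(chrom_sizes = chrom_sizes, resolution = resolution,
                 seed = seed), class = "genome_spec")
}

#' Synthetic mark specification
#'
#' Feature geometry and signal levels for the three simulated marks:
#' megabase-scale broad H3K9me2 domains, kilobase-scale H3K4me1 peaks
#' partially inside those domains, and intermediate H3K9me3 blocks.
#' Widths are scaled to the default 5-Mb toy genome; coverage fractions
#' follow the real marks' character (H3K9me2 very broad and abundant,
#' H3K4me1 narrow and sparse).
#'
#' @param k9me2_width,k4me1_width,k9me3_width Length-2 vectors giving the
#'   (min, max) feature width in bp.
#' @param k9me2_cov,k4me1_cov,k9me3_cov Target genome coverage fractions
#'   in (0, 1).
#' @param k4me1_in_domain Fraction of H3K4me1 peaks placed inside H3K9me2
#'   domains.
#' @param level Named signal levels inside features.
#' @param background Background signal outside features.
#' @param smooth_bins Width (in resolution bins) of the masked
#'   moving-average that tapers feature edges.
#' @param noise_sd Gaussian noise SD added to each emitted track.
#' @return A `mark_spec` list.
#' @export
mark_spec <- function(k9me2_width = c(2e5, 6e5), k9me2_cov = 0.4,
                      k4me1_width = c(500, 2000), k4me1_cov = 0.04,
                      k9me3_width = c(1e4, 5e4), k9me3_cov = 0.08,
                      k4me1_in_domain = 0.5,
                      level = c(K9me2 = 5, K4me1 = 10, K9me3 = 5),
                      background = 0.2, smooth_bins = 5, noise_sd = 0.3) {
  for (f in c(k9me2_cov, k4me1_cov, k9me3_cov))
    if (f < 0 || f >= 1) stop("coverage fractions must be in [0, 1)")
  if (any(level < 0) || background < 0 || noise_sd < 0)
    stop("signal levels, background and noise_sd must be >= 0")
  structure(list(k9me2_width = k9me2_width, k9me2_cov = k9me2_cov,
                 k4me1_width = k4me1_width, k4me1_cov = k4me1_cov,
                 k9me3_width = k9me3_width, k9me3_cov = k9me3_cov,
                 k4me1_in_domain = k4me1_in_domain, level = level,
                 background = background, smooth_bins = smooth_bins,
                 noise_sd = noise_sd), class = "mark_spec")
}

#' Reader-track coupling specification
#'
#' Weights of the rule generating the reader-domain (TTD-like) track from
#' the mark tracks: the signal follows H3K4me1 wherever a broad
#' H3K9me2/3 domain is present (the double-mark product terms), with a
#' weaker contribution from H3K9me2 alone.
#'
#' @param alpha Weight of K4me1 x 1(K9me2 domain).
#' @param beta Weight of K9me2 alone.
#' @param gamma Weight of K4me1 x 1(K9me3 domain).
#' @param noise_sd Gaussian noise SD of the reader track.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(alpha = 1, beta = 0.1, gamma = 0.5,
                          noise_sd = 0.3) {
  if (alpha < 0 || beta < 0 || gamma < 0 || noise_sd < 0)
    stop("coupling weights and noise_sd must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 noise_sd = noise_sd), class = "coupling_spec")
}

# Place non-overlapping features on one chromosome hitting a target
# covered fraction: widths drawn uniform in range, gaps by stick-breaking.
place_features <- function(chrom_len, width_range, cov_frac) {
  target <- cov_frac * chrom_len
  widths <- numeric(0)
  while (sum(widths) < target) {
    w <- round(stats::runif(1, width_range[1], width_range[2]))
    if (sum(widths) + w > target)
      w <- max(round(target - sum(widths)), 1)
    widths <- c(widths, w)
  }
  n <- length(widths)
  free <- chrom_len - sum(widths)
  if (free < 0) stop("features exceed chromosome length")
  cuts <- sort(stats::runif(n, 0, free))
  gaps <- diff(c(0, cuts))                    # leading gaps; rest trails
  starts <- cumsum(gaps) + cumsum(c(0, widths[-n])) + 1
  IRanges::IRanges(start = round(starts), width = widths)
}

place_mark <- function(chrom_sizes, width_range, cov_frac) {
  si <- GenomeInfoDb::Seqinfo(names(chrom_sizes), unname(chrom_sizes))
  grl <- lapply(names(chrom_sizes), function(chr) {
    ir <- place_features(chrom_sizes[[chr]], width_range, cov_frac)
    GenomicRanges::GRanges(rep(chr, length(ir)), ir, seqinfo = si)
  })
  GenomicRanges::sort(do.call(c, grl))
}

# Masked smoothing: moving average of the indicator, then masked back to
# the feature support so the signal is nonzero exactly on feature bases.
masked_smooth <- function(ind, k) {
  if (k <= 1) return(ind)
  sm <- stats::filter(ind, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- ind[is.na(sm)]
  as.numeric(sm) * ind
}

# Expand per-bin values to a base-resolution Rle for one chromosome.
bins_to_rle <- function(values, chrom_len, res) {
  reps <- rep(res, length(values))
  reps[length(reps)] <- chrom_len - res * (length(values) - 1L)
  S4Vectors::Rle(values, reps)
}

feature_indicator <- function(features, chr, n_bins, res) {
  ind <- numeric(n_bins)
  f <- features[as.character(GenomicRanges::seqnames(features)) == chr]
  if (length(f)) {
    for (i in seq_along(f)) {
      b0 <- ceiling(GenomicRanges::start(f)[i] / res)
      b1 <- ceiling(GenomicRanges::end(f)[i] / res)
      ind[b0:min(b1, n_bins)] <- 1
    }
  }
  ind
}

#' Generate coupled synthetic coverage tracks
#'
#' Emits five coverage tracks (`K9me2`, `K4me1`, `K9me3`, `TTD`,
#' `input`) plus the truth intervals of every planted feature.  Mark
#' tracks are masked-smoothed boxcars over the planted features, plus
#' background and Gaussian noise.  The reader track follows the
#' double-mark rule of [coupling_spec()]:
#' `alpha * K4me1fg * 1(K9me2 dom) + gamma * K4me1fg * 1(K9me3 dom) +
#'  beta * K9me2fg + noise`, floored at 0, where `*fg` are the clean
#' (background- and noise-free) foreground signals.  All randomness
#' derives from `genome$seed` through fixed per-track substreams, so the
#' same spec reproduces identical output.
#'
#' @param genome A [genome_spec()].
#' @param marks A [mark_spec()].
#' @param coupling A [coupling_spec()].
#' @return List: `tracks` (named list of `RleList`), `truth` (named list
#'   of `GRanges`: `k9me2_domains`, `k4me1_peaks`, `k9me3_domains`),
#'   `chrom_sizes`.
#' @export
generate_tracks <- function(genome, marks = mark_spec(),
                            coupling = coupling_spec()) {
  stopifnot(inherits(genome, "genome_spec"), inherits(marks, "mark_spec"),
            inherits(coupling, "coupling_spec"))
  cs <- genome$chrom_sizes
  res <- genome$resolution

  k9me2 <- with_seed(genome$seed + 101L,
                     place_mark(cs, marks$k9me2_width, marks$k9me2_cov))
  k9me3 <- with_seed(genome$seed + 102L,
                     place_mark(cs, marks$k9me3_width, marks$k9me3_cov))
  k4me1 <- with_seed(genome$seed + 103L,
                     place_k4me1(cs, marks, k9me2))

  tracks <- list()
  fg <- list()
  specs <- list(K9me2 = k9me2, K4me1 = k4me1, K9me3 = k9me3)
  for (j in seq_along(specs)) {
    nm <- names(specs)[j]
    per_chr <- list(); per_chr_fg <- list()
    for (chr in names(cs)) {
      n_bins <- ceiling(cs[[chr]] / res)
      ind <- feature_indicator(specs[[j]], chr, n_bins, res)
      clean <- masked_smooth(ind, marks$smooth_bins) * marks$level[[nm]]
      noise <- with_seed(genome$seed + 200L + 10L * j + match(chr, names(cs)),
                         stats::rnorm(n_bins, 0, marks$noise_sd))
      per_chr_fg[[chr]] <- bins_to_rle(clean, cs[[chr]], res)
      per_chr[[chr]] <- bins_to_rle(
        pmax(clean + marks$background + noise, 0), cs[[chr]], res)
    }
    tracks[[nm]] <- methods::as(per_chr, "SimpleRleList")
    fg[[nm]] <- methods::as(per_chr_fg, "SimpleRleList")
  }

  ttd <- list(); input <- list()
  for (chr in names(cs)) {
    n_bins <- ceiling(cs[[chr]] / res)
    ind2 <- feature_indicator(k9me2, chr, n_bins, res)
    ind3 <- feature_indicator(k9me3, chr, n_bins, res)
    fg4 <- as.numeric(rle_to_bins(fg$K4me1[[chr]], res, n_bins))
    fg2 <- as.numeric(rle_to_bins(fg$K9me2[[chr]], res, n_bins))
    mu <- coupling$alpha * fg4 * ind2 + coupling$gamma * fg4 * ind3 +
      coupling$beta * fg2
    noise <- with_seed(genome$seed + 300L + match(chr, names(cs)),
                       stats::rnorm(n_bins, 0, coupling$noise_sd))
    ttd[[chr]] <- bins_to_rle(pmax(mu + noise, 0), cs[[chr]], res)
    inoise <- with_seed(genome$seed + 400L + match(chr, names(cs)),
                        stats::rnorm(n_bins, 0, marks$noise_sd))
    input[[chr]] <- bins_to_rle(pmax(marks$background + inoise, 0),
                                cs[[chr]], res)
  }
  tracks$TTD <- methods::as(ttd, "SimpleRleList")
  tracks$input <- methods::as(input, "SimpleRleList")

  list(tracks = tracks,
       truth = list(k9me2_domains = k9me2, k4me1_peaks = k4me1,
                    k9me3_domains = k9me3),
       chrom_sizes = cs)
}

# Per-bin values of a base-resolution Rle (inverse of bins_to_rle).
rle_to_bins <- function(r, res, n_bins) {
  idx <- pmin(seq(1, by = res, length.out = n_bins), length(r))
  as.numeric(r[idx])
}

# K4me1 peaks: a fraction placed inside K9me2 domains, the rest outside,
# non-overlapping among themselves.
place_k4me1 <- function(chrom_sizes, marks, domains) {
  target <- marks$k4me1_cov * sum(chrom_sizes)
  si <- GenomeInfoDb::Seqinfo(names(chrom_sizes), unname(chrom_sizes))
  placed <- GenomicRanges::GRanges(seqinfo = si)
  guard <- 0L
  while (sum(GenomicRanges::width(placed)) < target && guard < 10000L) {
    guard <- guard + 1L
    w <- round(stats::runif(1, marks$k4me1_width[1], marks$k4me1_width[2]))
    inside <- stats::runif(1) < marks$k4me1_in_domain
    cand <- NULL
    for (try in 1:50) {
      if (inside && length(domains)) {
        d <- domains[sample.int(length(domains), 1L)]
        if (GenomicRanges::width(d) <= w + 1) next
        st <- GenomicRanges::start(d) +
          sample.int(GenomicRanges::width(d) - w, 1L) - 1L
        g <- GenomicRanges::GRanges(GenomicRanges::seqnames(d),
                                    IRanges::IRanges(st, width = w))
      } else {
        chr <- sample(names(chrom_sizes), 1L,
                      prob = pmax(chrom_sizes - w, 0))
        st <- sample.int(chrom_sizes[[chr]] - w + 1L, 1L)
        g <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, width = w))
        if (length(GenomicRanges::findOverlaps(g, domains)) > 0)
          next  # this draw must land outside the domains
      }
      GenomeInfoDb::seqlevels(g) <- GenomeInfoDb::seqlevels(si)
      GenomeInfoDb::seqinfo(g) <- si
      if (!length(GenomicRanges::findOverlaps(g, placed))) {
        cand <- g
        break
      }
    }
    if (!is.null(cand)) placed <- c(placed, cand)
  }
  GenomicRanges::sort(placed)
}

#' Generate chromatin-state annotation, TSSs and enhancer-gene map
#'
#' Paints a gap-free, non-overlapping chromatin-state partition over the
#' genome (Quiescent background, Heterochromatin over K9me2 domains,
#' FlankingTSS around sampled TSS positions, Enhancer intervals painted
#' last), places `n_enhancers` enhancers over planted K4me1 peaks with
#' probability `fidelity` (elsewhere uniformly), and assigns each
#' enhancer to a gene.
#'
#' @param genome A [genome_spec()].
#' @param k4me1_peaks `GRanges` of planted K4me1 peaks (truth from
#'   [generate_tracks()]).
#' @param k9me2_domains Optional `GRanges` used for the Heterochromatin
#'   state.
#' @param n_enhancers,n_tss Numbers of enhancers and TSSs.
#' @param fidelity Probability that an enhancer is placed over a K4me1
#'   peak, in [0, 1].
#' @param enhancer_width,tss_flank Feature geometry in bp.
#' @param genes Character vector of gene names to cycle enhancers over
#'   (default `gene0001`...).
#' @param seed Integer seed.
#' @return List: `states` (`GRanges`, partition with `state` column),
#'   `tss` (`GRanges`), `enhancer_map` (data.frame `enhancer_id`, `chrom`,
#'   `start`, `end`, `gene`), `enhancers` (`GRanges`).
#' @export
generate_annotations <- function(genome, k4me1_peaks,
                                 k9me2_domains = NULL,
                                 n_enhancers = 200, n_tss = 150,
                                 fidelity = 0.9, enhancer_width = 1000,
                                 tss_flank = 1000, genes = NULL,
                                 seed = genome$seed) {
  stopifnot(inherits(genome, "genome_spec"))
  if (fidelity < 0 || fidelity > 1) stop("fidelity must be in [0, 1]")
  cs <- genome$chrom_sizes
  si <- GenomeInfoDb::Seqinfo(names(cs), unname(cs))
  with_seed(seed + 500L, {
    # sample enhancer centres
    enh <- vector("list", n_enhancers)
    for (i in seq_len(n_enhancers)) {
      if (stats::runif(1) < fidelity && length(k4me1_peaks)) {
        pk <- k4me1_peaks[sample.int(length(k4me1_peaks), 1L)]
        centre <- floor((GenomicRanges::start(pk) +
                         GenomicRanges::end(pk)) / 2)
        chr <- as.character(GenomicRanges::seqnames(pk))
      } else {
        chr <- sample(names(cs), 1L, prob = cs)
        centre <- sample.int(cs[[chr]], 1L)
      }
      st <- max(1L, centre - enhancer_width %/% 2)
      en <- min(cs[[chr]], st + enhancer_width - 1L)
      enh[[i]] <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en),
                                         seqinfo = si)
    }
    enhancers <- do.call(c, enh)

    tss_chr <- sample(names(cs), n_tss, replace = TRUE, prob = cs)
    tss_pos <- vapply(tss_chr, function(chr) sample.int(cs[[chr]], 1L),
                      integer(1))
    tss <- GenomicRanges::sort(GenomicRanges::GRanges(
      tss_chr, IRanges::IRanges(tss_pos, width = 1L), seqinfo = si))

    # paint states at track resolution, later paints take priority
    res <- genome$resolution
    states <- list()
    paint <- function(vec, gr, chr, code) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == chr]
      if (length(g)) for (i in seq_along(g)) {
        b0 <- max(1L, ceiling(GenomicRanges::start(g)[i] / res))
        b1 <- ceiling(GenomicRanges::end(g)[i] / res)
        vec[b0:min(b1, length(vec))] <- code
      }
      vec
    }
    labels <- c("Quiescent", "Heterochromatin", "FlankingTSS", "Enhancer")
    out <- list()
    for (chr in names(cs)) {
      n_bins <- ceiling(cs[[chr]] / res)
      v <- rep(1L, n_bins)
      if (!is.null(k9me2_domains))
        v <- paint(v, k9me2_domains, chr, 2L)
      v <- paint(v, GenomicRanges::trim(suppressWarnings(
        GenomicRanges::resize(tss, 2L * tss_flank + 1L,
                              fix = "center"))), chr, 3L)
      v <- paint(v, enhancers, chr, 4L)
      r <- rle(v)
      ends_bin <- cumsum(r$lengths)
      starts_bin <- ends_bin - r$lengths + 1L
      st <- (starts_bin - 1L) * res + 1L
      en <- pmin(ends_bin * res, cs[[chr]])
      out[[chr]] <- GenomicRanges::GRanges(
        chr, IRanges::IRanges(st, en), state = labels[r$values],
        seqinfo = si)
    }
    states <- GenomicRanges::sort(do.call(c, unname(out)))

    if (is.null(genes))
      genes <- sprintf("gene%04d", seq_len(n_enhancers))
    gene_for <- rep_len(genes, n_enhancers)
    enhancer_map <- data.frame(
      enhancer_id = sprintf("enh%04d", seq_len(n_enhancers)),
      chrom = as.character(GenomicRanges::seqnames(enhancers)),
      start = GenomicRanges::start(enhancers) - 1L,   # 0-based half-open
      end = GenomicRanges::end(enhancers),
      gene = gene_for)
    list(states = states, tss = tss, enhancer_map = enhancer_map,
         enhancers = enhancers)
  })
}

#' Synthetic expression-design specification
#'
#' Parameters of the simulated two-channel rescue experiment: per-gene
#' log2 fold changes versus mock for a wild-type (WT) rescue and a
#' reader-dead (TTD*) rescue, with probe-level multiplicity, a planted
#' set of genes that are WT-non-responsive but upregulated under TTD*,
#' and an enhancer H3K4me1 shift (`delta_sd`, in units of the
#' between-enhancer SD) on the planted genes' enhancers.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Range (min, max) of probes per gene.
#' @param n_planted Size of the planted TTD*-dependent set (default 115).
#' @param planted_log2fc TTD*-channel log2 FC of planted genes (default 1,
#'   i.e. 2-fold).
#' @param n_wt_responsive Number of genes made WT-responsive (disjoint
#'   from the planted set).
#' @param wt_log2fc Log2 FC magnitude of WT-responsive genes.
#' @param noise_sd SD of the null log2 FC noise.
#' @param delta_sd Enhancer-K4me1 shift of planted genes, in SD units.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(n_genes = 2000, probes_per_gene = c(1, 3),
                            n_planted = 115, planted_log2fc = 1,
                            n_wt_responsive = 200, wt_log2fc = 1.2,
                            noise_sd = 0.1, delta_sd = 2) {
  if (n_planted + n_wt_responsive > n_genes)
    stop("planted and WT-responsive sets exceed the gene universe")
  structure(list(n_genes = n_genes, probes_per_gene = probes_per_gene,
                 n_planted = n_planted, planted_log2fc = planted_log2fc,
                 n_wt_responsive = n_wt_responsive, wt_log2fc = wt_log2fc,
                 noise_sd = noise_sd, delta_sd = delta_sd),
            class = "expression_spec")
}

#' Generate a probe-level expression table with planted structure
#'
#' Simulates probe-level log2 fold changes (vs mock) for a WT-rescue and
#' a TTD*-rescue channel.  Planted TTD*-dependent genes are
#' WT-non-responsive but shifted by `planted_log2fc` in the TTD* channel;
#' a disjoint WT-responsive set is shifted (half up, half down) in both
#' channels; all remaining genes are null noise.  If `enhancer_marks` is
#' supplied, a copy is returned in which the planted genes' enhancers
#' have their K4me1 signal shifted by `delta_sd` standard deviations.
#'
#' @param spec An [expression_spec()].
#' @param enhancer_marks Optional data.frame with columns `gene` and
#'   `K4me1` (per-enhancer signal), e.g. built from
#'   [generate_annotations()] output plus [mean_signal()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List: `probes` (data.frame `probe_id`, `gene`, `WT`,
#'   `TTDstar`), `truth` (list of gene-name vectors `planted`,
#'   `wt_responsive`), `enhancer_marks` (shifted copy or `NULL`).
#' @export
generate_expression <- function(spec, enhancer_marks = NULL, seed = 1) {
  stopifnot(inherits(spec, "expression_spec"))
  with_seed(seed + 700L, {
    genes <- sprintf("gene%04d", seq_len(spec$n_genes))
    planted <- genes[seq_len(spec$n_planted)]
    wt_resp <- genes[spec$n_planted + seq_len(spec$n_wt_responsive)]

    npr <- sample(seq(spec$probes_per_gene[1], spec$probes_per_gene[2]),
                  spec$n_genes, replace = TRUE)
    gene_col <- rep(genes, npr)
    n_probe <- length(gene_col)

    mu_wt <- stats::setNames(numeric(spec$n_genes), genes)
    mu_td <- stats::setNames(numeric(spec$n_genes), genes)
    sgn <- rep(c(1, -1), length.out = spec$n_wt_responsive)
    mu_wt[wt_resp] <- sgn * spec$wt_log2fc
    mu_td[wt_resp] <- sgn * spec$wt_log2fc  # rescue-independent response
    mu_td[planted] <- spec$planted_log2fc

    probes <- data.frame(
      probe_id = sprintf("probe%06d", seq_len(n_probe)),
      gene = gene_col,
      WT = mu_wt[gene_col] + stats::rnorm(n_probe, 0, spec$noise_sd),
      TTDstar = mu_td[gene_col] + stats::rnorm(n_probe, 0, spec$noise_sd),
      row.names = NULL)

    shifted <- NULL
    if (!is.null(enhancer_marks)) {
      if (!all(c("gene", "K4me1") %in% names(enhancer_marks)))
        stop("enhancer_marks needs 'gene' and 'K4me1' columns")
      shifted <- enhancer_marks
      s <- stats::sd(shifted$K4me1)
      if (!is.finite(s) || s == 0) s <- 1
      hit <- shifted$gene %in% planted
      shifted$K4me1[hit] <- shifted$K4me1[hit] + spec$delta_sd * s
    }
    list(probes = probes,
         truth = list(planted = planted, wt_responsive = wt_resp),
         enhancer_marks = shifted)
  })
}
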
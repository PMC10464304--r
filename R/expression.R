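#' Collapse probe-level fold changes to gene level
#'
#' Per-gene, per-condition median of the probe log2 fold changes, the
#' standard probe-to-gene summary when several array probes map to one
#' gene symbol.  Genes with duplicate symbols are merged by symbol.
#'
#' @param probes Data frame with `probe_id`, `gene`, and one numeric
#'   column per condition.
#' @return Data frame with `gene` plus the per-condition medians, one row
#'   per gene, in gene-name order.
#' @export
gene_medians <- function(probes) {
  if (!all(c("probe_id", "gene") %in% names(probes)))
    stop("probes needs 'probe_id' and 'gene' columns")
  cond <- setdiff(names(probes), c("probe_id", "gene"))
  cond <- cond[vapply(probes[cond], is.numeric, logical(1))]
  if (!length(cond)) stop("no numeric condition columns found")
  dt <- data.table::as.data.table(probes)
  out <- dt[, lapply(.SD, stats::median), by = "gene", .SDcols = cond]
  out <- as.data.frame(out[order(gene)])
  out
}

#' Call differentially regulated genes (DRGs)
#'
#' Classifies genes by a linear-scale fold-change threshold applied to
#' log2 fold changes: up if `log2FC >= log2(fc_threshold)`, down if
#' `log2FC <= -log2(fc_threshold)` (boundaries inclusive), otherwise
#' non-responder.  The three sets partition the gene universe.
#'
#' @param genes Gene-level table from [gene_medians()].
#' @param condition Name of the condition column to threshold.
#' @param fc_threshold Linear fold-change cutoff, > 1 (default 1.5).
#' @return A `drg_sets` list: `up`, `down`, `non_responder` (character
#'   vectors), `condition`, `fc_threshold`, `universe`.
#' @export
call_drgs <- function(genes, condition, fc_threshold = 1.5) {
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  if (!condition %in% names(genes))
    stop("missing condition column: ", condition)
  lfc <- genes[[condition]]
  thr <- log2(fc_threshold)
  structure(list(
    up = genes$gene[lfc >= thr],
    down = genes$gene[lfc <= -thr],
    non_responder = genes$gene[abs(lfc) < thr],
    condition = condition, fc_threshold = fc_threshold,
    universe = genes$gene), class = "drg_sets")
}

#' Reader-dependent gene set
#'
#' Genes whose silencing requires the reader domain: non-responders under
#' the wild-type rescue that are upregulated under the reader-dead
#' (TTD*) rescue.
#'
#' @param drg_wt,drg_ttdstar `drg_sets` from [call_drgs()] over the same
#'   gene universe.
#' @return Character vector of gene names.
#' @export
ttd_dependent_set <- function(drg_wt, drg_ttdstar) {
  stopifnot(inherits(drg_wt, "drg_sets"), inherits(drg_ttdstar, "drg_sets"))
  if (!length(intersect(drg_wt$universe, drg_ttdstar$universe)))
    stop("disjoint gene universes")
  intersect(drg_wt$non_responder, drg_ttdstar$up)
}

#' Enhancer mark-signal association between gene groups
#'
#' Compares a mark's mean enhancer signal between gene groups (e.g. the
#' reader-dependent upregulated set versus non-responders): per-group
#' distribution summaries, classical one-way ANOVA (equal-variance F), and
#' Bonferroni-multiplied pairwise t-test p-values (pooled SD, capped at 1).
#'
#' @param groups Named list of character gene-name vectors; names are the
#'   group labels.
#' @param enhancer_marks Data frame with `gene` and the signal column.
#' @param signal Name of the signal column (default `"K4me1"`).
#' @param welch If `TRUE`, use Welch's unequal-variance ANOVA instead of
#'   the classical equal-variance F test.
#' @return List: `summary` (per-group n/median/quartiles/p5/p95),
#'   `anova` (`F`, `df1`, `df2`, `p`), `pairwise` (Bonferroni-adjusted
#'   p matrix), `degenerate` (TRUE when all groups have zero variance).
#' @export
mark_association <- function(groups, enhancer_marks, signal = "K4me1",
                             welch = FALSE) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list of gene sets")
  if (!all(c("gene", signal) %in% names(enhancer_marks)))
    stop("enhancer_marks needs 'gene' and '", signal, "' columns")
  vals <- list()
  for (g in names(groups)) {
    v <- enhancer_marks[[signal]][enhancer_marks$gene %in% groups[[g]]]
    if (length(v) < 2L)
      stop("group '", g, "' has fewer than 2 enhancers with signal")
    vals[[g]] <- v
  }
  y <- unlist(vals, use.names = FALSE)
  grp <- factor(rep(names(vals), lengths(vals)), levels = names(vals))

  summ <- do.call(rbind, lapply(names(vals), function(g) {
    q <- stats::quantile(vals[[g]], c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE)
    data.frame(group = g, n = length(vals[[g]]), p5 = q[1], p25 = q[2],
               median = q[3], p75 = q[4], p95 = q[5],
               mean = mean(vals[[g]]))
  }))

  degenerate <- all(vapply(vals, function(v) stats::sd(v) == 0, logical(1)))
  if (degenerate && length(unique(vapply(vals, mean, numeric(1)))) == 1L) {
    an <- list(F = 0, df1 = length(vals) - 1L,
               df2 = length(y) - length(vals), p = 1)
  } else {
    tst <- stats::oneway.test(y ~ grp, var.equal = !welch)
    an <- list(F = unname(tst$statistic),
               df1 = unname(tst$parameter[1]),
               df2 = unname(tst$parameter[2]),
               p = unname(tst$p.value))
  }
  pw <- if (length(vals) >= 2L && !degenerate) {
    stats::pairwise.t.test(y, grp, p.adjust.method = "bonferroni",
                           pool.sd = !welch)$p.value
  } else NULL
  list(summary = summ, anova = an, pairwise = pw, degenerate = degenerate)
}

#' Filter and bin genes by expression ratio
#'
#' Reproduces the expression-ratio binning used to relate reader signal
#' to differential expression between two cell types: keep genes with at
#' least `min_fold` change in either direction AND at least `min_level`
#' expression in one of the two cell types; rank ascending by ratio
#' (ties broken by gene name); split into `k` near-equal bins; summarise
#' an associated signal column per bin.
#'
#' @param genes Data frame with `gene`, two expression-level columns, and
#'   optionally a signal column.
#' @param level_a,level_b Names of the two expression columns (ratio =
#'   `level_a / level_b`).
#' @param signal Optional name of a per-gene signal column to summarise.
#' @param min_level Minimum expression in at least one cell type
#'   (default 1000).
#' @param min_fold Minimum fold change in either direction (default 2).
#' @param k Number of bins (default 5).
#' @return List: `genes` (filtered table with `ratio` and integer `bin`,
#'   bin 1 = lowest ratio), `summary` (per-bin n, median ratio, and
#'   signal quantiles when `signal` is given).
#' @export
expression_ratio_bins <- function(genes, level_a, level_b, signal = NULL,
                                  min_level = 1000, min_fold = 2, k = 5) {
  for (col in c(level_a, level_b))
    if (!col %in% names(genes)) stop("missing column: ", col)
  a <- genes[[level_a]]; b <- genes[[level_b]]
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE))
    stop("expression levels must be >= 0")
  ratio <- a / b
  keep <- is.finite(ratio) & (ratio >= min_fold | ratio <= 1 / min_fold) &
    (pmax(a, b) >= min_level)
  kept <- genes[keep, , drop = FALSE]
  kept$ratio <- ratio[keep]
  n <- nrow(kept)
  if (n < k) stop("fewer genes (", n, ") than bins (", k, ") after filtering")
  ord <- order(kept$ratio, kept$gene)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[ord] <- rep(seq_len(k), times = sizes)
  kept$bin <- bin
  summ <- do.call(rbind, lapply(seq_len(k), function(j) {
    sub <- kept[kept$bin == j, , drop = FALSE]
    row <- data.frame(bin = j, n = nrow(sub),
                      median_ratio = stats::median(sub$ratio))
    if (!is.null(signal)) {
      q <- stats::quantile(sub[[signal]],
                           c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      row <- cbind(row, data.frame(p5 = q[1], p25 = q[2], median = q[3],
                                   p75 = q[4], p95 = q[5]))
    }
    row
  }))
  list(genes = kept, summary = summ)
}
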
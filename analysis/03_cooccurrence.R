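#!/usr/bin/env Rscript
# Genome co-occurrence layer, run on the files written by
# 02_simulate_genome.R (exercising the readers end to end): 1-kb
# binning, decile split by K9me2, decile-conditioned TTD-K4me1
# correlation, 150-bp fragmentation of the double-mark feature space
# with k-means clustering, chromatin-state shuffle enrichment, and a
# peak-centred signal matrix.
#
# Writes results/cooccurrence/*.tsv

suppressPackageStartupMessages(library(dualmark))
indir <- "results/genome_sim"
outdir <- "results/cooccurrence"
if (!dir.exists(indir))
  stop("run analysis/02_simulate_genome.R first")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

cs <- read_chrom_sizes(file.path(indir, "genome.chrom.sizes"))
tracks <- sapply(c("TTD", "K4me1", "K9me2"), function(nm)
  read_bedgraph(file.path(indir, paste0(nm, ".bedGraph")), cs),
  simplify = FALSE)
peaks <- read_bed(file.path(indir, "k4me1_peaks.bed"), cs)
domains <- read_bed(file.path(indir, "k9me2_domains.bed"), cs)
states <- read_bed(file.path(indir, "chromatin_states.bed"), cs)

# decile-conditioned correlation
bins <- bin_signal(bin_genome(cs, 1000), tracks)
bins <- quantile_split(bins, "K9me2", k = 10)
cc <- conditional_correlation(bins, "TTD", "K4me1")
write_tsv_report(cc, file.path(outdir, "decile_correlation.tsv"))
write_tsv_report(group_summary(bins, "TTD"),
                 file.path(outdir, "decile_ttd_summary.tsv"))
cat(sprintf("r(TTD, K4me1): %.2f in the top K9me2 decile, %.2f in the bottom\n",
            cc$r[1], cc$r[10]))

# genome-wide binned correlations (2 kb bins)
cat(sprintf("genome-wide 2-kb r: TTD-K4me1 %.2f, TTD-K9me2 %.2f\n",
            binned_correlation(tracks$TTD, tracks$K4me1, 2000),
            binned_correlation(tracks$TTD, tracks$K9me2, 2000)))

# fragmentation + clustering of the double-mark feature space
frags <- fragment_peaks(GenomicRanges::reduce(c(peaks, domains)), cs,
                        fragment_size = 150, retention = 0.5)
frags <- bin_signal(frags, tracks)
frags <- cluster_fragments(frags, k = 3, order_by = "TTD", seed = seed)
centers <- attr(frags, "centers")
write_tsv_report(
  data.frame(cluster = seq_len(nrow(centers)), centers,
             n = attr(frags, "sizes")),
  file.path(outdir, "fragment_cluster_centers.tsv"))
cat("Cluster centres (TTD order):\n")
print(round(centers, 2))

# chromatin-state enrichment of the peaks against a shuffle null
enr <- state_enrichment(peaks, states, cs, n_shuffles = 50, seed = seed)
write_tsv_report(enr, file.path(outdir, "state_enrichment.tsv"))
cat(sprintf("Enhancer-state enrichment ratio: %.1f (p = %.3f)\n",
            enr$ratio[enr$state == "Enhancer"],
            enr$p_value[enr$state == "Enhancer"]))

# peak-centred reader signal matrix
rm <- region_matrix(tracks$TTD, peaks, flank = 2500, n_columns = 50)
write_tsv_report(data.frame(column = seq_along(rm$col_means),
                            mean_TTD = rm$col_means),
                 file.path(outdir, "peak_matrix_colmeans.tsv"))
cat("Reports in", outdir, "\n")
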
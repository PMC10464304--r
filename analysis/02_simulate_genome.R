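#!/usr/bin/env Rscript
# Synthetic-genome layer: generate the coupled toy genome (broad K9me2
# domains, kilobase K4me1 peaks partially inside them, K9me3 blocks, a
# reader track following the double-mark rule, and an input control),
# plus chromatin-state/TSS/enhancer annotations, and write everything
# as bedGraph / BED / chrom.sizes / TSV under results/genome_sim/.

suppressPackageStartupMessages(library(dualmark))
outdir <- "results/genome_sim"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

g <- genome_spec(seed = 1)            # 2 x 2.5 Mb, 10 bp resolution
sim <- generate_tracks(g)
ann <- generate_annotations(g, sim$truth$k4me1_peaks,
                            k9me2_domains = sim$truth$k9me2_domains)

write_chrom_sizes(g$chrom_sizes, file.path(outdir, "genome.chrom.sizes"))
for (nm in names(sim$tracks))
  write_bedgraph(sim$tracks[[nm]],
                 file.path(outdir, paste0(nm, ".bedGraph")))
write_bed(sim$truth$k9me2_domains, file.path(outdir, "k9me2_domains.bed"))
write_bed(sim$truth$k4me1_peaks, file.path(outdir, "k4me1_peaks.bed"))
write_bed(sim$truth$k9me3_domains, file.path(outdir, "k9me3_domains.bed"))
write_bed(ann$states, file.path(outdir, "chromatin_states.bed"))
write_bed(ann$tss, file.path(outdir, "tss.bed"))
write_tsv_report(ann$enhancer_map, file.path(outdir, "enhancer_map.tsv"))

cat("Simulated", sum(g$chrom_sizes) / 1e6, "Mb across",
    length(g$chrom_sizes), "chromosomes\n")
cat("Planted:", length(sim$truth$k9me2_domains), "K9me2 domains (",
    round(100 * sum(GenomicRanges::width(sim$truth$k9me2_domains)) /
            sum(g$chrom_sizes)), "% of genome ),",
    length(sim$truth$k4me1_peaks), "K4me1 peaks\n")
cat("Outputs in", outdir, "\n")
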
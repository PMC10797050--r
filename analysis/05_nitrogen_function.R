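#!/usr/bin/env Rscript
# Stage 5 — nitrogen-cycle gene profiles and their (de)coupling from SIN.
#
# Converts gene counts to RPKM, rolls genes up to pathways (fixation,
# nitrification, denitrification, nitrate reduction, DNRA, anammox),
# Welch-tests every gene and pathway between seasons and latitude groups
# (BH-corrected), Mantel-tests the Bray-Curtis functional dissimilarity
# against the SIN axis, and screens the top-10 genes against SIN
# concentrations.
#
# Reads results/scenario/; writes results/rpkm.tsv, results/pathways.tsv,
# results/gene_tests_{season,latitude}.tsv, results/functional_mantel.tsv,
# results/top_gene_sin.tsv.

suppressPackageStartupMessages(library(phylosin))

counts <- read_table_typed("results/scenario/genes.tsv", "gene_counts")
gm <- read_gene_map("results/scenario/gene_map.tsv")
totals_df <- read.table("results/scenario/mapped_reads.tsv", header = TRUE,
                        sep = "\t")
totals <- setNames(totals_df$total_mapped_reads, totals_df$sample_id)
env <- read_table_typed("results/scenario/env.tsv", "env")
meta <- read_sample_metadata("results/scenario/samples.tsv")

r <- rpkm(counts, setNames(gm$length_bp, gm$gene_id), totals)
write_tsv_stable(r, "results/rpkm.tsv")
pw <- aggregate_pathways(r, gm)
write_tsv_stable(pw, "results/pathways.tsv")

for (grp in c("season", "latitude_group")) {
  g <- setNames(meta[[grp]], meta$sample_id)
  gt <- spatiotemporal_tests(cbind(r, pw), g)
  out <- sprintf("results/gene_tests_%s.tsv",
                 if (grp == "season") "season" else "latitude")
  write_tsv_stable(gt, out)
  message(sprintf("%s contrast: %d/%d features with q <= 0.05",
                  grp, sum(gt$q <= 0.05, na.rm = TRUE), nrow(gt)))
}

fd <- functional_dissimilarity(r)
mant <- mantel_test(fd, absdiff_dist(sin_axis(env)), n_perm = 999, seed = 501)
write_tsv_stable(data.frame(r = mant$r, p = mant$p, n_perm = mant$n_perm),
                 "results/functional_mantel.tsv")
message(sprintf("functional dissimilarity vs |delta SIN|: Mantel r %.2f, p %.3g",
                mant$r, mant$p))

top <- top_gene_sin_correlations(r, env)
write_tsv_stable(top, "results/top_gene_sin.tsv")
message(sprintf("top-10 gene x SIN screen: %d/%d significant at q <= 0.05",
                sum(top$q <= 0.05, na.rm = TRUE), nrow(top)))
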
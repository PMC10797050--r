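#!/usr/bin/env Rscript
# Stage 4 — seasonal co-occurrence networks of dominant OTUs.
#
# Within each season, keeps the 100 most abundant OTUs, draws an edge
# where |Spearman rho| >= 0.6 with BH q <= 0.05 across samples, and
# summarizes topology: average path length (APL) and diameter (ND) on the
# largest connected component, transitivity (Tarn) on the whole graph.
#
# Reads results/scenario/; writes results/network_topology.tsv and
# results/network_edges_<season>.tsv.

suppressPackageStartupMessages(library(phylosin))

comm <- read_table_typed("results/scenario/community.tsv", "community")
meta <- read_sample_metadata("results/scenario/samples.tsv")
season <- setNames(meta$season, meta$sample_id)

nets <- group_networks(comm, season, k = 100)
write_tsv_stable(nets$topology, "results/network_topology.tsv")
for (g in names(nets$networks))
  write_tsv_stable(nets$networks[[g]]$edges,
                   sprintf("results/network_edges_%s.tsv", g))

for (i in seq_len(nrow(nets$topology)))
  message(sprintf("%s: %d edges, APL %.2f, Tarn %.3f, ND %d (%d components)",
                  nets$topology$group[i], nets$topology$n_edges[i],
                  nets$topology$APL[i], nets$topology$Tarn[i],
                  nets$topology$ND[i], nets$topology$n_components[i]))
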
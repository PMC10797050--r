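# phylosin

Phylogenetic community assembly and nitrogen-cycle function along soil
inorganic nitrogen gradients.

Estuarine intertidal soils see strong seasonal swings in inorganic
nitrogen (SIN: exchangeable NO2⁻-N, NO3⁻-N, NH4⁺-N). `phylosin` is an
analysis pipeline, for microbial ecologists working with OTU tables,
phylogenies and metagenomic gene counts, that connects those swings to
bacterial community structure through four layers:

1. **Phylogenetic α diversity with null models** — MPD and MNTD per
   sample, standardized against 999 taxa-label shuffles of the patristic
   distance matrix into NRI and NTI (positive = clustering):
   `NRI = −(MPD_obs − μ_null)/σ_null`, `NTI = −(MNTD_obs − μ_null)/σ_null`.
2. **Community assembly via phylogenetic turnover** — pairwise βMNTD and
   `βNTI = (βMNTD_obs − μ_null)/σ_null`, with pairs classed as
   deterministic (heterogeneous selection βNTI > 2, homogeneous
   selection βNTI < −2) or stochastic, then regressed and Mantel-tested
   against pairwise SIN differences.
3. **Nitrogen-cycle function** — RPKM gene abundances
   (`count / ((length/10³) × (mapped/10⁶))`), pathway rollups (nif, amo,
   nir/nor/nos, nar/nap, nrfA, hdh), Bray–Curtis functional
   dissimilarity, and Welch/BH screens for spatiotemporal differences.
4. **Path models** — observed-variable path analysis contrasting an
   environment-only model with one where a phylogenetic-diversity
   composite mediates SIN → nitrogen function, compared by the R² of the
   function node.

A first-class synthetic-data generator produces the study design these
analyses assume — 10 coastal sites × 2 seasons × 4 replicates, seasonal
SIN contrasts (NH4/NO2 high in March, NO3 high in September),
phylogenetically conserved nitrogen niches, and filtering vs neutral
assembly — so the whole chain is testable against known ground truth.
The methods vignette (`vignettes/soil-nitrogen-assembly.Rmd`) documents
the models, defaults and their rationale.

## Worked example

```r
library(phylosin)

cfg <- scenario_config(assembly_mode = "filtering", seed = 1)
sim <- simulate_scenario(cfg)

alpha <- ses_alpha(sim$community, sim$tree, n_reps = 999, seed = 11)
round(mean(alpha$nti), 2)
#> [1] 1.53

bt <- beta_nti(sim$community, sim$tree, n_reps = 999, seed = 12)
bt
#> betaNTI over 80 samples ( 3160 pairs ), 999 null reps, tau = 2
#> deterministic_heterogeneous   deterministic_homogeneous
#>                       0.610                       0.015
#>                  stochastic
#>                       0.375

betanti_mantel(bt, absdiff_dist(sin_axis(sim$env)), n_perm = 999, seed = 13)
#> Mantel r = 0.8291 (spearman), p = 0.001 (999 permutations)

season <- setNames(sim$metadata$season, sim$metadata$sample_id)
a <- anova_oneway(sim$env[, "NH4"], season[rownames(sim$env)])
sprintf("NH4: F = %.1f, p = %.2g; March %.1f vs September %.1f",
        a$F, a$p, a$group_means["March"], a$group_means["September"])
#> "NH4: F = 67.4, p = 3.7e-12; March 53.7 vs September 11.3"
```

Under environmental filtering the communities are phylogenetically
clustered (mean NTI 1.53, far above the null expectation of 0), a
majority of pairwise comparisons are deterministic (62%, almost all
heterogeneous selection along the SIN gradient), phylogenetic turnover
tracks SIN differences (Mantel r 0.83, p 0.001), and the generator's
seasonal NH4 contrast is exactly the kind of signal the ANOVA layer is
meant to flag. Running the same chain with
`assembly_mode = "neutral"` gives mean NTI ≈ 0 and a small stochastic
exceedance fraction — the calibration the null model promises.

## The analysis workflow

`analysis/` holds numbered drivers that run the study end to end on the
synthetic scenario and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # scenario -> results/scenario/
Rscript analysis/02_alpha_diversity.R   # NRI/NTI + SIN associations
Rscript analysis/03_assembly.R          # betaNTI, classes, Mantel layer
Rscript analysis/04_networks.R          # seasonal top-100 co-occurrence networks
Rscript analysis/05_nitrogen_function.R # RPKM, pathways, decoupling tests
Rscript analysis/06_path_models.R       # env-only vs phylogeny-mediated SEM
```

`run_all(run_config(...))` performs the same chain programmatically and
is byte-reproducible from its master seed.

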
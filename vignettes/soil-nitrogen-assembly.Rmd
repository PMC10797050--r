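---
title: "Linking soil inorganic nitrogen to bacterial community assembly and nitrogen-cycle function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking soil inorganic nitrogen to bacterial community assembly and nitrogen-cycle function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Estuarine intertidal soils receive strongly seasonal loads of inorganic
nitrogen (SIN: exchangeable NO2⁻-N, NO3⁻-N, NH4⁺-N). `phylosin` implements
an inference chain that asks three linked questions about such systems:

1. Does SIN structure the *phylogenetic* composition of the bacterial
   community — both within samples (clustering) and between samples
   (turnover driven by selection rather than drift)?
2. Do the *nitrogen-cycle gene profiles* of those communities respond to
   SIN directly, or are they buffered by functional redundancy?
3. When both are modelled together, is the effect of SIN on nitrogen
   function *mediated* by phylogenetic community structure?

The chain runs entirely on synthetic communities with known assembly
processes, so every stage can be validated against ground truth before it
is pointed at real data.

# Phylogenetic diversity and its null models

For a sample with relative abundances $w_i$ over taxa with patristic
distances $d_{ij}$ (sum of branch lengths on the tip-to-tip path):

* **MPD** (mean pairwise distance):
  $\sum_{i \ne j} w_i w_j d_{ij} / \sum_{i \ne j} w_i w_j$ when
  abundance-weighted, the mean over distinct present pairs otherwise.
  Note the normalization excludes the diagonal; some implementations keep
  it, which rescales weighted MPD by $1 - \sum_i w_i^2$.
* **MNTD** (mean nearest-taxon distance): the (weighted) mean over present
  taxa of the minimum distance to another present taxon.

Standardized effect sizes come from a taxa-label null: tip labels are
shuffled across the distance matrix (the pool is every tip in the tree),
the metric is recomputed for each of 999 shuffles, and

$$\mathrm{NRI} = -\frac{\mathrm{MPD}_{obs} - \mu_{null}}{\sigma_{null}},
\qquad
\mathrm{NTI} = -\frac{\mathrm{MNTD}_{obs} - \mu_{null}}{\sigma_{null}}.$$

Positive values mean phylogenetic clustering. The same construction
between samples gives βMNTD (each taxon matched to its nearest relative in
the *other* community, averaged over both directions) and

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{obs} - \mu_{null}}{\sigma_{null}},$$

with pairs classified as deterministic-heterogeneous (βNTI > τ),
deterministic-homogeneous (βNTI < −τ) or stochastic (|βNTI| ≤ τ), τ = 2 by
default. The null scheme, rep count, weighting and sign convention are all
recorded in the outputs, because none of them are standardized enough
across the literature to leave implicit.

Numerical choices worth knowing about:

* One seeded shuffle sequence is shared across all pairs within a run, so
  the βNTI matrix is exactly symmetric and a run is reproducible from its
  seed.
* Null moments are accumulated as deviations from the observed value. This
  keeps shuffle-invariant samples (e.g. a sample containing the whole
  species pool with equal abundances) at *exactly* zero null variance,
  where the degenerate-null guard (`null_sd < 1e-12` ⇒ SES := 0, flagged)
  applies. Without centering, floating-point cancellation produces
  spurious null SDs around 1e-8 and grossly inflated SES values.
* A pair of *identical* communities is degenerate by construction: a
  taxa-label shuffle relabels both communities identically, so βMNTD is 0
  in every draw. Such pairs are flagged, not classified as homogeneous
  selection.
* Samples with fewer than two present taxa get NA sentinel rows rather
  than errors; an analysis should not die on a blank sample.

The per-permutation loops are in C++ (Rcpp); a full default-scale run
(80 samples × 500 taxa × 999 reps, alpha and beta) takes around half a
minute on one core.

# The synthetic study design

`scenario_config()` encodes the study conditions the analyses assume and
is deliberately opinionated; its defaults are chosen once, for statistical
detectability at desk scale, and the tests run against them.

* **Design**: 10 sites (S01–S05 "high latitude", S06–S10 "low"), two
  seasons (March, September), 4 replicates — 80 samples; 500 OTUs; 20,000
  reads per sample.
* **Environment**: each sample carries a latent standardized SIN axis
  $z = \pm$`season_effect` $+$ site effect $+$ noise (SDs 0.6 / 0.4).
  Observed NO2, NO3, NH4 are lognormal with log-means loading on $z$
  (±0.8; NO3 negative), producing the seasonal contrast the design
  requires: NH4 and NO2 higher in March, NO3 higher in September. The
  analysis-side summary `sin_axis()` recovers the axis as the first
  principal component of the z-scored log concentrations, oriented
  positively with NH4. Non-SIN covariates (pH, moisture, CEC, TOC, DOC,
  Fe²⁺, Fe³⁺, sulfide) carry site effects; MAT and MAP are site-level
  climate constants along the latitude gradient.
* **Niches**: tip optima evolve by Brownian motion on a birth–death tree
  and are standardized to the SIN-axis scale, so relatives prefer similar
  nitrogen regimes — the ingredient that lets selection imprint on
  phylogeny.
* **Communities**: sampling weight of taxon $i$ in sample $s$ is
  $\mathrm{base}_i \times \mathrm{drift}_{is} \times
  \exp(-(z_s - o_i)^2 / 2\sigma_{niche}^2)$ under filtering (the kernel is
  dropped under neutral assembly), followed by a multinomial draw of the
  sampling depth. Base abundances are lognormal with log-SD 2 — the
  heavy-tailed abundance distribution typical of microbial communities,
  and what makes a "top 100 OTUs" selection meaningful. The per-sample
  lognormal drift term (log-SD 1.2) represents ecological drift; without
  it, samples converge on near-complete copies of the pool, which both
  lacks realism and forces the degenerate-null guard to fire. With these
  defaults per-sample occupancy is roughly 35–65% of the pool.
  $\sigma_{niche} = 0.35$ makes selection strong relative to drift: the
  filtering preset yields mean NTI well above 0.5 and a majority of
  deterministic pairs, while the neutral preset stays calibrated
  (NRI/NTI ≈ mean 0, SD ≈ 1 pooled over replicate scenarios).
* **Genes**: 16 nitrogen-cycle marker genes (nifD/H/K; amoA/B/C, hao;
  nirK/S, norB/C, nosZ; narG, napA; nrfA; hdh) with realistic lengths.
  Each taxon's copy profile is a shared baseline times a lognormal
  deviation scaled by $1 - \mathrm{redundancy}$, evolving by Brownian
  motion so function weakly tracks phylogeny; counts are Poisson draws
  scaled to each sample's total mapped reads (~2 × 10⁶). At
  `redundancy = 1` every taxon is functionally identical, which decouples
  gene profiles from community turnover entirely — the design probe for
  the functional-redundancy hypothesis.

What the generator does *not* emulate: sequencing error and chimeras,
spatial autocorrelation beyond site effects, compositional artifacts of
relative-abundance data, and seasonal turnover of the species pool itself.
Passing tests therefore demonstrate that the inference chain recovers the
processes it targets under its own assumptions; they do not certify
behaviour on real 16S/metagenome data.

# Downstream statistical layers

* **Co-occurrence networks**: per group (e.g. season), the 100 most
  abundant OTUs (mean relative abundance, lexicographic tie-break);
  edges where |Spearman ρ| ≥ 0.6 and BH q ≤ 0.05 over all pairs. Average
  path length and diameter are computed on the largest connected
  component (with the component count reported — both are undefined on
  disconnected graphs); transitivity on the whole graph, defined as 0
  when no connected triple exists. The edge rule is a field convention,
  not a derived quantity, and is carried in the result's provenance.
  Correlations are computed on total-sum-scaled relative abundances;
  compositionality-aware inference (SparCC and relatives) is out of
  scope, a known caveat.
* **RPKM**: count / ((length/10³) × (mapped reads/10⁶)), with the
  denominator taken as *mapped* reads per sample. Pathway abundances are
  sums of member-gene RPKM.
* **Group tests**: Welch's t per gene/pathway (the unequal-variance
  default is safer when group spreads differ; a pooled flag exists), BH
  across features, raw p and q both reported.
* **Mantel tests**: Spearman correlation of off-diagonal entries with a
  one-tailed permutation p, `p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1)`
  (resolution exactly 1/(n_perm+1)); the permutation engine is
  `vegan::mantel()`. All "similarity" layers are implemented as
  dissimilarities throughout, which leaves Mantel inference unchanged as
  long as usage is consistent — the pipeline enforces that.
* **Random-forest importance**: permutation increase in out-of-bag MSE as
  a percentage of baseline OOB MSE (500 trees, mtry = ⌈p/3⌉), the "MSE%"
  unit.
* **Per-taxon linear models**: arcsine-square-root transformed relative
  abundances on SIN covariates plus season, BH across taxon × covariate
  coefficients, significance called at q ≤ 0.25 (the convention of the
  multivariate-association tools this mirrors).

# Path models

The two shipped model specifications are *reconstructed* observed-variable
path diagrams (editable text files under `inst/models/`): an
environment-only model (temperature → SIN and soil covariates → nitrogen
function) and a phylogeny-mediated model adding a diversity composite
(first PC of NRI/NTI/MPD/MNTD) between SIN and function. Latent-variable
structure is deliberately avoided: the variables are measured indices, and
an unidentified measurement model would add assumptions the data cannot
check.

For a recursive DAG over observed variables, maximum-likelihood covariance
fitting and per-equation OLS on standardized variables give the same path
coefficients; the fitter therefore runs sequential standardized OLS, and a
test verifies the equivalence numerically against a direct ML optimization
of the implied covariance. A single-predictor path equals the Pearson
correlation, which is also asserted. `compare_models()` reports the plain
R² of the nitrogen-function node under both models and their ratio —
deliberately the simplest defensible reading of "variance explained
increased by a factor".

One empirical observation from the full synthetic chain is itself
informative: filtering scenarios produce strong *direct* SIN–function
associations (community composition drives both), while the
diversity-index composite is only a weak mediator — clustering summaries
do not pin down *which* clades dominate. The mediation contrast is
therefore exercised on a dedicated linear-Gaussian scenario
(`simulate_path_data()`, mediation strength 0.6 by default) where the
ground-truth coefficients are known exactly.

# Problem sizes and reproducibility

Everything stochastic takes a seed; one master seed derives per-stage
seeds (`derive_seed()`), and two runs of `run_all()` with the same
configuration produce byte-identical tables. Null-model calibration
checks pool 100+ samples over replicate scenarios of 300 taxa at depth
12,000 (depth scaled with the pool so per-taxon coverage matches the
default preset) — samples within one scenario share base abundances and
are not independent draws, so replicate scenarios, not more samples per
scenario, are what tighten the calibration estimate. Recovery checks run
the full default preset (80 samples × 500 taxa, 999 reps). The tie-break,
degenerate-input and sentinel conventions above are all asserted in the
test suite.

# Known limitations

* The taxa-label shuffle is the only null model implemented; richness- or
  frequency-constrained nulls (independent swap and relatives) can
  reclassify borderline samples.
* The deterministic/stochastic reading is two-way on βNTI; the Bray–Curtis
  based partition of the stochastic fraction into dispersal processes is
  intentionally out of scope.
* Network topology is sensitive to the (conventional) edge rule; values
  should be compared across groups built with the same rule only.
* Path models assume linear relations among observed composites and
  complete cases.
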
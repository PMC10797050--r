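#' Scenario configuration for the synthetic estuarine study
#'
#' Defaults mirror the study design the analyses assume: 10 estuarine sites
#' (S01-S05 high latitude, S06-S10 low latitude) sampled in March and
#' September with 4 replicates each (80 samples), a species pool of 500
#' OTUs, and 20,000 reads per sample. The seasonal soil-inorganic-nitrogen
#' (SIN) contrast is built in: NH4 and NO2 concentrations are higher in
#' March, NO3 higher in September, all three driven by one latent
#' standardized SIN axis that environmental filtering acts on.
#'
#' @param n_taxa Species-pool size.
#' @param n_sites Number of sites (half high, half low latitude).
#' @param samples_per_site_season Replicates per site and season.
#' @param assembly_mode `"filtering"` (niche selection on the SIN axis),
#'   `"neutral"` (abundance-only sampling), or `"mixed"` (alternate sites).
#' @param sigma_niche Niche breadth on the standardized SIN axis.
#' @param sigma_bm Brownian-motion rate for niche optima.
#' @param sampling_depth Multinomial reads per sample.
#' @param season_effect Latent SIN-axis shift of March (+) vs September (-).
#' @param site_sd,sample_sd SDs of site and residual sample effects on the
#'   latent SIN axis.
#' @param sin_loading Loading of each observed SIN variable (log scale) on
#'   the latent axis; NO3 loads negatively.
#' @param sin_noise_sd Residual log-scale noise of observed SIN variables.
#' @param base_abund_sd SD of log base abundances (heavy tails make a
#'   "top 100 OTUs" selection meaningful).
#' @param abund_noise_sd SD of per-sample lognormal abundance noise
#'   (ecological drift): each sample multiplies every taxon's weight by an
#'   independent lognormal factor, so samples are not saturated copies of
#'   the pool and stochastic turnover exists even in neutral mode.
#' @param redundancy Functional redundancy of gene-copy profiles in
#'   `[0, 1]`; 1 means every taxon carries the identical nitrogen-gene
#'   profile so community turnover cannot move gene abundances.
#' @param total_mapped_reads Mean metagenomic reads mapped per sample.
#' @param mediation_strength Diversity -> function path weight used by
#'   [simulate_path_data()].
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 500, n_sites = 10,
                            samples_per_site_season = 4,
                            assembly_mode = c("filtering", "neutral", "mixed"),
                            sigma_niche = 0.35, sigma_bm = 1,
                            sampling_depth = 20000,
                            season_effect = 1, site_sd = 0.6, sample_sd = 0.4,
                            sin_loading = 0.8, sin_noise_sd = 0.3,
                            base_abund_sd = 2, abund_noise_sd = 1.2,
                            redundancy = 0.3, total_mapped_reads = 2e6,
                            mediation_strength = 0.6,
                            seed = 1) {
  assembly_mode <- match.arg(assembly_mode)
  stopifnot(n_taxa >= 3, n_sites >= 1, samples_per_site_season >= 1,
            sigma_niche > 0, sigma_bm >= 0, sampling_depth >= 1,
            redundancy >= 0, redundancy <= 1)
  structure(as.list(environment()), class = "scenario_config")
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' @param n_taxa Number of tips (>= 3), labelled `OTU0001`, ...
#' @param birth,death Speciation and extinction rates (`birth > death >= 0`).
#' @param seed RNG seed.
#' @return An ultrametric `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, birth = 1, death = 0, seed = NULL) {
  stopifnot(n_taxa >= 3, birth > death, death >= 0)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = death))
  tr$tip.label <- sprintf("OTU%04d", seq_len(n_taxa))
  validate_tree(tr)
}

#' Simulate phylogenetically conserved nitrogen-niche optima
#'
#' Brownian motion along the tree: close relatives get similar optima on
#' the SIN axis, which is what lets environmental filtering imprint on
#' phylogeny (clustering, positive NTI).
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param sigma_bm Diffusion rate (> 0; the `sigma_bm = 0` limit returns the
#'   root value for every tip).
#' @param seed RNG seed.
#' @return Named numeric vector of tip optima.
#' @export
simulate_niche_optima <- function(tree, sigma_bm = 1, seed = NULL) {
  validate_tree(tree)
  if (sigma_bm < 0) stop("sigma_bm must be >= 0", call. = FALSE)
  if (sigma_bm == 0)
    return(setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma_bm,
                                  root.value = 0))
}

site_labels <- function(n_sites) sprintf("S%02d", seq_len(n_sites))

#' Simulate the environmental table and sample metadata
#'
#' Per-sample latent SIN axis: `season_effect` (+ for March, - for
#' September) plus Gaussian site and sample effects. Observed NO2/NO3/NH4
#' are lognormal with log-mean loading on the axis (NO3 negatively), so the
#' March/September contrast of the study design emerges: NH4 and NO2 higher
#' in March, NO3 higher in September. Non-SIN covariates (pH, moisture, CEC,
#' TOC, DOC, Fe2, Fe3, sulfide) carry site effects; MAT and MAP are
#' site-level climate constants along the latitude gradient.
#'
#' @param config A [scenario_config()].
#' @return List with `env` (samples x variables matrix), `metadata`
#'   (sample_id, site, season, latitude_group), and `sin_axis` (the latent
#'   axis each sample was generated with).
#' @export
simulate_env <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, 2), {
    sites <- site_labels(cfg$n_sites)
    grid <- expand.grid(rep = seq_len(cfg$samples_per_site_season),
                        season = c("March", "September"), site = sites,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$site, grid$season, grid$rep), ]
    n <- nrow(grid)
    sample_id <- sprintf("%s_%s_%02d", grid$site, substr(grid$season, 1, 3), grid$rep)

    site_eff <- setNames(rnorm(cfg$n_sites, 0, cfg$site_sd), sites)
    z <- ifelse(grid$season == "March", cfg$season_effect, -cfg$season_effect) +
      site_eff[grid$site] + rnorm(n, 0, cfg$sample_sd)

    ln <- function(base, load) exp(base + load * z + rnorm(n, 0, cfg$sin_noise_sd))
    NO2 <- ln(log(0.3), cfg$sin_loading)
    NH4 <- ln(log(15),  cfg$sin_loading)
    NO3 <- ln(log(8),  -cfg$sin_loading)

    site_idx <- match(grid$site, sites)
    cov_site <- function(sd) setNames(rnorm(cfg$n_sites, 0, sd), sites)[grid$site]
    pH <- 7.6 + cov_site(0.3) + rnorm(n, 0, 0.15)
    MC <- pmax(exp(log(30) + cov_site(0.25) + rnorm(n, 0, 0.1)), 1)
    CEC <- exp(log(12) + cov_site(0.2) + rnorm(n, 0, 0.1))
    TOC <- exp(log(10) + cov_site(0.35) + rnorm(n, 0, 0.15))
    DOC <- exp(log(120) + cov_site(0.3) + rnorm(n, 0, 0.2))
    Fe2 <- exp(log(2.5) + cov_site(0.4) + rnorm(n, 0, 0.25))
    Fe3 <- exp(log(6) + cov_site(0.4) + rnorm(n, 0, 0.25))
    sulfide <- exp(log(0.15) + cov_site(0.5) + rnorm(n, 0, 0.3))
    MAT <- 10 + 1.4 * (site_idx - 1)
    MAP <- 600 + 130 * (site_idx - 1)

    env <- cbind(NO2 = NO2, NO3 = NO3, NH4 = NH4, pH = pH, MC = MC,
                 CEC = CEC, TOC = TOC, DOC = DOC, Fe2 = Fe2, Fe3 = Fe3,
                 sulfide = sulfide, MAT = MAT, MAP = MAP)
    rownames(env) <- sample_id
    metadata <- data.frame(
      sample_id = sample_id, site = grid$site, season = grid$season,
      latitude_group = ifelse(site_idx <= ceiling(cfg$n_sites / 2), "high", "low"),
      stringsAsFactors = FALSE)
    list(env = env, metadata = metadata,
         sin_axis = setNames(as.numeric(z), sample_id))
  })
}

#' Standardized SIN axis from observed concentrations
#'
#' First principal axis of the z-scored log SIN concentrations
#' (NO2, NO3, NH4), oriented to correlate positively with NH4. This is the
#' one-dimensional summary of inorganic-nitrogen state used as the filtering
#' gradient and as the SIN node of the path models.
#'
#' @param env Environment matrix containing NO2, NO3, NH4 columns.
#' @return Named numeric vector of per-sample scores (unit variance).
#' @export
sin_axis <- function(env) {
  need <- c("NO2", "NO3", "NH4")
  miss <- setdiff(need, colnames(env))
  if (length(miss)) stop("env lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  x <- scale(log(env[, need, drop = FALSE]))
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  s <- pc$x[, 1]
  if (cor(s, x[, "NH4"]) < 0) s <- -s
  s <- s / sd(s)
  setNames(as.numeric(s), rownames(env))
}

#' Simulate communities under filtering or neutral assembly
#'
#' Sampling weight of taxon *i* in sample *s*:
#' `base_i * exp(-(z_s - opt_i)^2 / (2 * sigma_niche^2))` under filtering,
#' `base_i` alone under neutral assembly; reads are a multinomial draw of
#' `sampling_depth` from the normalized weights, so row sums equal the depth
#' exactly. `mixed` mode assigns filtering to odd-numbered sites and neutral
#' to even-numbered ones.
#'
#' @param tree Tree (defines the taxa set and order).
#' @param optima Named niche optima from [simulate_niche_optima()];
#'   standardized internally to the SIN-axis scale.
#' @param env_axis Per-sample SIN-axis values (e.g. `simulate_env()$sin_axis`).
#' @param config A [scenario_config()].
#' @param metadata Sample metadata (needed for `mixed` mode site lookup).
#' @return Samples x taxa count matrix with attribute `base_abund`.
#' @export
simulate_communities <- function(tree, optima, env_axis, config, metadata = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  taxa <- tree$tip.label
  stopifnot(all(taxa %in% names(optima)))
  opt <- optima[taxa]
  opt_sd <- sd(opt)
  opt_std <- if (opt_sd > 0) (opt - mean(opt)) / opt_sd else rep(0, length(opt))

  mode_of <- function(sample_id) {
    if (config$assembly_mode != "mixed") return(rep(config$assembly_mode, length(sample_id)))
    if (is.null(metadata)) stop("mixed mode needs metadata for site lookup", call. = FALSE)
    site_idx <- match(metadata$site[match(sample_id, metadata$sample_id)],
                      site_labels(config$n_sites))
    ifelse(site_idx %% 2 == 1, "filtering", "neutral")
  }

  with_seed(derive_seed(config$seed, 3), {
    base <- rlnorm(length(taxa), meanlog = 0, sdlog = config$base_abund_sd)
    names(base) <- taxa
    modes <- mode_of(names(env_axis))
    comm <- matrix(0L, nrow = length(env_axis), ncol = length(taxa),
                   dimnames = list(names(env_axis), taxa))
    for (s in seq_along(env_axis)) {
      drift <- exp(rnorm(length(taxa), 0, config$abund_noise_sd))
      w <- if (modes[s] == "filtering") {
        base * drift * exp(-(env_axis[s] - opt_std)^2 / (2 * config$sigma_niche^2))
      } else base * drift
      if (sum(w) <= 0 || !any(w > 0))
        stop("all-zero sampling weights in sample ", names(env_axis)[s],
             "; increase sigma_niche", call. = FALSE)
      comm[s, ] <- rmultinom(1, size = config$sampling_depth, prob = w / sum(w))[, 1]
    }
    attr(comm, "base_abund") <- base
    comm
  })
}

#' Reference nitrogen-cycle gene set
#'
#' Marker genes with typical lengths (bp) and pathway assignments: nitrogen
#' fixation (nifD/H/K), nitrification (amoA/B/C, hao), denitrification
#' (nirK/S, norB/C, nosZ), nitrate reduction (narG, napA), DNRA (nrfA), and
#' anammox (hdh).
#'
#' @return data.frame(gene_id, length_bp, pathway).
#' @export
nitrogen_gene_map <- function() {
  data.frame(
    gene_id = c("nifD", "nifH", "nifK", "amoA", "amoB", "amoC", "hao",
                "nirK", "nirS", "norB", "norC", "nosZ", "narG", "napA",
                "nrfA", "hdh"),
    length_bp = c(1500, 900, 1550, 850, 1250, 830, 1710,
                  1140, 1700, 1390, 450, 1950, 3700, 2500,
                  1450, 1600),
    pathway = c(rep("nitrogen_fixation", 3), rep("nitrification", 4),
                rep("denitrification", 5), rep("nitrate_reduction", 2),
                "DNRA", "anammox"),
    stringsAsFactors = FALSE)
}

#' Simulate a nitrogen-cycle gene count table from communities
#'
#' Each taxon carries a gene-copy profile: a shared baseline per gene times
#' a taxon-specific lognormal deviation scaled by `1 - redundancy`, the
#' deviations evolving by Brownian motion on the tree so function weakly
#' tracks phylogeny. Sample read counts are Poisson around the
#' community-weighted copy intensity scaled to the sample's total mapped
#' reads. At `redundancy = 1` every taxon has the identical profile and
#' between-sample functional turnover collapses regardless of community
#' turnover.
#'
#' @param community Samples x taxa count matrix (positive row totals).
#' @param tree The phylogeny (for profile conservation).
#' @param config A [scenario_config()].
#' @param gene_map Gene set; defaults to [nitrogen_gene_map()].
#' @return List: `counts` (samples x genes), `gene_map`,
#'   `total_mapped_reads` (named per sample).
#' @export
simulate_gene_table <- function(community, tree, config, gene_map = nitrogen_gene_map()) {
  stopifnot(inherits(config, "scenario_config"))
  if (nrow(gene_map) == 0) stop("empty gene set", call. = FALSE)
  tot <- rowSums(community)
  if (any(tot <= 0)) stop("community has samples with zero total", call. = FALSE)
  taxa <- colnames(community)
  with_seed(derive_seed(config$seed, 4), {
    ngene <- nrow(gene_map)
    base_copy <- rlnorm(ngene, meanlog = log(1.5), sdlog = 0.4)
    dev_scale <- 1 - config$redundancy
    copy <- matrix(0, nrow = length(taxa), ncol = ngene,
                   dimnames = list(taxa, gene_map$gene_id))
    for (g in seq_len(ngene)) {
      u <- if (dev_scale > 0)
        ape::rTraitCont(tree, model = "BM", sigma = 1, root.value = 0)[taxa]
      else rep(0, length(taxa))
      copy[, g] <- base_copy[g] * exp(dev_scale * u)
    }
    relab <- community / tot
    intensity <- relab %*% copy                      # samples x genes
    len <- gene_map$length_bp
    totals <- round(rlnorm(nrow(community), meanlog = log(config$total_mapped_reads),
                           sdlog = 0.15))
    expected <- sweep(intensity, 2, len, "*")
    expected <- expected / rowSums(expected) * totals
    counts <- matrix(rpois(length(expected), lambda = expected),
                     nrow = nrow(expected), dimnames = dimnames(expected))
    list(counts = counts, gene_map = gene_map,
         total_mapped_reads = setNames(totals, rownames(community)))
  })
}

#' Run the full scenario generator
#'
#' @param config A [scenario_config()].
#' @return List: `tree`, `optima`, `env`, `metadata`, `sin_axis`,
#'   `community`, `genes`, `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  tree <- simulate_tree(config$n_taxa, config$birth %||% 1, config$death %||% 0,
                        seed = derive_seed(config$seed, 1))
  optima <- simulate_niche_optima(tree, config$sigma_bm,
                                  seed = derive_seed(config$seed, 5))
  e <- simulate_env(config)
  community <- simulate_communities(tree, optima, e$sin_axis, config,
                                    metadata = e$metadata)
  genes <- simulate_gene_table(community, tree, config)
  list(tree = tree, optima = optima, env = e$env, metadata = e$metadata,
       sin_axis = e$sin_axis, community = community, genes = genes,
       config = config)
}

#' Write a simulated scenario to disk
#'
#' Writes tree.nwk, community.tsv, samples.tsv, env.tsv, genes.tsv,
#' gene_map.tsv and scenario.json (provenance incl. the seed).
#'
#' @param sim Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_tsv_stable(sim$community, file.path(dir, "community.tsv"))
  write_tsv_stable(sim$metadata, file.path(dir, "samples.tsv"))
  write_tsv_stable(sim$env, file.path(dir, "env.tsv"))
  write_tsv_stable(sim$genes$counts, file.path(dir, "genes.tsv"))
  gm <- sim$genes$gene_map
  gm$total_template <- NULL
  write_tsv_stable(gm, file.path(dir, "gene_map.tsv"))
  totals <- data.frame(sample_id = names(sim$genes$total_mapped_reads),
                       total_mapped_reads = as.numeric(sim$genes$total_mapped_reads))
  write_tsv_stable(totals, file.path(dir, "mapped_reads.tsv"))
  cfg <- sim$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "")], file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate observed-variable data for the path models
#'
#' Linear-Gaussian system on standardized scales mirroring the mediation
#' structure of interest: temperature (MAT) drives SIN and soil covariates;
#' SIN drives phylogenetic diversity; diversity drives nitrogen function
#' with weight `mediation_strength`, while the direct SIN -> function path
#' is weak (0.1).
#'
#' @param n Sample size.
#' @param mediation_strength Diversity -> function coefficient (0 switches
#'   mediation off).
#' @param seed RNG seed.
#' @return data.frame with MAT, SIN, TOC, MC, Fe, PhyloDiv, Nfunc.
#' @export
simulate_path_data <- function(n = 500, mediation_strength = 0.6, seed = NULL) {
  with_seed(seed, {
    MAT <- rnorm(n)
    SIN <- 0.6 * MAT + rnorm(n, 0, sqrt(1 - 0.36))
    TOC <- 0.4 * MAT + rnorm(n, 0, sqrt(1 - 0.16))
    MC  <- 0.3 * MAT + rnorm(n, 0, sqrt(1 - 0.09))
    Fe  <- rnorm(n)
    PhyloDiv <- 0.7 * SIN + rnorm(n, 0, sqrt(1 - 0.49))
    res_sd <- sqrt(max(1 - mediation_strength^2 - 0.1^2, 0.05))
    Nfunc <- mediation_strength * PhyloDiv + 0.1 * SIN + rnorm(n, 0, res_sd)
    data.frame(MAT, SIN, TOC, MC, Fe, PhyloDiv, Nfunc)
  })
}
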
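#' Pipeline run configuration
#'
#' One master seed (the scenario's) derives every stage seed, so a config
#' pins the entire run.
#'
#' @param scenario A [scenario_config()] describing the synthetic study.
#' @param n_reps Null-model randomizations for NRI/NTI and betaNTI.
#' @param tau betaNTI classification threshold.
#' @param weighted Abundance weighting for the phylogenetic metrics.
#' @param top_k Dominant-OTU count per co-occurrence network.
#' @param rho_min,alpha Network edge rule (|Spearman rho| and BH q).
#' @param n_perm Mantel permutations.
#' @param n_trees Random-forest trees.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), n_reps = 999, tau = 2,
                       weighted = TRUE, top_k = 100, rho_min = 0.6,
                       alpha = 0.05, n_perm = 999, n_trees = 500) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full inference chain end to end
#'
#' simulate -> phylogenetic alpha SES -> betaNTI + assembly classification
#' -> seasonal co-occurrence networks -> RPKM/pathways/functional tests ->
#' association layer (ANOVA, Spearman, random forest, Mantel) -> path
#' models. Writes every stage's tables under `out_dir` plus a JSON run
#' report with seeds and headline numbers, and invisibly returns the full
#' result list for programmatic use.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (`NULL` to skip writing).
#' @return List with all stage results and the `report`.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$scenario$seed
  t0 <- proc.time()[3]

  sim <- simulate_scenario(config$scenario)
  season <- setNames(sim$metadata$season, sim$metadata$sample_id)
  axis <- sin_axis(sim$env)

  alpha <- ses_alpha(sim$community, sim$tree, n_reps = config$n_reps,
                     weighted = config$weighted,
                     seed = derive_seed(seed, 11))

  beta <- beta_nti(sim$community, sim$tree, n_reps = config$n_reps,
                   weighted = config$weighted, seed = derive_seed(seed, 12),
                   tau = config$tau)
  fits <- betanti_vs_env(beta, setNames(sim$env[, "NH4"], rownames(sim$env)),
                         groups = season)
  beta_mant <- betanti_mantel(beta, absdiff_dist(axis),
                              n_perm = config$n_perm,
                              seed = derive_seed(seed, 13))

  nets <- group_networks(sim$community, season, k = config$top_k,
                         rho_min = config$rho_min, alpha = config$alpha)

  gene_rpkm <- rpkm(sim$genes$counts,
                    setNames(sim$genes$gene_map$length_bp,
                             sim$genes$gene_map$gene_id),
                    sim$genes$total_mapped_reads)
  pathways <- aggregate_pathways(gene_rpkm, sim$genes$gene_map)
  fdiss <- functional_dissimilarity(gene_rpkm)
  gene_tests <- spatiotemporal_tests(gene_rpkm, season)
  fdiss_mant <- mantel_test(fdiss, absdiff_dist(axis),
                            n_perm = config$n_perm,
                            seed = derive_seed(seed, 14))

  sin_vars <- sim$env[, c("NO2", "NO3", "NH4")]
  anova_sin <- lapply(colnames(sin_vars), function(v)
    anova_oneway(sin_vars[, v], season[rownames(sin_vars)]))
  names(anova_sin) <- colnames(sin_vars)
  div_screen <- spearman_screen(
    cbind(NRI = alpha$nri, NTI = alpha$nti, MPD = alpha$mpd_obs,
          MNTD = alpha$mntd_obs), sin_vars)
  rf_nti <- rf_importance(sin_vars, alpha$nti, n_trees = config$n_trees,
                          seed = derive_seed(seed, 15))

  div_pc <- pca_reduce(cbind(NRI = alpha$nri, NTI = alpha$nti,
                             MPD = alpha$mpd_obs, MNTD = alpha$mntd_obs),
                       n_components = 1, orient_to = alpha$nti)
  fun_pc <- pca_reduce(pathways, n_components = 1)
  merged <- data.frame(
    MAT = sim$env[, "MAT"], SIN = axis,
    TOC = sim$env[, "TOC"], MC = sim$env[, "MC"],
    Fe = sim$env[, "Fe2"] + sim$env[, "Fe3"],
    PhyloDiv = div_pc$scores[, 1], Nfunc = fun_pc$scores[, 1],
    row.names = rownames(sim$env))
  fit_env <- fit_path_model(builtin_path_spec("env_only"), merged)
  fit_phy <- fit_path_model(builtin_path_spec("phylo_mediation"), merged)
  cmp <- compare_models(fit_env, fit_phy)

  report <- list(
    seed = seed, n_samples = nrow(sim$community),
    n_taxa = ncol(sim$community), n_reps = config$n_reps,
    mean_nti_by_season = tapply(alpha$nti, season[alpha$sample_id], mean),
    class_fractions = as.list(beta$class_fractions),
    deterministic_fraction = unname(deterministic_fraction(beta)["deterministic"]),
    betanti_mantel = list(r = beta_mant$r, p = beta_mant$p),
    functional_mantel = list(r = fdiss_mant$r, p = fdiss_mant$p),
    anova_sin_p = lapply(anova_sin, `[[`, "p"),
    topology = nets$topology,
    r2_ratio = cmp$r2_ratio,
    elapsed_s = unname(proc.time()[3] - t0))

  res <- list(sim = sim, alpha = alpha, beta = beta, beta_fits = fits,
              beta_mantel = beta_mant, networks = nets,
              rpkm = gene_rpkm, pathways = pathways, fdiss = fdiss,
              gene_tests = gene_tests, functional_mantel = fdiss_mant,
              anova_sin = anova_sin, diversity_screen = div_screen,
              rf_nti = rf_nti, merged = merged, fit_env_only = fit_env,
              fit_with_phylo = fit_phy, comparison = cmp, report = report,
              config = config)
  if (!is.null(out_dir)) write_run(res, out_dir)
  invisible(res)
}

# Write every stage table; TSV content is a pure function of the config.
write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scenario(res$sim, file.path(out_dir, "inputs"))
  write_tsv_stable(res$alpha, file.path(out_dir, "alpha_phylo.tsv"))
  write_tsv_stable(res$beta$bnti, file.path(out_dir, "betanti_matrix.tsv"))
  write_tsv_stable(res$beta$pairs, file.path(out_dir, "pair_classes.tsv"))
  write_tsv_stable(res$beta_fits, file.path(out_dir, "group_fits.tsv"))
  write_tsv_stable(res$networks$topology, file.path(out_dir, "topology.tsv"))
  for (g in names(res$networks$networks))
    write_tsv_stable(res$networks$networks[[g]]$edges,
                     file.path(out_dir, paste0("edges_", g, ".tsv")))
  write_tsv_stable(res$rpkm, file.path(out_dir, "rpkm.tsv"))
  write_tsv_stable(res$pathways, file.path(out_dir, "pathways.tsv"))
  write_tsv_stable(res$fdiss, file.path(out_dir, "fdiss.tsv"))
  write_tsv_stable(res$gene_tests, file.path(out_dir, "gene_tests.tsv"))
  write_tsv_stable(res$diversity_screen, file.path(out_dir, "associations.tsv"))
  write_tsv_stable(res$fit_env_only$edges,
                   file.path(out_dir, "path_env_only.tsv"))
  write_tsv_stable(res$fit_with_phylo$edges,
                   file.path(out_dir, "path_with_phylo.tsv"))
  write_tsv_stable(data.frame(rownames(res$merged), res$merged,
                              check.names = FALSE,
                              stringsAsFactors = FALSE) |>
                     setNames(c("sample_id", names(res$merged))),
                   file.path(out_dir, "merged.tsv"))
  jsonlite::write_json(res$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
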
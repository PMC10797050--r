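test_that("tree simulation is seeded, ultrametric, and well-formed", {
  t1 <- simulate_tree(8, seed = 1)
  t2 <- simulate_tree(8, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  t3 <- simulate_tree(3, seed = 2)
  expect_equal(length(t3$tip.label), 3L)
  expect_equal(t3$Nnode, 2L)
  depths <- ape::node.depth.edgelength(t1)[seq_len(8)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(simulate_tree(2, seed = 1))
  expect_error(simulate_tree(5, birth = 0.5, death = 0.6, seed = 1))
})

test_that("niche optima are Brownian with phylogenetic signal", {
  tr <- simulate_tree(6, seed = 3)
  o1 <- simulate_niche_optima(tr, sigma_bm = 1, seed = 4)
  o2 <- simulate_niche_optima(tr, sigma_bm = 1, seed = 4)
  expect_identical(o1, o2)
  expect_equal(unname(simulate_niche_optima(tr, sigma_bm = 0)),
               rep(0, 6))

  # sister-tip trait contrasts smaller than random-pair contrasts
  sister_sq <- random_sq <- numeric(0)
  for (rep in 1:50) {
    tr <- simulate_tree(20, seed = 100 + rep)
    o <- simulate_niche_optima(tr, sigma_bm = 1, seed = 200 + rep)
    d <- patristic_matrix(tr)
    for (i in seq_len(20)) {
      nn <- which.min(replace(d[i, ], i, Inf))
      sister_sq <- c(sister_sq, (o[i] - o[nn])^2)
    }
    pair <- sample(20, 2)
    random_sq <- c(random_sq, (o[pair[1]] - o[pair[2]])^2)
  }
  expect_lt(mean(sister_sq), mean(random_sq))
})

test_that("environment generator reproduces the seasonal SIN contrast", {
  cfg <- scenario_config(n_sites = 10, samples_per_site_season = 4, seed = 11)
  e <- simulate_env(cfg)
  expect_equal(nrow(e$env), 80L)
  expect_true(all(e$env[, c("NO2", "NO3", "NH4")] > 0))
  mar <- e$metadata$season == "March"
  expect_gt(mean(e$env[mar, "NH4"]), mean(e$env[!mar, "NH4"]))
  expect_gt(mean(e$env[mar, "NO2"]), mean(e$env[!mar, "NO2"]))
  expect_lt(mean(e$env[mar, "NO3"]), mean(e$env[!mar, "NO3"]))

  # null configuration: no seasonal effect leaves means equal within noise
  cfg0 <- scenario_config(season_effect = 0, seed = 12)
  e0 <- simulate_env(cfg0)
  mar0 <- e0$metadata$season == "March"
  tt <- t.test(log(e0$env[mar0, "NH4"]), log(e0$env[!mar0, "NH4"]))
  expect_gt(tt$p.value, 0.01)

  expect_identical(simulate_env(cfg)$env, e$env)  # seed determinism
})

test_that("community generator follows the stated filtering kernel", {
  cfg <- scenario_config(n_taxa = 50, n_sites = 2, samples_per_site_season = 2,
                         sigma_niche = 0.5, sampling_depth = 1000, seed = 21)
  tr <- simulate_tree(cfg$n_taxa, seed = 1)
  opt <- simulate_niche_optima(tr, 1, seed = 2)
  e <- simulate_env(cfg)
  comm <- simulate_communities(tr, opt, e$sin_axis, cfg, e$metadata)
  expect_true(all(rowSums(comm) == cfg$sampling_depth))

  # expected relative weights match the analytic kernel: far taxa < 1% of near
  base <- attr(comm, "base_abund")
  opt_std <- (opt - mean(opt)) / sd(opt)
  z <- e$sin_axis[1]
  w <- base * exp(-(z - opt_std)^2 / (2 * cfg$sigma_niche^2))
  far <- abs(opt_std - z) > 3 * cfg$sigma_niche
  near <- abs(opt_std - z) < cfg$sigma_niche
  if (any(far) && any(near)) {
    kern_far <- exp(-(z - opt_std[far])^2 / (2 * cfg$sigma_niche^2))
    expect_true(all(kern_far < 0.01 * max(exp(-(z - opt_std[near])^2 /
                                              (2 * cfg$sigma_niche^2)))))
  }

  # huge niche breadth reduces filtering to neutral weights
  cfg_wide <- scenario_config(n_taxa = 50, n_sites = 2, samples_per_site_season = 2,
                              sigma_niche = 1e6, seed = 21)
  w_wide <- base * exp(-(z - opt_std)^2 / (2 * cfg_wide$sigma_niche^2))
  tv <- 0.5 * sum(abs(w_wide / sum(w_wide) - base / sum(base)))
  expect_lt(tv, 1e-6)

  comm2 <- simulate_communities(tr, opt, e$sin_axis, cfg, e$metadata)
  expect_identical(comm, comm2)  # seed determinism
})

test_that("gene tables encode functional redundancy", {
  cfg <- scenario_config(n_taxa = 60, n_sites = 3, samples_per_site_season = 2,
                         redundancy = 1, seed = 31)
  sim <- simulate_scenario(cfg)
  g <- sim$genes
  r <- rpkm(g$counts, setNames(g$gene_map$length_bp, g$gene_map$gene_id),
            g$total_mapped_reads)
  bc <- functional_dissimilarity(r)
  expect_lt(max(bc[upper.tri(bc)]), 0.05)

  g2 <- simulate_gene_table(sim$community, sim$tree, cfg)
  expect_identical(g$counts, g2$counts)  # seed determinism
  expect_error(simulate_gene_table(sim$community, sim$tree, cfg,
                                   gene_map = nitrogen_gene_map()[0, ]),
               "empty gene set")
})
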
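test_that("betaMNTD matches hand values and the double-loop oracle", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  d <- patristic_matrix(tr)
  a <- c(A = 1, B = 0, C = 0); b <- c(A = 0, B = 0, C = 1)
  expect_equal(beta_mntd(a, b, d), 4)
  same <- c(A = 2, B = 1, C = 3)
  expect_equal(beta_mntd(same, same, d), 0)
  expect_error(beta_mntd(a, c(A = 0, B = 0, C = 0), d), "empty")

  for (seed in 1:8) {
    tr <- random_tree(6, seed + 30)
    d <- patristic_matrix(tr)
    comm <- random_community(2, tr$tip.label, seed + 60, depth = 30)
    for (w in c(TRUE, FALSE))
      expect_equal(beta_mntd(comm[1, ], comm[2, ], d, w),
                   oracle_beta_mntd(comm[1, ], comm[2, ], d, w),
                   tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante comdistnt", {
  skip_if_not_installed("picante")
  tr <- random_tree(20, 91)
  d <- patristic_matrix(tr)
  comm <- random_community(6, tr$tip.label, 92)
  ours <- cpp_beta_mntd(comm, d[colnames(comm), colnames(comm)], TRUE)
  ref <- as.matrix(picante::comdistnt(comm, d, abundance.weighted = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("betaNTI is symmetric, classified, and tau-monotone", {
  tr <- random_tree(25, 3)
  comm <- random_community(8, tr$tip.label, 4)
  res <- beta_nti(comm, patristic_matrix(tr), n_reps = 199, seed = 5)
  expect_equal(res$bnti, t(res$bnti))
  expect_equal(diag(res$bnti), setNames(rep(0, 8), rownames(comm)))
  expect_equal(sum(res$class_fractions), 1)

  expect_equal(classify_bnti(c(2.5, -2.5, 0.5)),
               c("deterministic_heterogeneous", "deterministic_homogeneous",
                 "stochastic"))

  taus <- c(0.5, 1, 2, 3)
  det <- sapply(taus, function(t) deterministic_fraction(res, t)["deterministic"])
  expect_true(all(diff(det) <= 0))

  res2 <- beta_nti(comm, patristic_matrix(tr), n_reps = 199, seed = 5)
  expect_identical(res2$bnti, res$bnti)  # seeded shuffle sequence
})

test_that("identical communities give zero turnover and a degenerate null", {
  # a taxa-label shuffle relabels both communities identically, so a pair of
  # identical samples has betaMNTD 0 under every randomization: the null is
  # degenerate and the pair is flagged rather than classified as selection
  tr <- random_tree(30, 6)
  row <- random_community(1, tr$tip.label, 7)[1, ]
  comm <- rbind(s1 = row, s2 = row, s3 = row)
  res <- beta_nti(comm, patristic_matrix(tr), n_reps = 199, seed = 8)
  expect_true(all(res$pairs$bmntd_obs == 0))
  expect_true(all(res$pairs$degenerate))
  expect_true(all(res$pairs$bnti == 0))
})

test_that("communities confined to one tight clade classify as homogeneous", {
  # homogeneous selection: samples draw different members of the same tight
  # clade, so observed turnover is far below what random tip sets produce
  clade <- paste0("a", 1:10, ":0.1", collapse = ",")
  rest <- paste0("b", 1:30, ":5", collapse = ",")
  tr <- read_newick(text = sprintf("((%s):5,%s);", clade, rest))
  d <- patristic_matrix(tr)
  set.seed(17)
  comm <- t(vapply(1:4, function(i) {
    v <- setNames(integer(40), tr$tip.label)
    v[sample(paste0("a", 1:10), 5)] <- rpois(5, 40) + 1L
    v
  }, integer(40)))
  rownames(comm) <- paste0("s", 1:4)
  res <- beta_nti(comm, d, n_reps = 199, seed = 18)
  expect_true(all(res$pairs$bnti < 0))
  expect_true(all(res$pairs$class == "deterministic_homogeneous"))
})

test_that("betaNTI regression on environmental differences recovers slopes", {
  # synthetic pair structure: bnti = 2 |dNH4| + noise
  set.seed(11)
  n <- 15
  ids <- sprintf("s%02d", 1:n)
  env <- setNames(runif(n, 0, 3), ids)
  bnti <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- 2 * abs(env[i] - env[j]) + rnorm(1, 0, 0.1)
    bnti[i, j] <- v; bnti[j, i] <- v
  }
  fake <- structure(list(bnti = bnti,
                         pairs = data.frame(
                           sample_i = ids[row(bnti)[upper.tri(bnti)]],
                           sample_j = ids[col(bnti)[upper.tri(bnti)]],
                           bnti = bnti[upper.tri(bnti)])),
                    class = "beta_nti_result")
  fit <- betanti_vs_env(fake, env)
  expect_gt(fit$slope[fit$group == "pooled"], 1.9)
  expect_lt(fit$slope[fit$group == "pooled"], 2.1)
  expect_lt(fit$p[fit$group == "pooled"], 1e-6)

  # constant betaNTI: slope and R2 are 0
  fake$pairs$bnti <- rep(1, nrow(fake$pairs))
  fit0 <- betanti_vs_env(fake, env)
  expect_equal(fit0$r2, 0)

  # groups with < 3 pairs are skipped
  grp <- setNames(c("a", "a", rep("b", n - 2)), ids)
  expect_message(betanti_vs_env(fake, env, groups = grp), "skipping")
})

test_that("betaNTI Mantel layer detects self-correlation exactly", {
  set.seed(12)
  ids <- sprintf("s%d", 1:10)
  m <- matrix(runif(100), 10, dimnames = list(ids, ids))
  m <- (m + t(m)) / 2; diag(m) <- 0
  r <- betanti_mantel(structure(list(bnti = m), class = "beta_nti_result"),
                      m, n_perm = 199, seed = 1)
  expect_equal(r$r, 1)
  expect_equal(r$p, 1 / 200)
})
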
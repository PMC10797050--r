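test_that("PCA reduction handles rank-1 data and orients PC1 deterministically", {
  x <- rnorm(20)
  tab <- cbind(a = x, b = 2 * x, c = -x)
  out <- pca_reduce(tab, n_components = 1)
  expect_equal(out$variance_explained[1], 1, tolerance = 1e-12)

  # orientation: scores identical whether or not loadings are negated upstream
  set.seed(91)
  tab2 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  o1 <- pca_reduce(tab2, 1)
  o2 <- pca_reduce(-tab2, 1, orient_to = rowSums(tab2))
  expect_equal(o1$scores[, 1], o2$scores[, 1], tolerance = 1e-9)
  expect_gt(cor(o1$scores[, 1], rowSums(tab2)), 0)

  # zero-variance columns are dropped with a message
  expect_message(pca_reduce(cbind(tab2, flat = 1), 1), "flat")

  # isotropic data spreads variance roughly evenly
  set.seed(92)
  iso <- matrix(rnorm(2000 * 4), 2000, 4, dimnames = list(NULL, letters[1:4]))
  ve <- pca_reduce(iso)$variance_explained
  expect_true(all(abs(ve - 0.25) < 0.05))
})

test_that("path spec parsing accepts edges, rejects cycles and junk", {
  spec <- parse_path_spec(c("# comment", "A -> B", "B -> C", ""))
  expect_equal(nrow(spec), 2L)
  expect_error(parse_path_spec(c("A -> B", "B -> A")), "cycle")
  expect_error(parse_path_spec("A => B"), "malformed")
  for (nm in c("env_only", "phylo_mediation"))
    expect_s3_class(builtin_path_spec(nm), "path_spec")
})

test_that("single-edge coefficient equals the Pearson correlation", {
  set.seed(93)
  d <- data.frame(x = rnorm(100))
  d$y <- 0.5 * d$x + rnorm(100)
  fit <- fit_path_model(parse_path_spec("x -> y"), d)
  expect_equal(fit$edges$coefficient, cor(d$x, d$y), tolerance = 1e-9)
  expect_equal(unname(fit$r2["y"]), cor(d$x, d$y)^2, tolerance = 1e-9)
})

test_that("standardized coefficients are recovered from linear data", {
  set.seed(94)
  n <- 500
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.64))
  fit <- fit_path_model(parse_path_spec("x -> y"), data.frame(x, y))
  expect_gt(fit$edges$coefficient, 0.7)
  expect_lt(fit$edges$coefficient, 0.9)

  # chain mediation: indirect effect approximately 0.7 * 0.6
  m <- 0.7 * x + rnorm(n, 0, sqrt(1 - 0.49))
  z <- 0.6 * m + rnorm(n, 0, sqrt(1 - 0.36))
  cf <- fit_path_model(parse_path_spec(c("x -> m", "m -> z")),
                       data.frame(x, m, z))
  expect_lt(abs(indirect_effect(cf, c("x", "m", "z")) - 0.42), 0.1)

  # an edge between independent variables stays small and non-significant
  hits <- 0
  for (rep in 1:10) {
    set.seed(500 + rep)
    a <- rnorm(500); b <- rnorm(500)
    f <- fit_path_model(parse_path_spec("a -> b"), data.frame(a, b))
    if (abs(f$edges$coefficient) < 0.1 && f$edges$p > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("recursive OLS agrees with ML covariance fitting on a DAG", {
  # ML for a recursive observed-variable DAG: minimize the multivariate
  # normal discrepancy over path coefficients + residual variances; here
  # checked numerically against the sequential-OLS solution.
  set.seed(95)
  n <- 400
  x <- rnorm(n); m <- 0.6 * x + rnorm(n, 0, 0.8); y <- 0.5 * m - 0.3 * x + rnorm(n)
  d <- as.data.frame(scale(data.frame(x, m, y)))
  fit <- fit_path_model(parse_path_spec(c("x -> m", "x -> y", "m -> y")), d)
  S <- cov(d)
  nll <- function(th) {
    b_xm <- th[1]; b_xy <- th[2]; b_my <- th[3]
    v_m <- exp(th[4]); v_y <- exp(th[5]); v_x <- exp(th[6])
    # implied covariance of (x, m, y)
    B <- matrix(c(0, 0, 0, b_xm, 0, 0, b_xy, b_my, 0), 3, 3, byrow = TRUE)
    Iinv <- solve(diag(3) - B)
    Psi <- diag(c(v_x, v_m, v_y))
    Sigma <- Iinv %*% Psi %*% t(Iinv)
    log(det(Sigma)) + sum(diag(solve(Sigma) %*% S))
  }
  opt <- optim(c(0, 0, 0, 0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  ours <- fit$edges$coefficient[match(c("x m", "x y", "m y"),
                                      paste(fit$edges$from, fit$edges$to))]
  expect_equal(ours, opt$par[1:3], tolerance = 1e-4)
})

test_that("model comparison reports the R2 ratio and mediation contrast", {
  set.seed(96)
  d <- simulate_path_data(500, mediation_strength = 0.6, seed = 97)
  fit_env <- fit_path_model(builtin_path_spec("env_only"), d)
  fit_phy <- fit_path_model(builtin_path_spec("phylo_mediation"), d)
  cmp <- compare_models(fit_env, fit_phy)
  expect_gt(cmp$r2_ratio, 1)
  dp <- fit_phy$edges[fit_phy$edges$from == "PhyloDiv", ]
  expect_lt(dp$p, 0.05)

  # identical models give ratio exactly 1
  cmp0 <- compare_models(fit_env, fit_env)
  expect_equal(cmp0$r2_ratio, 1)

  # env-independent function: env-only model explains nearly nothing
  d0 <- simulate_path_data(500, mediation_strength = 0, seed = 98)
  d0$Nfunc <- rnorm(500)
  f0 <- fit_path_model(builtin_path_spec("env_only"), d0)
  expect_lt(unname(f0$r2["Nfunc"]), 0.05)
})

test_that("mediation strength switches the diversity path on and off", {
  on_hits <- off_hits <- 0
  for (rep in 1:10) {
    d_on <- simulate_path_data(300, 0.6, seed = 600 + rep)
    d_off <- simulate_path_data(300, 0, seed = 700 + rep)
    f_on <- fit_path_model(builtin_path_spec("phylo_mediation"), d_on)
    f_off <- fit_path_model(builtin_path_spec("phylo_mediation"), d_off)
    p_on <- f_on$edges$p[f_on$edges$from == "PhyloDiv"]
    p_off <- f_off$edges$p[f_off$edges$from == "PhyloDiv"]
    if (p_on <= 0.05) on_hits <- on_hits + 1
    if (p_off > 0.05) off_hits <- off_hits + 1
  }
  expect_gte(on_hits, 9)
  expect_gte(off_hits, 9)
})
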
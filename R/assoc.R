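#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) of the off-diagonal entries, with a
#' one-tailed permutation p-value under simultaneous row/column permutation
#' of the second matrix: `p = (1 + #{perm r >= obs r}) / (n_perm + 1)`.
#' Delegates the permutation machinery to [vegan::mantel()].
#'
#' @param d1,d2 Symmetric distance matrices (or `dist`) over the same
#'   labelled samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Permutations (>= 99; default 999).
#' @param seed RNG seed.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `method`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_perm >= 99)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    miss <- setdiff(rownames(d1), rownames(d2))
    if (length(miss)) stop("labels missing from second matrix: ",
                           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  stopifnot(nrow(d1) == nrow(d2))
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  fit <- with_seed(seed,
    vegan::mantel(stats::as.dist(d1), stats::as.dist(d2), method = method,
                  permutations = n_perm))
  structure(list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm,
                 method = method, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f (%s), p = %.4g (%d permutations)\n",
              x$r, x$method, x$p, x$n_perm))
  invisible(x)
}

#' Spearman screen of features against variables
#'
#' All feature-by-variable rank correlations with raw p and BH q within the
#' screen. Zero-variance columns yield NA sentinel rows.
#'
#' @param X Samples x features matrix.
#' @param Y Samples x variables matrix (same sample order).
#' @return data.frame of class `association_table`: feature, covariate,
#'   rho, p, q.
#' @export
spearman_screen <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 4)
  rows <- list()
  for (f in colnames(X)) for (v in colnames(Y)) {
    if (var(X[, f]) == 0 || var(Y[, v]) == 0) {
      rows[[paste(f, v)]] <- data.frame(feature = f, covariate = v,
                                        rho = NA_real_, p = NA_real_,
                                        stringsAsFactors = FALSE)
      next
    }
    ct <- suppressWarnings(cor.test(X[, f], Y[, v], method = "spearman",
                                    exact = FALSE))
    rows[[paste(f, v)]] <- data.frame(feature = f, covariate = v,
                                      rho = unname(ct$estimate), p = ct$p.value,
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  class(out) <- c("association_table", class(out))
  out
}

#' One-way analysis of variance
#'
#' Classical one-way F test, used for the seasonal and latitudinal SIN
#' contrasts.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @return List: `F`, `p`, `df`, `group_means`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (all(tapply(values, groups, var) == 0))
    stop("zero within-group variance everywhere: F degenerate", call. = FALSE)
  fit <- aov(values ~ groups)
  tab <- summary(fit)[[1]]
  gm <- tapply(values, groups, mean)
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"],
       df = c(tab[1, "Df"], tab[2, "Df"]),
       group_means = setNames(as.numeric(gm), names(gm)))
}

#' Random-forest importance of predictors (MSE% units)
#'
#' Regression random forest ([randomForest::randomForest()], 500 trees,
#' `mtry = ceiling(p/3)`); importance is the permutation increase in
#' out-of-bag MSE expressed as a percentage of the forest's baseline OOB
#' MSE, the "MSE%" reporting unit.
#'
#' @param X Samples x predictors matrix/data.frame (n >= 20).
#' @param y Numeric response.
#' @param n_trees Trees (default 500).
#' @param seed RNG seed.
#' @return Named numeric vector of MSE% importances.
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = NULL) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) >= 20, length(y) == nrow(X))
  if (var(y) == 0) stop("constant response", call. = FALSE)
  fit <- with_seed(seed,
    randomForest::randomForest(x = X, y = y, ntree = n_trees,
                               mtry = max(1, ceiling(ncol(X) / 3)),
                               importance = TRUE))
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  baseline <- fit$mse[length(fit$mse)]
  100 * raw / baseline
}

#' Per-taxon multivariate linear models of abundance on SIN covariates
#'
#' MaAsLin-style screen: taxa (optionally aggregated to a clade rank via
#' `clade_map`) are converted to relative abundance, arcsine-square-root
#' transformed, and fit by ordinary linear models on the named covariates
#' (plus `season` as a fixed covariate when present in `env`). q-values are
#' BH-adjusted across all taxon-by-covariate coefficients; the conventional
#' significance call is `q <= q_threshold` (default 0.25).
#'
#' @param community Samples x taxa abundance matrix.
#' @param env data.frame/matrix of covariates (rows = samples).
#' @param covariates Covariate column names in `env`.
#' @param clade_map Optional named vector taxon -> clade for aggregation.
#' @param q_threshold Significance threshold on q.
#' @return data.frame of class `association_table`: feature, covariate,
#'   coefficient, p, q, significant. All-zero taxa are skipped with a
#'   message.
#' @export
taxa_linear_models <- function(community, env, covariates,
                               clade_map = NULL, q_threshold = 0.25) {
  stopifnot(nrow(community) >= 10)
  env <- as.data.frame(env)
  if (!is.null(clade_map)) {
    clade <- clade_map[colnames(community)]
    community <- t(rowsum(t(community), clade))
  }
  rel <- relative_abundance(community)
  y_all <- asin(sqrt(pmin(rel, 1)))
  has_season <- "season" %in% names(env)
  rhs <- paste(c(covariates, if (has_season) "season"), collapse = " + ")
  rows <- list()
  for (taxon in colnames(y_all)) {
    if (all(community[, taxon] == 0)) {
      message("skipping all-zero taxon ", taxon)
      next
    }
    dat <- data.frame(.y = y_all[, taxon], env[rownames(community), , drop = FALSE])
    fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    for (cv in covariates) {
      if (!cv %in% rownames(sm)) next
      rows[[paste(taxon, cv)]] <- data.frame(
        feature = taxon, covariate = cv, coefficient = sm[cv, 1],
        p = sm[cv, 4], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_threshold
  class(out) <- c("association_table", class(out))
  out
}
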
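#' Between-community mean nearest-taxon distance
#'
#' For each taxon in one community, the minimum patristic distance to any
#' taxon in the other community (a taxon shared by both contributes 0);
#' means (abundance-weighted if set) are taken within each direction and
#' averaged over both.
#'
#' @param abund_a,abund_b Named abundance vectors over the same taxa set.
#' @param dist Patristic distance matrix.
#' @param weighted Abundance weighting.
#' @return betaMNTD value.
#' @export
beta_mntd <- function(abund_a, abund_b, dist, weighted = TRUE) {
  if (!any(abund_a > 0) || !any(abund_b > 0))
    stop("empty sample in beta_mntd", call. = FALSE)
  taxa <- names(abund_a)
  stopifnot(identical(taxa, names(abund_b)))
  comm <- rbind(a = abund_a, b = abund_b)
  cpp_beta_mntd(comm, dist[taxa, taxa], weighted)[1, 2]
}

#' Pairwise betaNTI with deterministic/stochastic classification
#'
#' For every sample pair, betaMNTD is compared with its null distribution
#' under taxa-label randomization (the same seeded shuffle sequence reused
#' across pairs, so the matrix is exactly symmetric):
#' `betaNTI = (obs - null_mean) / null_sd`. Pairs with `betaNTI > tau` are
#' classed deterministic (heterogeneous selection), `< -tau` deterministic
#' (homogeneous selection), otherwise stochastic. Degenerate nulls
#' (`null_sd < 1e-12`) get betaNTI 0 and a flag.
#'
#' @param community Samples x taxa abundance matrix.
#' @param tree_or_dist Tree or patristic distance matrix.
#' @param n_reps Null randomizations (>= 99; default 999).
#' @param weighted Abundance weighting (default TRUE).
#' @param seed RNG seed.
#' @param tau Classification threshold (default 2).
#' @return List of class `beta_nti_result`: matrices `bmntd_obs`,
#'   `null_mean`, `null_sd`, `bnti`; `pairs` data.frame (sample_i,
#'   sample_j, bmntd_obs, bnti, class, degenerate); `class_fractions`;
#'   parameters.
#' @export
beta_nti <- function(community, tree_or_dist, n_reps = 999, weighted = TRUE,
                     seed = NULL, tau = 2) {
  stopifnot(n_reps >= 99)
  if (any(rowSums(community > 0) < 1)) stop("empty sample", call. = FALSE)
  rd <- resolve_dist(community, tree_or_dist)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(i) sample.int(ncol(rd$dist)) - 1L,
             integer(ncol(rd$dist))))
  })
  res <- cpp_beta_nti(rd$community, rd$dist, perms, weighted)
  ids <- rownames(rd$community)
  dimnames(res$obs) <- dimnames(res$null_mean) <- dimnames(res$null_sd) <-
    list(ids, ids)
  degen <- res$null_sd < 1e-12
  bnti <- ifelse(degen, 0, (res$obs - res$null_mean) / res$null_sd)
  diag(bnti) <- 0
  ut <- which(upper.tri(bnti), arr.ind = TRUE)
  pairs <- data.frame(
    sample_i = ids[ut[, 1]], sample_j = ids[ut[, 2]],
    bmntd_obs = res$obs[ut], null_mean = res$null_mean[ut],
    null_sd = res$null_sd[ut], bnti = bnti[ut],
    degenerate = degen[ut] & !(diag(TRUE, nrow(bnti))[ut]),
    stringsAsFactors = FALSE)
  pairs$class <- classify_bnti(pairs$bnti, tau)
  frac <- prop.table(table(factor(pairs$class, levels = bnti_classes())))
  structure(list(bmntd_obs = res$obs, null_mean = res$null_mean,
                 null_sd = res$null_sd, bnti = bnti, pairs = pairs,
                 class_fractions = frac, tau = tau, n_reps = n_reps,
                 weighted = weighted, seed = seed),
            class = "beta_nti_result")
}

bnti_classes <- function() {
  c("deterministic_heterogeneous", "deterministic_homogeneous", "stochastic")
}

#' Classify betaNTI values
#'
#' @param bnti Numeric betaNTI values.
#' @param tau Threshold (default 2).
#' @return Character vector over
#'   deterministic_heterogeneous (`bnti > tau`),
#'   deterministic_homogeneous (`bnti < -tau`), stochastic otherwise.
#' @export
classify_bnti <- function(bnti, tau = 2) {
  ifelse(bnti > tau, "deterministic_heterogeneous",
         ifelse(bnti < -tau, "deterministic_homogeneous", "stochastic"))
}

#' Fraction of sample pairs classed deterministic
#' @param x A `beta_nti_result` or numeric betaNTI vector.
#' @param tau Threshold (default: the result's own).
#' @return Named vector: heterogeneous, homogeneous, deterministic (pooled),
#'   stochastic.
#' @export
deterministic_fraction <- function(x, tau = NULL) {
  b <- if (inherits(x, "beta_nti_result")) x$pairs$bnti else x
  tau <- tau %||% if (inherits(x, "beta_nti_result")) x$tau else 2
  het <- mean(b > tau); hom <- mean(b < -tau)
  c(heterogeneous = het, homogeneous = hom, deterministic = het + hom,
    stochastic = 1 - het - hom)
}

#' Linear fit of betaNTI on pairwise environmental differences
#'
#' Pair-level predictor is `|env_i - env_j|` (default) or the pair mean;
#' ordinary least squares per group (pairs whose two samples share the
#' group label) and pooled.
#'
#' @param result A `beta_nti_result`.
#' @param env_values Named per-sample environmental values.
#' @param groups Optional named per-sample group labels.
#' @param mode `"absdiff"` or `"mean"` pair mapping.
#' @return data.frame per group (+ `"pooled"`): slope, r2, p, n_pairs.
#'   Groups with fewer than 3 pairs are skipped with a message.
#' @export
betanti_vs_env <- function(result, env_values, groups = NULL,
                           mode = c("absdiff", "mean")) {
  mode <- match.arg(mode)
  p <- result$pairs
  ei <- env_values[p$sample_i]; ej <- env_values[p$sample_j]
  pred <- if (mode == "absdiff") abs(ei - ej) else (ei + ej) / 2
  fit_one <- function(keep, label) {
    if (sum(keep) < 3) { message("skipping group ", label, ": < 3 pairs"); return(NULL) }
    if (var(p$bnti[keep]) == 0)
      return(data.frame(group = label, slope = 0, r2 = 0, p = NA_real_,
                        n_pairs = sum(keep), stringsAsFactors = FALSE))
    fm <- lm(p$bnti[keep] ~ pred[keep])
    sm <- summary(fm)
    pv <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
    sl <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 1] else 0
    data.frame(group = label, slope = sl, r2 = sm$r.squared, p = pv,
               n_pairs = sum(keep), stringsAsFactors = FALSE)
  }
  out <- list(fit_one(rep(TRUE, nrow(p)), "pooled"))
  if (!is.null(groups)) {
    gi <- groups[p$sample_i]; gj <- groups[p$sample_j]
    for (g in unique(na.omit(groups)))
      out <- c(out, list(fit_one(gi == g & gj == g, g)))
  }
  do.call(rbind, out)
}

#' Mantel test of the betaNTI matrix against an environmental distance
#'
#' @param result A `beta_nti_result` (or a symmetric matrix).
#' @param env_dist Environmental distance matrix (e.g. `|Δ SIN|`) over the
#'   same samples.
#' @param ... Passed to [mantel_test()].
#' @return A `mantel_result`.
#' @export
betanti_mantel <- function(result, env_dist, ...) {
  b <- if (inherits(x = result, "beta_nti_result")) result$bnti else result
  mantel_test(b, env_dist, ...)
}

#' Pairwise absolute-difference distance from a per-sample variable
#' @param values Named numeric vector.
#' @return Symmetric matrix `|v_i - v_j|`.
#' @export
absdiff_dist <- function(values) {
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  m
}

#' @export
print.beta_nti_result <- function(x, ...) {
  cat("betaNTI over", nrow(x$bnti), "samples (", nrow(x$pairs), "pairs ),",
      x$n_reps, "null reps, tau =", x$tau, "\n")
  print(round(x$class_fractions, 3))
  invisible(x)
}
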
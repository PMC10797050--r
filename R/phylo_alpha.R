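#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips, in tree
#' tip order.
#'
#' @param tree An `ape::phylo` tree.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree)
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

# Coerce tree-or-matrix to a distance matrix aligned to community columns.
resolve_dist <- function(community, tree_or_dist, prune_missing = FALSE) {
  if (inherits(tree_or_dist, "phylo")) {
    community <- match_community_tree(community, tree_or_dist, prune_missing)
    d <- patristic_matrix(tree_or_dist)
  } else d <- tree_or_dist
  miss <- setdiff(colnames(community), rownames(d))
  if (length(miss)) stop("taxa missing from distance matrix: ",
                         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  list(community = community, dist = d[colnames(community), colnames(community)])
}

#' Mean pairwise phylogenetic distance of one sample
#'
#' Unweighted: mean of d(i, j) over distinct present-taxon pairs. Weighted:
#' `sum_{i != j} w_i w_j d(i, j) / sum_{i != j} w_i w_j` with `w` relative
#' abundances.
#'
#' @param abund Named abundance vector (taxa in `dist` rownames).
#' @param dist Patristic distance matrix.
#' @param weighted Abundance weighting.
#' @return MPD, or `NA` (sentinel) for fewer than two present taxa.
#' @export
mpd_single <- function(abund, dist, weighted = TRUE) {
  alpha_single(abund, dist, weighted)["mpd"]
}

#' Mean nearest-taxon distance of one sample
#'
#' Mean (abundance-weighted if set) over present taxa of the minimum
#' distance to another present taxon.
#'
#' @inheritParams mpd_single
#' @return MNTD, or `NA` for fewer than two present taxa.
#' @export
mntd_single <- function(abund, dist, weighted = TRUE) {
  alpha_single(abund, dist, weighted)["mntd"]
}

alpha_single <- function(abund, dist, weighted = TRUE) {
  comm <- matrix(abund, nrow = 1, dimnames = list("s", names(abund)))
  d <- dist[names(abund), names(abund)]
  res <- cpp_ses_alpha(comm, d, matrix(integer(0), 0, length(abund)), weighted)
  c(mpd = res$mpd_obs[1], mntd = res$mntd_obs[1])
}

#' Phylogenetic alpha diversity with null-model standardized effect sizes
#'
#' Computes observed MPD and MNTD per sample and their null distributions
#' under taxa-label randomization (tip labels shuffled across the patristic
#' distance matrix, pool = all tips), then the net relatedness index
#' NRI = -(MPD_obs - null_mean) / null_sd and the nearest taxon index
#' NTI = -(MNTD_obs - null_mean) / null_sd. Positive values indicate
#' phylogenetic clustering. When a null SD collapses below `1e-12`
#' (e.g. every sample holds the whole species pool) the index is defined
#' as 0.
#'
#' @param community Samples x taxa abundance matrix.
#' @param tree_or_dist Tree or precomputed patristic distance matrix.
#' @param n_reps Null randomizations (>= 99; default 999).
#' @param weighted Abundance weighting (default TRUE).
#' @param seed RNG seed for the shuffle sequence.
#' @return data.frame per sample: `mpd_obs`, `mntd_obs`, null means/SDs,
#'   `nri`, `nti`, `n_taxa`; attributes record `n_reps`, `weighted`, `seed`
#'   and the sign convention. Samples with < 2 present taxa get NA rows.
#' @export
ses_alpha <- function(community, tree_or_dist, n_reps = 999, weighted = TRUE,
                      seed = NULL) {
  stopifnot(n_reps >= 99)
  rd <- resolve_dist(community, tree_or_dist)
  perms <- with_seed(seed, {
    t(vapply(seq_len(n_reps), function(i) sample.int(ncol(rd$dist)) - 1L,
             integer(ncol(rd$dist))))
  })
  res <- cpp_ses_alpha(rd$community, rd$dist, perms, weighted)
  ses <- function(obs, m, s) ifelse(is.na(s) | s < 1e-12, 0, -(obs - m) / s)
  out <- data.frame(
    sample_id = rownames(rd$community),
    n_taxa = rowSums(rd$community > 0),
    mpd_obs = res$mpd_obs, mpd_null_mean = res$mpd_null_mean,
    mpd_null_sd = res$mpd_null_sd,
    mntd_obs = res$mntd_obs, mntd_null_mean = res$mntd_null_mean,
    mntd_null_sd = res$mntd_null_sd,
    stringsAsFactors = FALSE)
  out$nri <- ifelse(is.na(out$mpd_obs), NA,
                    ses(out$mpd_obs, out$mpd_null_mean, out$mpd_null_sd))
  out$nti <- ifelse(is.na(out$mntd_obs), NA,
                    ses(out$mntd_obs, out$mntd_null_mean, out$mntd_null_sd))
  structure(out, n_reps = n_reps, weighted = weighted, seed = seed,
            sign_convention = "positive = phylogenetic clustering (negated SES)")
}
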
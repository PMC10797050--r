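#' Per-sample relative abundances
#' @param community Samples x taxa matrix with positive row totals.
#' @return Matrix of row-normalized abundances.
#' @export
relative_abundance <- function(community) {
  tot <- rowSums(community)
  if (any(tot <= 0)) stop("samples with zero total", call. = FALSE)
  community / tot
}

#' Select the most abundant OTUs
#'
#' Ranks OTUs by mean relative abundance across the given samples and keeps
#' the top `k` (default 100, the dominant-taxa convention for co-occurrence
#' networks). Ties at the cutoff break lexicographically by OTU id. If `k`
#' exceeds richness all OTUs are kept with a warning.
#'
#' @param community Samples x taxa matrix.
#' @param k Number of OTUs to keep (>= 2).
#' @return Reduced community matrix (columns in rank order).
#' @export
select_top_otus <- function(community, k = 100) {
  stopifnot(k >= 2)
  if (nrow(community) == 0) stop("empty sample group", call. = FALSE)
  rel <- relative_abundance(community)
  mean_rel <- colMeans(rel)
  ord <- order(-mean_rel, colnames(community))
  if (k > length(ord)) {
    warning("k = ", k, " exceeds richness ", length(ord), "; keeping all")
    k <- length(ord)
  }
  community[, ord[seq_len(k)], drop = FALSE]
}

#' Build a co-occurrence network over dominant OTUs
#'
#' Pairwise Spearman correlations of relative abundances across samples; an
#' edge is drawn iff `|rho| >= rho_min` and the Benjamini-Hochberg q-value
#' over all pairs is `<= alpha` (defaults 0.6 / 0.05, the usual convention
#' in microbial co-occurrence work — recorded in the result's provenance).
#' Constant OTUs have undefined correlations: the node is kept, its edges
#' skipped and counted.
#'
#' @param community Samples x OTUs matrix (>= 3 samples).
#' @param corr_method `"spearman"` (default) or `"pearson"`.
#' @param rho_min Minimum absolute correlation.
#' @param alpha FDR threshold.
#' @param adjust p-adjustment method (default `"BH"`).
#' @return List of class `co_network`: `graph` (igraph), `edges`
#'   data.frame (node1, node2, rho, p, q), `nodes`, `params`,
#'   `n_skipped_constant`.
#' @export
build_network <- function(community, corr_method = c("spearman", "pearson"),
                          rho_min = 0.6, alpha = 0.05, adjust = "BH") {
  corr_method <- match.arg(corr_method)
  if (nrow(community) < 3) stop("need >= 3 samples", call. = FALSE)
  rel <- relative_abundance(community)
  nodes <- colnames(rel)
  p <- ncol(rel)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  const <- apply(rel, 2, function(x) var(x) == 0)
  rho <- pv <- rep(NA_real_, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (const[i] || const[j]) next
    ct <- suppressWarnings(cor.test(rel[, i], rel[, j], method = corr_method,
                                    exact = FALSE))
    rho[r] <- unname(ct$estimate); pv[r] <- ct$p.value
  }
  q <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  q[ok] <- p.adjust(pv[ok], method = adjust)
  keep <- ok & abs(rho) >= rho_min & q <= alpha
  edges <- data.frame(node1 = nodes[pairs[keep, 1]],
                      node2 = nodes[pairs[keep, 2]],
                      rho = rho[keep], p = pv[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("node1", "node2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(corr_method = corr_method, rho_min = rho_min,
                               alpha = alpha, adjust = adjust),
                 n_skipped_constant = sum((const[pairs[, 1]] | const[pairs[, 2]]))),
            class = "co_network")
}

#' Topology summary: APL, Tarn, ND
#'
#' Average shortest-path length (APL, edges as unit length) and diameter
#' (ND) computed on the largest connected component (reported alongside the
#' component count, since both are undefined on disconnected graphs);
#' transitivity (Tarn = 3 x triangles / connected triples) on the whole
#' graph, 0 when the graph has no connected triple. An edgeless graph gets
#' NA sentinels for APL/ND.
#'
#' @param network A `co_network` or an igraph graph.
#' @return List: `APL`, `Tarn`, `ND`, `n_components`, `n_nodes_lcc`,
#'   `n_edges`.
#' @export
topology <- function(network) {
  g <- if (inherits(network, "co_network")) network$graph else network
  comp <- igraph::components(g)
  nontrivial <- sum(comp$csize > 1)
  tarn <- igraph::transitivity(g, type = "global")
  if (is.nan(tarn)) tarn <- 0
  if (igraph::ecount(g) == 0)
    return(list(APL = NA_real_, Tarn = tarn, ND = NA_real_,
                n_components = nontrivial, n_nodes_lcc = 0L,
                n_edges = 0L))
  lcc_id <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(g, which(comp$membership == lcc_id))
  list(APL = igraph::mean_distance(lcc, directed = FALSE, unconnected = FALSE),
       Tarn = tarn,
       ND = igraph::diameter(lcc, directed = FALSE, unconnected = FALSE,
                             weights = NA),
       n_components = nontrivial,
       n_nodes_lcc = igraph::vcount(lcc),
       n_edges = igraph::ecount(g))
}

#' Per-group co-occurrence networks and topology
#'
#' Builds a top-`k` network within each group of samples (e.g. season) and
#' summarizes topology.
#'
#' @param community Samples x OTUs matrix.
#' @param groups Named per-sample group labels.
#' @param k Top-OTU count per group.
#' @param ... Passed to [build_network()].
#' @return List: `networks` (per group), `topology` data.frame.
#' @export
group_networks <- function(community, groups, k = 100, ...) {
  groups <- groups[rownames(community)]
  nets <- list(); rows <- list()
  for (g in unique(groups)) {
    sub <- community[groups == g, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    net <- build_network(select_top_otus(sub, k), ...)
    top <- topology(net)
    nets[[g]] <- net
    rows[[g]] <- data.frame(group = g, APL = top$APL, Tarn = top$Tarn,
                            ND = top$ND, n_components = top$n_components,
                            n_edges = top$n_edges, stringsAsFactors = FALSE)
  }
  list(networks = nets, topology = do.call(rbind, rows))
}

#' @export
print.co_network <- function(x, ...) {
  cat("co-occurrence network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (", x$params$corr_method, ", |rho| >=", x$params$rho_min,
      ", q <=", x$params$alpha, ")\n")
  invisible(x)
}
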
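# Independent brute-force oracles. These deliberately avoid the package's
# computational routes (C++ metrics, igraph, vegan) so agreement is a real
# two-route check.

# Patristic distance via root paths: d(i, j) = depth(i) + depth(j)
# - 2 * depth(LCA), with depths/ancestors walked edge by edge.
oracle_patristic <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge)); elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- node; len <- c(0)
    while (node != root) {
      len <- c(len, len[length(len)] + elen[node])
      node <- parent[node]
      nodes <- c(nodes, node)
    }
    setNames(len, nodes)
  }
  d <- matrix(0, n_tip, n_tip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n_tip), path_to_root)
  for (i in seq_len(n_tip)) for (j in seq_len(n_tip)) {
    if (i >= j) next
    pi <- paths[[i]]; pj <- paths[[j]]
    shared <- intersect(names(pi), names(pj))
    lca_depth <- min(pi[shared])  # first shared ancestor has smallest path length
    lca <- shared[which.min(pi[shared])]
    d[i, j] <- d[j, i] <- pi[lca] + pj[lca]
  }
  d
}

# Double-loop MPD/MNTD on one abundance vector.
oracle_mpd <- function(abund, d, weighted) {
  pres <- names(abund)[abund > 0]
  if (length(pres) < 2) return(NA_real_)
  w <- abund[pres] / sum(abund[pres])
  num <- den <- 0
  for (i in pres) for (j in pres) {
    if (i == j) next
    wij <- if (weighted) w[i] * w[j] else 1
    num <- num + wij * d[i, j]; den <- den + wij
  }
  num / den
}

oracle_mntd <- function(abund, d, weighted) {
  pres <- names(abund)[abund > 0]
  if (length(pres) < 2) return(NA_real_)
  w <- abund[pres] / sum(abund[pres])
  acc <- 0
  for (i in pres) {
    m <- min(sapply(setdiff(pres, i), function(j) d[i, j]))
    acc <- acc + if (weighted) w[i] * m else m / length(pres)
  }
  acc
}

oracle_beta_mntd <- function(a, b, d, weighted) {
  pa <- names(a)[a > 0]; pb <- names(b)[b > 0]
  wa <- a[pa] / sum(a[pa]); wb <- b[pb] / sum(b[pb])
  one_dir <- function(pres, other, w) {
    acc <- 0
    for (i in pres) {
      m <- min(sapply(other, function(j) d[i, j]))
      acc <- acc + if (weighted) w[i] * m else m / length(pres)
    }
    unname(acc)
  }
  (one_dir(pa, pb, wa) + one_dir(pb, pa, wb)) / 2
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Exhaustive BFS topology on an edge list over given nodes.
oracle_topology <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(src) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[src] <- 0; queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1; queue <- c(queue, u)
      }
    }
    dist
  }
  dists <- sapply(nodes, bfs)  # matrix dist[target, source]
  # largest connected component
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes); k <- 0
  for (v in nodes) if (is.na(comp[v])) {
    k <- k + 1
    comp[names(bfs(v))[is.finite(bfs(v))]] <- k
  }
  sizes <- table(comp)
  lcc <- names(comp)[comp == names(sizes)[which.max(sizes)]]
  if (length(lcc) < 2) return(list(APL = NA_real_, ND = NA_real_, Tarn = oracle_tarn(nodes, adj)))
  sub <- dists[lcc, lcc]
  off <- sub[upper.tri(sub)]
  list(APL = mean(off), ND = max(off), Tarn = oracle_tarn(nodes, adj))
}

oracle_tarn <- function(nodes, adj) {
  triangles <- 0; triples <- 0
  for (v in nodes) {
    nb <- unique(adj[[v]])
    k <- length(nb)
    if (k < 2) next
    triples <- triples + choose(k, 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (nb[j] %in% adj[[nb[i]]]) triangles <- triangles + 1
  }
  if (triples == 0) return(0)
  # each triangle counted once per vertex = 3 times total
  triangles / triples
}

# Random rooted tree with branch lengths, via ape (standard substrate;
# the oracle part is the arithmetic above, not tree generation).
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

random_community <- function(n_samples, taxa, seed, depth = 200) {
  set.seed(seed)
  m <- t(vapply(seq_len(n_samples), function(i) {
    w <- rlnorm(length(taxa), 0, 1)
    rmultinom(1, depth, w / sum(w))[, 1]
  }, integer(length(taxa))))
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)), taxa)
  m
}
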
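#' RPKM gene abundances
#'
#' `RPKM(s, g) = count(s, g) / ((length_g / 1e3) * (total_s / 1e6))` with
#' `total_s` the sample's total mapped reads. Invariant under uniform
#' scaling of a sample's counts together with its total.
#'
#' @param counts Samples x genes count matrix.
#' @param gene_length_bp Named (or ordered) gene lengths in bp (> 0).
#' @param total_mapped_reads Named (or ordered) per-sample totals (> 0).
#' @return Samples x genes RPKM matrix; attributes keep the inputs used.
#' @export
rpkm <- function(counts, gene_length_bp, total_mapped_reads) {
  if (!is.null(names(gene_length_bp)))
    gene_length_bp <- gene_length_bp[colnames(counts)]
  if (!is.null(names(total_mapped_reads)))
    total_mapped_reads <- total_mapped_reads[rownames(counts)]
  if (any(is.na(gene_length_bp)) || any(gene_length_bp <= 0))
    stop("gene lengths must be positive for all genes", call. = FALSE)
  bad <- which(is.na(total_mapped_reads) | total_mapped_reads <= 0)
  if (length(bad))
    stop("nonpositive total mapped reads for sample(s): ",
         paste(rownames(counts)[bad], collapse = ", "), call. = FALSE)
  out <- sweep(counts, 2, gene_length_bp / 1e3, "/")
  out <- sweep(out, 1, total_mapped_reads / 1e6, "/")
  structure(out, gene_length_bp = gene_length_bp,
            total_mapped_reads = total_mapped_reads)
}

#' Aggregate gene abundances to nitrogen-cycle pathways
#'
#' Pathway abundance is the sum of its member genes' RPKM.
#'
#' @param table Samples x genes RPKM (or count) matrix.
#' @param pathway_map data.frame with `gene_id` and `pathway` columns
#'   covering every gene in `table`.
#' @return Samples x pathways matrix.
#' @export
aggregate_pathways <- function(table, pathway_map) {
  unmapped <- setdiff(colnames(table), pathway_map$gene_id)
  if (length(unmapped))
    stop("unmapped gene(s): ", paste(unmapped, collapse = ", "), call. = FALSE)
  pw <- pathway_map$pathway[match(colnames(table), pathway_map$gene_id)]
  pws <- unique(pathway_map$pathway)
  out <- matrix(0, nrow(table), length(pws),
                dimnames = list(rownames(table), pws))
  for (p in pws) {
    cols <- which(pw == p)
    if (length(cols))
      out[, p] <- rowSums(table[, cols, drop = FALSE])
  }
  out
}

#' Functional dissimilarity between samples
#'
#' Bray-Curtis (default) or Euclidean distance on RPKM profiles.
#'
#' @param table Samples x genes RPKM matrix (>= 2 samples).
#' @param metric `"bray"` or `"euclidean"`.
#' @return Symmetric distance matrix.
#' @export
functional_dissimilarity <- function(table, metric = c("bray", "euclidean")) {
  metric <- match.arg(metric)
  if (nrow(table) < 2) stop("need >= 2 samples", call. = FALSE)
  if (metric == "bray" && any(rowSums(table) == 0))
    stop("Bray-Curtis undefined for all-zero sample(s): ",
         paste(rownames(table)[rowSums(table) == 0], collapse = ", "),
         call. = FALSE)
  as.matrix(vegan::vegdist(table, method = ifelse(metric == "bray",
                                                  "bray", "euclidean")))
}

#' Two-group tests of gene (and pathway) abundances
#'
#' Welch two-sample t-test per column between the two levels of `groups`
#' (e.g. March vs September, or high vs low latitude), with
#' Benjamini-Hochberg q-values across columns. A column with zero variance
#' in both groups gets an NA sentinel.
#'
#' @param table Samples x genes (or pathways) abundance matrix.
#' @param groups Named two-level factor/character over the samples.
#' @param pooled Use the pooled-variance t instead of Welch.
#' @return data.frame: feature, mean per group, t, p, q.
#' @export
spatiotemporal_tests <- function(table, groups, pooled = FALSE) {
  groups <- groups[rownames(table)]
  lv <- unique(na.omit(groups))
  if (length(lv) != 2) stop("need exactly two groups", call. = FALSE)
  a <- table[groups == lv[1], , drop = FALSE]
  b <- table[groups == lv[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("each group needs n >= 2", call. = FALSE)
  res <- lapply(colnames(table), function(g) {
    x <- a[, g]; y <- b[, g]
    if (var(x) == 0 && var(y) == 0)
      return(data.frame(feature = g, mean_1 = mean(x), mean_2 = mean(y),
                        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    tt <- t.test(x, y, var.equal = pooled)
    data.frame(feature = g, mean_1 = mean(x), mean_2 = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", lv)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  structure(out, groups = lv, welch = !pooled)
}

#' Spearman correlations of the top-k genes with SIN variables
#'
#' Ranks genes by mean RPKM, keeps the top `k` (default 10) and screens
#' them against the SIN columns of the environment table.
#'
#' @param rpkm_table Samples x genes RPKM matrix.
#' @param env Environment matrix (uses NO2, NO3, NH4 columns).
#' @param k Number of top genes.
#' @return An association table from [spearman_screen()].
#' @export
top_gene_sin_correlations <- function(rpkm_table, env, k = 10) {
  k <- min(k, ncol(rpkm_table))
  top <- names(sort(colMeans(rpkm_table), decreasing = TRUE))[seq_len(k)]
  sin <- intersect(c("NO2", "NO3", "NH4"), colnames(env))
  spearman_screen(rpkm_table[, top, drop = FALSE],
                  env[rownames(rpkm_table), sin, drop = FALSE])
}
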
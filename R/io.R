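#' Read and validate a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream phylogenetic metrics rely on: at least two uniquely labelled
#' tips, branch lengths present and nonnegative.
#'
#' @param path Path to a Newick file.
#' @param text Newick string; used instead of `path` when supplied.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: could not parse a tree", call. = FALSE)
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Validate tree invariants
#'
#' @param tree An `ape::phylo` tree.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2)
    stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be present and nonnegative", call. = FALSE)
  invisible(tree)
}

# Sniff TSV vs CSV from the header line.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a typed sample-by-feature table
#'
#' First column holds sample identifiers, the header row feature identifiers.
#' TSV by default; CSV accepted by delimiter sniffing. `kind` selects the
#' validation applied:
#' * `community` — nonnegative abundances, every sample total positive;
#' * `env` — numeric environmental variables, concentration columns
#'   (everything except pH, MAT temperature, and latitude/ordination axes)
#'   must be nonnegative;
#' * `gene_counts` — nonnegative integer read counts.
#'
#' @param path File path.
#' @param kind One of `"community"`, `"env"`, `"gene_counts"`.
#' @return A numeric matrix with sample rownames and feature colnames.
#' @export
read_table_typed <- function(path, kind = c("community", "env", "gene_counts")) {
  kind <- match.arg(kind)
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample ids in ", path, call. = FALSE)
  if (kind %in% c("community", "gene_counts")) {
    if (any(m < 0, na.rm = TRUE))
      stop("negative entries not allowed for kind '", kind, "'", call. = FALSE)
  }
  if (kind == "community") {
    tot <- rowSums(m)
    if (any(tot <= 0))
      stop("samples with zero total abundance: ",
           paste(rownames(m)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  if (kind == "env") {
    allow_neg <- c("pH", "MAT", "latitude", "lat")
    conc <- setdiff(colnames(m), allow_neg)
    bad <- conc[vapply(conc, function(v) any(m[, v] < 0, na.rm = TRUE), logical(1))]
    if (length(bad))
      stop("negative concentrations in column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

#' Read per-sample metadata (sample_id, site, season, latitude_group)
#' @param path TSV/CSV with a `sample_id` column.
#' @return A data.frame keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  df
}

#' Read a gene map (gene_id, length_bp, pathway)
#' @param path TSV/CSV file.
#' @return A data.frame with one row per gene.
#' @export
read_gene_map <- function(path) {
  sep <- sniff_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "length_bp", "pathway")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene map missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in gene map", call. = FALSE)
  if (any(df$length_bp <= 0)) stop("gene lengths must be positive", call. = FALSE)
  df
}

#' Check that community taxa are tips of the tree
#'
#' Taxa present in the community but absent from the tree are an error by
#' default; with `prune_missing = TRUE` they are dropped and counted.
#'
#' @param community Samples x taxa matrix.
#' @param tree An `ape::phylo` tree.
#' @param prune_missing Drop unknown taxa instead of erroring.
#' @return The (possibly pruned) community matrix, with attribute
#'   `n_pruned` when pruning occurred.
#' @export
match_community_tree <- function(community, tree, prune_missing = FALSE) {
  validate_tree(tree)
  missing <- setdiff(colnames(community), tree$tip.label)
  if (length(missing)) {
    if (!prune_missing)
      stop("taxa absent from tree: ", paste(head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10),
           call. = FALSE)
    community <- community[, setdiff(colnames(community), missing), drop = FALSE]
    attr(community, "n_pruned") <- length(missing)
    message("pruned ", length(missing), " taxa absent from tree")
  }
  community
}

#' Restrict tables to their common samples, in a consistent order
#'
#' @param ... Two or more matrices/data.frames whose rows (or `sample_id`
#'   column, for metadata frames) identify samples.
#' @return A list of the same objects restricted to the shared samples, all
#'   in the same order; attribute `dropped` lists removed ids per input.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  if (length(objs) < 2) stop("need at least two tables", call. = FALSE)
  ids <- lapply(objs, function(o) {
    if (is.data.frame(o) && "sample_id" %in% names(o)) o$sample_id else rownames(o)
  })
  common <- Reduce(intersect, ids)
  if (!length(common)) stop("no samples shared across tables", call. = FALSE)
  dropped <- lapply(ids, function(x) setdiff(x, common))
  out <- Map(function(o, id) {
    if (is.data.frame(o) && "sample_id" %in% names(o)) {
      o[match(common, o$sample_id), , drop = FALSE]
    } else {
      o[match(common, id), , drop = FALSE]
    }
  }, objs, ids)
  names(out) <- names(objs)
  attr(out, "dropped") <- dropped
  out
}

#' Write a matrix or data.frame as a stable TSV
#'
#' Fixed quoting and number formatting so identical inputs give
#' byte-identical files; matrices get their rownames as a leading
#' `row_label` column.
#'
#' @param x Matrix (rownames become the first column) or data.frame.
#' @param path Output path.
#' @param row_label Column name for matrix rownames.
#' @return `path`, invisibly.
#' @export
write_tsv_stable <- function(x, path, row_label = "sample_id") {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1] <- row_label
  } else df <- x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
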
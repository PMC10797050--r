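#' PCA reduction with a deterministic sign convention
#'
#' Columns are z-scored (zero-variance columns dropped with a message)
#' before [stats::prcomp()]. PC1 is oriented to correlate positively with
#' `orient_to` (default: the row sums of the original table, i.e. total
#' abundance), so the composite's sign is reproducible regardless of the
#' eigendecomposition's arbitrary sign.
#'
#' @param table Samples x variables matrix (>= 2 variables, n >= 3).
#' @param n_components Components to keep (default: all).
#' @param orient_to Numeric vector used to orient PC1.
#' @return List: `scores`, `loadings`, `variance_explained`.
#' @export
pca_reduce <- function(table, n_components = NULL, orient_to = NULL) {
  table <- as.matrix(table)
  stopifnot(ncol(table) >= 2, nrow(table) >= 3)
  v <- apply(table, 2, var)
  if (any(v == 0)) {
    message("dropping zero-variance column(s): ",
            paste(colnames(table)[v == 0], collapse = ", "))
    table <- table[, v > 0, drop = FALSE]
  }
  if (ncol(table) < 2) stop("fewer than 2 informative columns", call. = FALSE)
  orient_to <- orient_to %||% rowSums(table)
  pc <- prcomp(table, center = TRUE, scale. = TRUE)
  k <- min(n_components %||% ncol(pc$x), ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  if (cor(scores[, 1], orient_to) < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       variance_explained = ve[seq_len(k)])
}

#' Parse a path-model specification
#'
#' One directed edge per line, `source -> target`; `#` starts a comment.
#' The edge set must form a DAG over observed variables.
#'
#' @param x A file path or a character vector of spec lines.
#' @return data.frame (from, to) of class `path_spec`.
#' @export
parse_path_spec <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^(\\S+)\\s*->\\s*(\\S+)$", lines))
  bad <- lines[vapply(m, length, 1L) != 3]
  if (length(bad)) stop("malformed edge line(s): ", paste(bad, collapse = "; "),
                        call. = FALSE)
  edges <- data.frame(from = vapply(m, `[`, "", 2), to = vapply(m, `[`, "", 3),
                      stringsAsFactors = FALSE)
  assert_dag(edges)
  class(edges) <- c("path_spec", class(edges))
  edges
}

# Topological order of the edge set (Kahn's algorithm); errors on cycles.
assert_dag <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  remaining <- edges
  order <- character(0)
  while (length(order) < length(nodes)) {
    src <- setdiff(setdiff(nodes, order), remaining$to)
    if (!length(src))
      stop("path specification contains a cycle", call. = FALSE)
    order <- c(order, src)
    remaining <- remaining[!remaining$from %in% order, , drop = FALSE]
  }
  order
}

#' Fit an observed-variable path model
#'
#' Recursive path analysis on standardized variables: each endogenous
#' variable is regressed by OLS on its parents, which for a recursive
#' observed-variable DAG yields the maximum-likelihood standardized path
#' coefficients. Indirect effects along a chain are products of its
#' standardized coefficients.
#'
#' @param spec A `path_spec` (or something [parse_path_spec()] accepts).
#' @param data data.frame with every spec variable; complete cases only.
#' @return List of class `path_model_fit`: `edges` (from, to, coefficient,
#'   se, p), `r2` per endogenous variable, `n`, `spec`.
#' @export
fit_path_model <- function(spec, data) {
  if (!inherits(spec, "path_spec")) spec <- parse_path_spec(spec)
  vars <- unique(c(spec$from, spec$to))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("data lacks variable(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  n <- nrow(data)
  if (n < 30) stop("need n >= 30 complete cases", call. = FALSE)
  if (n < 3 * length(vars))
    warning("n < 3 x variables; coefficients may be unstable")
  z <- as.data.frame(scale(data))
  edges <- spec
  edges$coefficient <- edges$se <- edges$p <- NA_real_
  r2 <- c()
  for (y in unique(spec$to)) {
    parents <- spec$from[spec$to == y]
    fit <- lm(as.formula(paste(y, "~", paste(parents, collapse = " + "))),
              data = z)
    sm <- summary(fit)
    for (pvar in parents) {
      i <- which(edges$to == y & edges$from == pvar)
      edges$coefficient[i] <- sm$coefficients[pvar, 1]
      edges$se[i] <- sm$coefficients[pvar, 2]
      edges$p[i] <- sm$coefficients[pvar, 4]
    }
    r2[y] <- sm$r.squared
  }
  structure(list(edges = as.data.frame(edges), r2 = r2, n = n, spec = spec),
            class = "path_model_fit")
}

#' Indirect effect along a chain of variables
#'
#' @param fit A `path_model_fit`.
#' @param chain Character vector of variables, e.g. `c("SIN", "PhyloDiv",
#'   "Nfunc")`.
#' @return Product of the standardized coefficients along the chain.
#' @export
indirect_effect <- function(fit, chain) {
  stopifnot(length(chain) >= 2)
  coefs <- vapply(seq_len(length(chain) - 1), function(i) {
    j <- which(fit$edges$from == chain[i] & fit$edges$to == chain[i + 1])
    if (!length(j)) stop("no edge ", chain[i], " -> ", chain[i + 1], call. = FALSE)
    fit$edges$coefficient[j]
  }, numeric(1))
  prod(coefs)
}

#' Compare an environment-only and a phylogeny-mediated path model
#'
#' Reports the R-squared of the shared nitrogen-function endogenous
#' variable under both fits, their ratio, and coefficients whose
#' significance class (at `alpha`) changes between models.
#'
#' @param fit_env_only,fit_with_phylo `path_model_fit` objects fit on the
#'   same samples with the same outcome variable.
#' @param outcome Endogenous variable to compare (default `"Nfunc"`).
#' @param alpha Significance level for the class comparison.
#' @return List: `r2_env_only`, `r2_with_phylo`, `r2_ratio`,
#'   `changed_edges`.
#' @export
compare_models <- function(fit_env_only, fit_with_phylo, outcome = "Nfunc",
                           alpha = 0.05) {
  if (fit_env_only$n != fit_with_phylo$n)
    stop("fits use different sample sizes", call. = FALSE)
  if (!outcome %in% names(fit_env_only$r2) ||
      !outcome %in% names(fit_with_phylo$r2))
    stop("outcome not endogenous in both fits", call. = FALSE)
  e1 <- fit_env_only$edges; e2 <- fit_with_phylo$edges
  key <- function(e) paste(e$from, e$to)
  shared <- intersect(key(e1), key(e2))
  s1 <- e1$p[match(shared, key(e1))] <= alpha
  s2 <- e2$p[match(shared, key(e2))] <= alpha
  list(r2_env_only = unname(fit_env_only$r2[outcome]),
       r2_with_phylo = unname(fit_with_phylo$r2[outcome]),
       r2_ratio = unname(fit_with_phylo$r2[outcome] / fit_env_only$r2[outcome]),
       changed_edges = shared[which(s1 != s2)])
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat("path model:", nrow(x$edges), "edges, n =", x$n, "\n")
  print(cbind(x$edges[, c("from", "to")],
              round(x$edges[, c("coefficient", "se", "p")], 4)))
  cat("R2:", paste(sprintf("%s = %.3f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Built-in path-model specifications
#'
#' Reconstructed observed-variable specifications: `env_only` (temperature
#' -> SIN and soil covariates -> nitrogen function) and `phylo_mediation`
#' (adding a phylogenetic-diversity block mediating SIN -> function).
#' Shipped as editable text files under `inst/models/`.
#'
#' @param name `"env_only"` or `"phylo_mediation"`.
#' @return A `path_spec`.
#' @export
builtin_path_spec <- function(name = c("env_only", "phylo_mediation")) {
  name <- match.arg(name)
  path <- system.file("models", paste0(name, ".path"), package = "phylosin")
  parse_path_spec(path)
}
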
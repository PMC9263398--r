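#' Network-based statistic (NBS) permutation test
#'
#' Controls the family-wise error rate over connected components of
#' suprathreshold edges in an edge-wise group contrast. Each edge of the
#' subjects x edges matrix is tested with the covariate-adjusted group GLM
#' ([fit_group_glm()]); edges with `|t| >= t(primary_p)` form a graph whose
#' connected components (edges joined through shared ROI endpoints) are the
#' candidate effects. The null distribution of the maximal component size
#' (edge count) is built by permuting group labels across subjects while
#' keeping each subject's covariates attached, and
#' `p_fwe = (1 + #\{null max >= observed size\}) / (1 + n_perm)`.
#'
#' @param edge_values Subjects x edges numeric matrix (rownames matched to
#'   `phenotypes$subject_id` when present).
#' @param edges Data frame with columns `node1`, `node2` (ROI ids), one row
#'   per column of `edge_values`.
#' @param phenotypes Phenotype table (see [fit_group_glm()]).
#' @param n_perm Number of permutations (default 1000; below 100 warns).
#' @param primary_p Two-sided p-value defining the edge threshold
#'   (default 0.005).
#' @param covariates Covariate columns for the GLM.
#' @param seed Optional RNG seed for the permutation stream.
#' @param permutations Optional matrix of row indices (one permutation per
#'   row) overriding the random stream; used for deterministic checks.
#' @return An `nbs_result` list: `components` (list of edge-index vectors),
#'   `component_size`, `p_fwe`, `n_permutations`, `primary_threshold` (the t
#'   cut-off), `null_max_size`, `observed_t`, and a flag
#'   `all_suprathreshold`.
#' @export
nbs_test <- function(edge_values, edges, phenotypes, n_perm = 1000L,
                     primary_p = 0.005,
                     covariates = c("age", "sex", "education", "mean_fd"),
                     seed = NULL, permutations = NULL) {
  stopifnot(nrow(edges) == ncol(edge_values))
  if (!is.null(rownames(edge_values))) {
    idx <- match(phenotypes$subject_id, rownames(edge_values))
    if (anyNA(idx)) stop("subjects missing from the edge matrix")
    edge_values <- edge_values[idx, , drop = FALSE]
  }
  X <- group_design(phenotypes, covariates)
  n <- nrow(X)
  if (!is.null(permutations)) {
    permutations <- as.matrix(permutations)
    stopifnot(ncol(permutations) == n)
    n_perm <- nrow(permutations)
  }
  if (n_perm < 100L) {
    warning("n_perm = ", n_perm, " permutations gives a coarse ",
            "null distribution; 1000 is conventional")
  }
  if (!is.null(seed)) set.seed(seed)

  fit <- glm_group_t(X, edge_values)
  t_crit <- stats::qt(1 - primary_p / 2, fit$df)
  supra <- which(abs(fit$t) >= t_crit)
  all_supra <- length(supra) == ncol(edge_values)
  comp <- edge_components(edges, supra)

  g_col <- which(colnames(X) == "group")
  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- if (is.null(permutations)) sample.int(n) else permutations[b, ]
    Xp <- X
    Xp[, g_col] <- X[perm, g_col]
    tp <- glm_group_t(Xp, edge_values)$t
    sp <- which(abs(tp) >= t_crit)
    null_max[b] <- if (length(sp) == 0L) 0L else
      max(lengths(edge_components(edges, sp)))
  }
  sizes <- unname(lengths(comp))
  p_fwe <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (1 + n_perm),
                  numeric(1))
  structure(list(
    components = comp,
    component_size = sizes,
    p_fwe = p_fwe,
    n_permutations = n_perm,
    primary_threshold = t_crit,
    null_max_size = null_max,
    observed_t = fit$t,
    all_suprathreshold = all_supra
  ), class = "nbs_result")
}

# Connected components of the suprathreshold edge subgraph; edges belong to
# the same component when reachable through shared ROI endpoints. Returns a
# list of integer vectors of edge indices (into the full edge frame).
edge_components <- function(edges, supra_idx) {
  if (length(supra_idx) == 0L) return(list())
  sub <- edges[supra_idx, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$node1), to = as.character(sub$node2)),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  split(supra_idx, memb[as.character(sub$node1)])
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS permutation test:", length(x$components),
      "suprathreshold component(s),", x$n_permutations, "permutations\n")
  cat("primary |t| threshold:", signif(x$primary_threshold, 4), "\n")
  if (length(x$components) > 0L) {
    for (i in seq_along(x$components)) {
      cat(sprintf("  component %d: %d edge(s), p_fwe = %.4g\n",
                  i, x$component_size[i], x$p_fwe[i]))
    }
  }
  if (x$all_suprathreshold) {
    cat("  note: every edge crossed the primary threshold\n")
  }
  invisible(x)
}
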
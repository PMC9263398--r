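#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the OLS residuals of `x` and `y` on
#' `[intercept, covariates]`; with no covariates this is the ordinary
#' Pearson correlation. The p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n`.
#' @param covariates Optional n x k numeric matrix (or vector).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `r`, `p`, `df`, `n`, `k`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    k <- ncol(covariates)
  }
  if (n <= k + 3L) stop("need n > k + 3 observations")
  Z <- cbind(rep(1, n), covariates)
  qr_z <- qr(Z)
  rx <- qr.resid(qr_z, x)
  ry <- qr.resid(qr_z, y)
  tol <- 1e-12
  if (stats::sd(rx) <= tol * max(mean(abs(x)), 1e-300) ||
      stats::sd(ry) <= tol * max(mean(abs(y)), 1e-300)) {
    stop("zero residual variance after covariate adjustment")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t_stat), df),
              greater = stats::pt(t_stat, df, lower.tail = FALSE),
              less = stats::pt(t_stat, df))
  list(r = r, p = min(p, 1), df = df, n = n, k = k)
}

#' Compare two independent correlations via Fisher's Z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3 - k) + 1/(n2 - 3 - k))`,
#' with a normal reference distribution. `k` adjusts the Fisher variance for
#' the covariates removed before each correlation.
#'
#' @param r1,r2 Correlations (|r| < 1) from two independent groups.
#' @param n1,n2 Group sample sizes.
#' @param k Number of adjustment covariates (default 0).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `z` and `p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2, k = 0L,
                                        alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1")
  if (n1 - 3 - k <= 0 || n2 - 3 - k <= 0) {
    stop("insufficient sample size for the Fisher variance (need n > k + 3)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3 - k) + 1 / (n2 - 3 - k))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p)
}

#' Clinical correlation grid with per-group comparison
#'
#' For every metric column x score column pair: the covariate-adjusted
#' partial correlation over all subjects (`r_all`, FDR over the whole grid as
#' one family), the per-group partial correlations (`r_scd`, `r_nc`), and
#' their Fisher-Z comparison (`group_diff_z`, grid-wise FDR `group_diff_q`).
#' The group comparison is two-sided by default; `one_sided_group_diff`
#' switches it to one-sided in the direction of the observed difference.
#'
#' @param metrics Subjects x metrics numeric matrix (named columns; rownames
#'   matched to `phenotypes$subject_id` when present).
#' @param phenotypes Phenotype table carrying the covariates and the score
#'   columns.
#' @param scores Score column names present in `phenotypes`.
#' @param covariates Covariate column names.
#' @param fdr_q Significance level applied to the FDR-corrected grids.
#' @param one_sided_group_diff Use a one-sided group comparison (default
#'   FALSE).
#' @return Long data frame, one row per metric x score cell.
#' @export
correlation_grid <- function(metrics, phenotypes,
                             scores = intersect(clinical_score_names,
                                                names(phenotypes)),
                             covariates = c("age", "sex", "education",
                                            "mean_fd"),
                             fdr_q = 0.05, one_sided_group_diff = FALSE) {
  if (!is.null(rownames(metrics))) {
    idx <- match(phenotypes$subject_id, rownames(metrics))
    if (anyNA(idx)) stop("subjects missing from the metric matrix")
    metrics <- metrics[idx, , drop = FALSE]
  }
  Z <- covariate_matrix(phenotypes, covariates)
  k <- ncol(Z)
  is_scd <- phenotypes$group == "SCD"
  cells <- expand.grid(metric = colnames(metrics), score = scores,
                       stringsAsFactors = FALSE)
  na_fit <- list(r = NA_real_, p = NA_real_, df = NA_integer_,
                 n = NA_integer_, k = k)
  safe_pc <- function(...) {
    tryCatch(partial_correlation(...), error = function(e) na_fit)
  }
  res <- lapply(seq_len(nrow(cells)), function(i) {
    m <- metrics[, cells$metric[i]]
    s <- phenotypes[[cells$score[i]]]
    ok <- stats::complete.cases(m, s, Z)
    all_fit <- safe_pc(m[ok], s[ok], Z[ok, , drop = FALSE])
    scd <- safe_pc(m[ok & is_scd], s[ok & is_scd],
                   Z[ok & is_scd, , drop = FALSE])
    nc <- safe_pc(m[ok & !is_scd], s[ok & !is_scd],
                  Z[ok & !is_scd, , drop = FALSE])
    cmp <- if (is.na(scd$r) || is.na(nc$r)) {
      list(z = NA_real_, p = NA_real_)
    } else {
      alt <- if (!one_sided_group_diff) "two.sided"
             else if (scd$r >= nc$r) "greater" else "less"
      compare_correlations_fisher(scd$r, scd$n, nc$r, nc$n, k = k,
                                  alternative = alt)
    }
    data.frame(metric = cells$metric[i], score = cells$score[i],
               r_all = all_fit$r, p_all = all_fit$p, df_all = all_fit$df,
               r_scd = scd$r, r_nc = nc$r,
               group_diff_z = cmp$z, group_diff_p = cmp$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q_fdr <- fdr_correct(res$p_all)
  res$group_diff_q <- fdr_correct(res$group_diff_p)
  res$significant <- !is.na(res$q_fdr) & res$q_fdr < fdr_q
  res$group_diff_significant <- !is.na(res$group_diff_q) &
    res$group_diff_q < fdr_q
  res
}

covariate_matrix <- function(phenotypes, covariates) {
  Z <- vapply(covariates, function(cv) {
    v <- phenotypes[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' missing from phenotypes")
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      as.numeric(as.character(v) == "female")
    } else as.numeric(v)
  }, numeric(nrow(phenotypes)))
  matrix(Z, nrow = nrow(phenotypes),
         dimnames = list(NULL, covariates))
}
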
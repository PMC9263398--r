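# Shared design-matrix construction for the covariate-adjusted group model.
# Coding: group SCD = 1 (contrast SCD - NC), sex female = 1, male = 0.
group_design <- function(phenotypes,
                         covariates = c("age", "sex", "education",
                                        "mean_fd")) {
  if (any(table(phenotypes$group) < 2L)) {
    stop("each group needs at least 2 subjects")
  }
  X <- cbind(intercept = rep(1, nrow(phenotypes)),
             group = as.numeric(phenotypes$group == "SCD"))
  for (cv in covariates) {
    v <- phenotypes[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' missing from phenotypes")
    if (cv == "sex" || is.character(v) || is.factor(v)) {
      v <- as.numeric(as.character(v) == "female")
    }
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  X
}

# Vectorized OLS group t-test over the columns of Y (subjects x units).
# One QR factorization serves every unit.
glm_group_t <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qr_x, Y)
  res <- qr.resid(qr_x, Y)
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  # a numerically zero residual (y exactly in the design span) is a null
  # effect, not an infinite t
  s2[s2 <= 1e-20 * pmax(colMeans(Y^2), .Machine$double.xmin)] <- NA
  xtx_inv_gg <- chol2inv(qr.R(qr_x))[qr_x$pivot == 2L, qr_x$pivot == 2L]
  se <- sqrt(s2 * xtx_inv_gg)
  beta <- coef["group", ]
  t_stat <- ifelse(is.na(se), 0, beta / se)
  list(beta = beta, t = t_stat, df = df,
       p = 2 * stats::pt(-abs(t_stat), df))
}

#' Covariate-adjusted group contrast per unit
#'
#' Fits, for every unit (ROI or edge), a Gaussian-identity GLM — ordinary
#' least squares — of the metric on group plus the adjustment covariates
#' (age, sex, education, mean frame displacement by default) and tests the
#' group coefficient (SCD minus NC) with a two-sided Wald t test. With
#' exactly two groups the Tukey post hoc comparison coincides with this
#' test, so no separate branch is needed.
#'
#' @param values Numeric subjects x units matrix (rownames matched against
#'   `phenotypes$subject_id` when present) or a vector for a single unit.
#' @param phenotypes Phenotype data frame with `subject_id`, `group` and the
#'   covariate columns.
#' @param covariates Covariate column names.
#' @return Data frame `unit`, `beta_group`, `t_stat`, `p_raw`, with the
#'   residual degrees of freedom as attribute `"df"`.
#' @export
fit_group_glm <- function(values, phenotypes,
                          covariates = c("age", "sex", "education",
                                         "mean_fd")) {
  if (is.null(dim(values))) {
    values <- matrix(values, ncol = 1L,
                     dimnames = list(names(values), "value"))
  }
  if (!is.null(rownames(values))) {
    idx <- match(phenotypes$subject_id, rownames(values))
    if (anyNA(idx)) {
      stop("subjects missing from the value matrix: ",
           paste(phenotypes$subject_id[is.na(idx)], collapse = ", "))
    }
    values <- values[idx, , drop = FALSE]
  } else if (nrow(values) != nrow(phenotypes)) {
    stop("value rows do not match the phenotype table")
  }
  X <- group_design(phenotypes, covariates)
  fit <- glm_group_t(X, values)
  out <- data.frame(
    unit = if (!is.null(colnames(values))) colnames(values)
           else as.character(seq_len(ncol(values))),
    beta_group = unname(fit$beta),
    t_stat = unname(fit$t),
    p_raw = unname(fit$p),
    stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  out
}

#' Benjamini-Hochberg FDR within families
#'
#' Step-up BH adjustment with monotonicity enforcement (as in
#' `p.adjust(method = "BH")`), applied independently within each family.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param families Optional grouping vector/factor of the same length; NULL
#'   treats all p-values as one family. Factor levels with no members are
#'   skipped with a warning.
#' @return Vector of q-values aligned with `p_values`.
#' @export
fdr_correct <- function(p_values, families = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(families)) {
    return(stats::p.adjust(p_values, method = "BH"))
  }
  families <- as.factor(families)
  empty <- levels(families)[tabulate(families, nlevels(families)) == 0L]
  if (length(empty) > 0L) {
    warning("skipping empty famil",
            if (length(empty) > 1L) "ies: " else "y: ",
            paste(empty, collapse = ", "))
  }
  q <- rep(NA_real_, length(p_values))
  for (lev in levels(families)) {
    idx <- which(families == lev)
    if (length(idx) > 0L) {
      q[idx] <- stats::p.adjust(p_values[idx], method = "BH")
    }
  }
  q
}

#' Annotate ROI contrasts with dual FDR families and significance tiers
#'
#' Adds whole-brain BH q-values (one family over all filtered ROIs),
#' network-wise BH q-values (one family per network label), and the
#' significance tier: `significant` for `p < alpha_primary`, `marginal` for
#' `alpha_primary <= p < alpha_marginal`, else `none`.
#'
#' @param contrasts Output of [fit_group_glm()] with ROI ids in `unit`.
#' @param atlas Filtered `parcellation_atlas` supplying network labels.
#' @param alpha_primary,alpha_marginal Tier cut-offs (defaults 0.005, 0.01).
#' @return The contrast table with `network`, `anatomy`, `q_wholebrain`,
#'   `q_network` and `significance_tier` columns.
#' @export
annotate_contrasts <- function(contrasts, atlas, alpha_primary = 0.005,
                               alpha_marginal = 0.01) {
  idx <- match(as.integer(contrasts$unit), atlas$roi_id)
  if (anyNA(idx)) {
    stop("contrast unit(s) absent from the atlas: ",
         paste(contrasts$unit[is.na(idx)], collapse = ", "))
  }
  contrasts$network <- atlas$network[idx]
  contrasts$anatomy <- atlas$anatomy[idx]
  contrasts$q_wholebrain <- fdr_correct(contrasts$p_raw)
  contrasts$q_network <- fdr_correct(contrasts$p_raw, contrasts$network)
  contrasts$significance_tier <- ifelse(
    contrasts$p_raw < alpha_primary, "significant",
    ifelse(contrasts$p_raw < alpha_marginal, "marginal", "none"))
  contrasts
}
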
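test_that("group GLM recovers a null effect when covariates explain y", {
  phen <- make_phenotypes(10, 10, seed = 2)
  y <- 2 + 0.3 * phen$age - 0.1 * phen$education +
    5 * (phen$sex == "female") + 4 * phen$mean_fd
  res <- fit_group_glm(y, phen)
  expect_equal(res$beta_group, 0, tolerance = 1e-8)
  expect_gt(res$p_raw, 0.999)
})

test_that("group GLM matches the lm() oracle on a hand-built table", {
  phen <- make_phenotypes(4, 4, seed = 3)
  set.seed(4)
  y <- rnorm(8)
  res <- fit_group_glm(y, phen)
  fit <- lm(y ~ I(group == "SCD") + age + I(sex == "female") + education +
              mean_fd, data = phen)
  sm <- summary(fit)$coefficients[2, ]
  expect_equal(res$beta_group, unname(sm["Estimate"]), tolerance = 1e-10)
  expect_equal(res$t_stat, unname(sm["t value"]), tolerance = 1e-10)
  expect_equal(res$p_raw, unname(sm["Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(attr(res, "df"), 2L)
})

test_that("group GLM is invariant to subject order and guards its design", {
  phen <- make_phenotypes(6, 6, seed = 5)
  set.seed(6)
  y <- matrix(rnorm(12 * 4), 12, 4,
              dimnames = list(phen$subject_id, paste0("u", 1:4)))
  res <- fit_group_glm(y, phen)
  shuffle <- sample(12)
  res2 <- fit_group_glm(y[shuffle, ], phen)
  expect_equal(res2, res)

  phen_bad <- phen
  phen_bad$copy_age <- phen_bad$age
  expect_error(fit_group_glm(y, phen_bad,
                             covariates = c("age", "copy_age")),
               "collinear")
  phen_small <- phen[c(1, 7:12), ]
  expect_error(fit_group_glm(y[phen_small$subject_id, ], phen_small),
               "at least 2")
})

test_that("BH correction reproduces the hand-computed step-up example", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 6)), rep(1, 6))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("family-wise FDR corrects independently within families", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.001)
  fam <- c("a", "a", "a", "a", "b")
  q <- fdr_correct(p, fam)
  expect_equal(q[1:4], rep(0.04, 4))
  expect_equal(q[5], 0.001)
  fam2 <- factor(fam, levels = c("a", "b", "ghost"))
  expect_warning(q2 <- fdr_correct(p, fam2), "ghost")
  expect_equal(q2, q)
})

test_that("contrast annotation builds tiers and dual q-value families", {
  atlas <- filter_defined_networks(synthetic_atlas())
  phen <- make_phenotypes(20, 20, seed = 9)
  set.seed(10)
  y <- matrix(rnorm(40 * 273), 40, 273,
              dimnames = list(phen$subject_id, atlas$roi_id))
  res <- annotate_contrasts(fit_group_glm(y, phen), atlas)
  expect_true(all(res$q_wholebrain >= res$p_raw))
  expect_true(all(res$q_network >= res$p_raw))
  expect_setequal(unique(res$network), setdiff(unique(atlas$network),
                                               "undefined"))
  expect_true(all(res$significance_tier[res$p_raw < 0.005] == "significant"))
  expect_true(all(res$significance_tier[res$p_raw >= 0.01] == "none"))
  # each network family is its own BH correction
  vis <- res$network == "VIS"
  expect_equal(res$q_network[vis], fdr_correct(res$p_raw[vis]))
})

test_that("partial correlation equals the residualize-then-correlate oracle", {
  set.seed(11)
  x <- rnorm(12)
  z <- rnorm(12)
  y <- 0.5 * x + 0.8 * z + rnorm(12, sd = 0.3)
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r, oracle_partial_r(x, y, z), tolerance = 1e-12)
  expect_equal(pc$df, 9L)
  # consistency of the t-based p-value
  t_ref <- pc$r * sqrt(pc$df / (1 - pc$r^2))
  expect_equal(pc$p, 2 * pt(-abs(t_ref), pc$df), tolerance = 1e-12)

  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  expect_equal(partial_correlation(x, x + 0)$r, 1)
  expect_error(partial_correlation(x[1:4], y[1:4], z[1:4]), "n > k")
  expect_error(partial_correlation(x, rep(2, 12), z), "zero residual")
})

test_that("Fisher-Z comparison of correlations follows the stated formula", {
  eq <- compare_correlations_fisher(0.4, 30, 0.4, 25)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  a <- compare_correlations_fisher(0.5, 40, 0.0, 45, k = 4)
  b <- compare_correlations_fisher(0.0, 45, 0.5, 40, k = 4)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  z_ref <- (atanh(0.5) - atanh(0)) / sqrt(1 / (40 - 3 - 4) + 1 / (45 - 3 - 4))
  expect_equal(a$z, z_ref, tolerance = 1e-12)
  expect_equal(a$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)
  expect_error(compare_correlations_fisher(1, 40, 0, 45), "< 1")
  expect_error(compare_correlations_fisher(0.2, 6, 0.1, 45, k = 4),
               "insufficient")
})

test_that("correlation grid covers all cells and supports one-sided mode", {
  phen <- make_phenotypes(20, 22, seed = 12)
  phen$MMSE <- round(pmin(pmax(rnorm(42, 28, 1.5), 0), 30), 1)
  phen$AD8 <- round(pmin(pmax(rnorm(42, 2, 1.5), 0), 8))
  set.seed(13)
  metrics <- matrix(rnorm(42 * 2), 42, 2,
                    dimnames = list(phen$subject_id,
                                    c("mean_194", "var_75")))
  grid <- correlation_grid(metrics, phen, scores = c("AD8", "MMSE"))
  expect_equal(nrow(grid), 4L)
  expect_true(all(abs(grid$r_all) <= 1))
  expect_true(all(grid$q_fdr >= grid$p_all))
  one <- correlation_grid(metrics, phen, scores = c("AD8", "MMSE"),
                          one_sided_group_diff = TRUE)
  expect_true(all(one$group_diff_p <= grid$group_diff_p + 1e-12))
})
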
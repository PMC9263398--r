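tr <- 2.5

test_that("sliding-window arithmetic discards the trailing partial window", {
  w <- make_windows(190, 50, 10)
  expect_equal(nrow(w), 15L)
  expect_equal(c(w$start[1], w$end[1]), c(1L, 50L))
  expect_equal(c(w$start[15], w$end[15]), c(141L, 190L))
  expect_equal(nrow(make_windows(50, 50, 10)), 1L)
  expect_error(make_windows(49, 50, 10), "exceeds")
  expect_error(make_windows(100, 50, 0))
})

test_that("ALFF is zero for silence, homogeneous, and exact on a sinusoid", {
  expect_equal(compute_alff(rep(0, 190), tr), 0)
  set.seed(3)
  x <- rnorm(190)
  expect_equal(compute_alff(3.7 * x, tr), 3.7 * compute_alff(x, tr),
               tolerance = 1e-12)
  # amplitude-2 sinusoid at 0.04 Hz sits exactly on bin 19 of the 190-point
  # grid; the 0.01-0.08 Hz band holds bins 5..38, so ALFF = 2/34
  t_sec <- (0:189) * tr
  expect_equal(compute_alff(2 * sin(2 * pi * 0.04 * t_sec), tr), 2 / 34,
               tolerance = 1e-10)
  expect_error(compute_alff(rnorm(10), tr, band = c(0.001, 0.002)),
               "bin spacing")
})

test_that("ALFF matches the brute-force DFT oracle on random series", {
  set.seed(17)
  for (n in c(64, 97, 190)) {
    for (rep in 1:5) {
      x <- rnorm(n)
      expect_equal(compute_alff(x, tr), oracle_alff(x, tr),
                   tolerance = 1e-10)
    }
  }
})

test_that("mALFF normalization conserves a unit masked mean", {
  expect_equal(normalize_malff(rep(5, 10)), rep(1, 10))
  expect_equal(normalize_malff(c(1, 3)), c(0.5, 1.5))
  set.seed(8)
  v <- runif(273, 0.1, 3)
  expect_equal(mean(normalize_malff(v)), 1, tolerance = 1e-12)
  mask <- 1:100
  expect_equal(mean(normalize_malff(v, mask)[mask]), 1, tolerance = 1e-12)
  expect_error(normalize_malff(rep(0, 5)), "degenerate")
})

test_that("unit-to-ROI aggregation is an unweighted group mean", {
  expect_equal(unname(aggregate_units_to_roi(c(4, 9), c(1, 2))), c(4, 9),
               ignore_attr = TRUE)
  expect_equal(unname(aggregate_units_to_roi(c(1, 2, 3), c(7, 7, 7))), 2,
               ignore_attr = TRUE)
  set.seed(12)
  v <- rnorm(200)
  map <- sample(1:20, 200, replace = TRUE)
  expect_equal(aggregate_units_to_roi(v, map),
               tapply(v, map, mean), tolerance = 1e-12,
               ignore_attr = TRUE)
  # NA units are dropped; empty ROIs reported
  out <- aggregate_units_to_roi(c(1, 2, NA_real_), c(1, NA, 2),
                                roi_ids = c(1, 2, 3))
  expect_equal(unname(out), c(1, NA, NA), ignore_attr = TRUE)
  expect_equal(attr(out, "empty_rois"), 3L)
})

test_that("mdALFF centres at 1 for stationary signals and tracks envelopes", {
  t_sec <- (0:189) * tr
  set.seed(31)
  x <- t(vapply(runif(8, 0, 2 * pi),
                function(ph) sin(2 * pi * 0.04 * t_sec + ph),
                numeric(190)))
  rownames(x) <- 1:8
  md <- compute_mdalff(x, tr)
  expect_equal(md$mdalff_mean, rep(1, 8), tolerance = 1e-6)
  expect_lt(max(md$mdalff_var), 1e-3)

  # doubling one ROI's amplitude in half the windows maximizes its variance
  x2 <- x
  x2[3, 96:190] <- 2 * x2[3, 96:190]
  md2 <- compute_mdalff(x2, tr)
  expect_equal(which.max(md2$mdalff_var), 3L)

  md1 <- compute_mdalff(x[, 1:50], tr)
  expect_equal(md1$mdalff_var, rep(0, 8))
})

test_that("mdALFF is invariant to global rescaling and self-consistent", {
  set.seed(44)
  x <- matrix(rnorm(6 * 150), 6, 150)
  rownames(x) <- c(2, 5, 9, 11, 20, 31)
  md <- compute_mdalff(x, tr, window_length = 40, window_step = 20)
  md_scaled <- compute_mdalff(100 * x, tr, window_length = 40,
                              window_step = 20)
  expect_equal(md$mdalff_mean, md_scaled$mdalff_mean, tolerance = 1e-10)
  expect_equal(md$mdalff_var, md_scaled$mdalff_var, tolerance = 1e-10)
  # window consistency: external mean/var over the windowed values
  win <- attr(md, "windowed")
  expect_equal(md$mdalff_mean, unname(colMeans(win)))
  expect_equal(md$mdalff_var, unname(apply(win, 2, var)))
})

test_that("mdALFF and dFC match a straight-line reimplementation", {
  set.seed(55)
  x <- matrix(rnorm(5 * 70), 5, 70)
  rownames(x) <- 1:5
  md <- compute_mdalff(x, tr)
  ora <- oracle_mdalff(x, tr, 50, 10)
  expect_equal(md$mdalff_mean, ora$mean, tolerance = 1e-10)
  expect_equal(md$mdalff_var, ora$var, tolerance = 1e-10)

  dfc <- compute_dfc_seed(x, 2)
  ora_d <- oracle_dfc(x, 2, 50, 10)
  expect_equal(dfc$target_roi, ora_d$targets)
  expect_equal(dfc$dfc_mean, ora_d$mean, tolerance = 1e-10)
  expect_equal(dfc$dfc_var, ora_d$var, tolerance = 1e-10)
})

test_that("metric tables reshape losslessly into subject x unit matrices", {
  tab <- expand.grid(subject_id = c("a", "b"), roi_id = c(3L, 9L),
                     stringsAsFactors = FALSE)
  tab$mdalff_mean <- c(1, 2, 3, 4)
  m <- metric_matrix(tab, "mdalff_mean")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["b", "9"], 4)
  expect_equal(m["a", "3"], 1)
})
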
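# 30-ROI sub-atlas (AUD rows incl. ROI 75, FPN rows incl. ROI 194) keeps
# the generator tests fast; the full 300-ROI atlas is exercised elsewhere.
small_atlas <- function() synthetic_atlas()[c(60:75, 185:198), ]

test_that("simulated phenotypes match the cohort structure", {
  spec <- simulation_spec(seed = 30)
  phen <- simulate_phenotypes(spec)
  expect_equal(nrow(phen), 85L)
  expect_equal(sum(phen$group == "SCD"), 40L)
  expect_equal(sum(phen$group == "NC"), 45L)
  # AD8 separates groups by construction: SCD mean near 4.03 (3 SE), NC <= 1
  expect_lt(abs(mean(phen$AD8[phen$group == "SCD"]) - 4.03),
            3 * 1.82 / sqrt(40))
  expect_true(all(phen$AD8[phen$group == "SCD"] >= 2))
  expect_true(all(phen$AD8[phen$group == "NC"] <= 1))
  expect_true(all(phen$mean_fd >= 0 & phen$mean_fd <= 0.5))
  expect_true(all(phen$age >= 50))
})

test_that("the generator is deterministic down to the written bytes", {
  spec <- simulation_spec(seed = 31)
  p1 <- simulate_phenotypes(spec)
  p2 <- simulate_phenotypes(spec)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_phenotypes(p1, f1)
  write_phenotypes(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  s1 <- simulate_timeseries(spec, p1, small_atlas())
  s2 <- simulate_timeseries(spec, p1, small_atlas())
  expect_identical(s1, s2)
})

test_that("simulated series are band-limited before noise", {
  spec <- simulation_spec(seed = 32, noise_sd = 0)
  phen <- simulate_phenotypes(spec)[1:2, ]
  series <- simulate_timeseries(spec, phen, small_atlas())
  x <- series[[1]]
  f <- (seq_len(ncol(x)) - 1) / (ncol(x) * spec$tr)
  f <- pmin(f, 1 / spec$tr - f)
  pow <- Mod(t(stats::mvfft(t(x))))^2
  frac <- sum(pow[, f >= 0.005 & f <= 0.1]) / sum(pow)
  expect_gte(frac, 0.9)
})

test_that("effect ROIs must exist in the filtered atlas", {
  spec <- simulation_spec(seed = 33,
                          effects = data.frame(roi_id = 9999,
                                               metric = "mean", d = 1))
  phen <- simulate_phenotypes(spec)
  expect_error(simulate_timeseries(spec, phen, small_atlas()),
               "not in the filtered atlas")
})

test_that("a variance effect leaves the mean metric unchanged", {
  diffs <- numeric(8)
  for (i in 1:8) {
    spec0 <- simulation_spec(seed = 300 + i)
    spec1 <- simulation_spec(seed = 300 + i,
                             effects = data.frame(roi_id = 75,
                                                  metric = "var", d = 1.2))
    phen <- simulate_phenotypes(spec0)
    md <- function(sp) {
      cohort <- cohort_dataset(small_atlas(), phen,
                               simulate_timeseries(sp, phen, small_atlas()),
                               sp$tr, "t")
      tab <- cohort_mdalff(condition_cohort(cohort))
      mean(tab$mdalff_mean[tab$roi_id == 75])
    }
    diffs[i] <- md(spec1) - md(spec0)
  }
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("clinical scores hit their targeted partial correlations", {
  covs <- function(phen) {
    cbind(phen$age, as.numeric(phen$sex == "female"), phen$education,
          phen$mean_fd)
  }
  realized <- function(rho, seed, score = "DSC") {
    spec <- simulation_spec(
      seed = seed,
      correlation_targets = data.frame(roi_id = 194, metric = "mean",
                                       score = score, rho = rho))
    cohort <- simulate_cohort(spec, atlas = small_atlas())
    md <- cohort_mdalff(condition_cohort(cohort))
    v <- metric_matrix(md, "mdalff_mean")[cohort$phenotypes$subject_id, "194"]
    partial_correlation(v, cohort$phenotypes[[score]],
                        covs(cohort$phenotypes))$r
  }
  # DSC sits mid-range, so scale clipping barely attenuates the target
  r_null <- vapply(1:10, function(i) realized(0, 400 + i), numeric(1))
  expect_lt(mean(abs(r_null)), 0.25)
  r_half <- vapply(1:10, function(i) realized(0.5, 500 + i), numeric(1))
  expect_lt(abs(mean(r_half) - 0.5), 0.1)
  r_neg <- vapply(1:10, function(i) realized(-0.29, 600 + i, "AD8"),
                  numeric(1))
  expect_gte(mean(r_neg < 0), 0.9)
  expect_error(simulation_spec(
    correlation_targets = data.frame(roi_id = 194, metric = "mean",
                                     score = "MMSE", rho = 1.2)))
})

test_that("injected mean effects are recovered in direction", {
  neg <- logical(6)
  for (i in 1:6) {
    res <- run_mdalff_contrasts(700 + i,
                                effects = data.frame(roi_id = 194,
                                                     metric = "mean",
                                                     d = -1.2),
                                atlas = small_atlas())
    row <- res$mean[res$mean$unit == "194", ]
    neg[i] <- row$beta_group < 0
  }
  expect_gte(mean(neg), 5 / 6)
})
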
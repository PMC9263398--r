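# Independent straight-line oracles used to pin the implementation.
# These deliberately share no code with the package: explicit O(N^2) DFT
# sums, lm()-based regressions, and plain loops.

# One-sided amplitude spectrum by explicit DFT summation.
oracle_dft_amp <- function(x, tr) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  amp <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    Mod(complex(real = re, imaginary = im)) / n
  }, numeric(1))
  scale <- ifelse(ks > 0 & ks < n / 2, 2, 1)
  list(freq = ks / (n * tr), amp = amp * scale)
}

oracle_alff <- function(x, tr, band = c(0.01, 0.08)) {
  sp <- oracle_dft_amp(x, tr)
  mean(sp$amp[sp$freq >= band[1] & sp$freq <= band[2]])
}

# Power-style frame displacement by explicit per-frame loop.
oracle_fd <- function(motion, radius = 50) {
  fd <- numeric(nrow(motion) - 1)
  for (i in 2:nrow(motion)) {
    d <- 0
    for (j in 1:3) d <- d + abs(motion[i, j] - motion[i - 1, j])
    for (j in 4:6) {
      d <- d + abs(motion[i, j] - motion[i - 1, j]) * pi / 180 * radius
    }
    fd[i - 1] <- d
  }
  fd
}

# Straight-line mdALFF: loops over windows, oracle DFT per unit,
# window-wise global-mean normalization, then mean / sample variance.
oracle_mdalff <- function(x, tr, len, step, band = c(0.01, 0.08)) {
  n_t <- ncol(x)
  n_w <- floor((n_t - len) / step) + 1
  vals <- matrix(NA_real_, n_w, nrow(x))
  for (w in seq_len(n_w)) {
    idx <- ((w - 1) * step + 1):((w - 1) * step + len)
    alff <- apply(x[, idx, drop = FALSE], 1, oracle_alff, tr = tr,
                  band = band)
    vals[w, ] <- alff / mean(alff)
  }
  list(mean = colMeans(vals),
       var = if (n_w > 1) apply(vals, 2, var) else rep(0, nrow(x)))
}

# Straight-line seed dFC: loop over windows and targets with cor().
oracle_dfc <- function(x, seed_row, len, step, clip = 1 - 1e-7) {
  n_t <- ncol(x)
  n_w <- floor((n_t - len) / step) + 1
  targets <- setdiff(seq_len(nrow(x)), seed_row)
  z <- matrix(NA_real_, n_w, length(targets))
  for (w in seq_len(n_w)) {
    idx <- ((w - 1) * step + 1):((w - 1) * step + len)
    for (j in seq_along(targets)) {
      r <- cor(x[seed_row, idx], x[targets[j], idx])
      z[w, j] <- atanh(min(max(r, -clip), clip))
    }
  }
  list(targets = targets, mean = colMeans(z),
       var = if (n_w > 1) apply(z, 2, var) else rep(0, length(targets)))
}

# Residualize-then-correlate partial correlation via lm().
oracle_partial_r <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  cor(rx, ry)
}

# A small phenotype table with balanced groups for GLM tests.
make_phenotypes <- function(n_scd, n_nc, seed = 1) {
  set.seed(seed)
  n <- n_scd + n_nc
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = c(rep("SCD", n_scd), rep("NC", n_nc)),
    age = round(rnorm(n, 65, 5), 1),
    sex = sample(c("female", "male"), n, replace = TRUE),
    education = round(rnorm(n, 10, 4), 1),
    mean_fd = round(abs(rnorm(n, 0.15, 0.05)), 4),
    stringsAsFactors = FALSE)
}

# Full generator -> conditioning -> mdALFF -> group-contrast run, shared by
# the calibration and recovery tests. Returns the two contrast tables.
run_mdalff_contrasts <- function(seed, effects = NULL,
                                 atlas = synthetic_atlas()) {
  spec <- simulation_spec(seed = seed, effects = effects)
  phen <- simulate_phenotypes(spec)
  series <- simulate_timeseries(spec, phen, atlas)
  cohort <- cohort_dataset(atlas, phen, series, spec$tr, "test")
  md <- cohort_mdalff(condition_cohort(cohort))
  list(mean = fit_group_glm(metric_matrix(md, "mdalff_mean"), phen),
       var = fit_group_glm(metric_matrix(md, "mdalff_var"), phen),
       phenotypes = phen, mdalff = md)
}
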
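#' Specification of a synthetic resting-state cohort
#'
#' Collects the generator's study conditions: group sizes (default 40
#' subjective-cognitive-decline vs 45 normal-control subjects), acquisition
#' geometry (200 timepoints at TR = 2.5 s before trimming), the effect
#' tables, and the noise/dynamics parameters. Defaults mirror the cohort
#' structure the analysis targets.
#'
#' Amplitude dynamics use a slow sinusoidal envelope
#' `a(t) = a0 * (1 + m * sin(2*pi*f_slow*t + phi))` on top of band-limited
#' signal; group effects on the mean metric shift the baseline amplitude
#' `a0` by `d` between-subject standard deviations, effects on the variance
#' metric shift the modulation depth `m` likewise, so mean and variance
#' effects are controlled separately.
#'
#' @param n_scd,n_nc Group sizes.
#' @param n_timepoints Timepoints per series before trimming (default 200).
#' @param tr Sampling interval in seconds (default 2.5).
#' @param effects Data frame `roi_id`, `metric` (`"mean"`/`"var"`), `d`
#'   (signed standardized effect, SCD minus NC).
#' @param dfc_effects Data frame `seed`, `target`, `metric`, `d` for
#'   coupling effects.
#' @param correlation_targets Data frame `roi_id`, `metric`, `score`, `rho`
#'   of target partial correlations for [generate_clinical_scores()].
#' @param noise_sd Additive white-noise SD relative to unit-variance signal.
#' @param amp_sd Between-subject SD of the baseline amplitude `a0` (mean 1).
#' @param mod_depth,mod_sd Mean and between-subject SD of the envelope
#'   modulation depth `m`.
#' @param f_slow Envelope frequency in Hz.
#' @param network_loading Loading of each ROI on its network's shared
#'   factor.
#' @param signal_band Band (Hz) of the band-limited signal and factors.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_scd = 40L, n_nc = 45L, n_timepoints = 200L,
                            tr = 2.5, effects = NULL, dfc_effects = NULL,
                            correlation_targets = NULL, noise_sd = 0.2,
                            amp_sd = 0.2, mod_depth = 0.3, mod_sd = 0.1,
                            f_slow = 0.004, network_loading = 0.5,
                            signal_band = c(0.01, 0.08), seed = 1L) {
  stopifnot(n_scd > 0L, n_nc > 0L, n_timepoints > 0L, tr > 0,
            noise_sd >= 0, seed == as.integer(seed))
  if (!is.null(effects)) {
    stopifnot(all(c("roi_id", "metric", "d") %in% names(effects)),
              all(effects$metric %in% c("mean", "var")),
              all(is.finite(effects$d)))
  }
  if (!is.null(correlation_targets)) {
    stopifnot(all(c("roi_id", "metric", "score", "rho") %in%
                    names(correlation_targets)),
              all(abs(correlation_targets$rho) < 1),
              !any(duplicated(correlation_targets$score)))
  }
  structure(list(
    n_scd = as.integer(n_scd), n_nc = as.integer(n_nc),
    n_timepoints = as.integer(n_timepoints), tr = tr,
    effects = effects, dfc_effects = dfc_effects,
    correlation_targets = correlation_targets,
    noise_sd = noise_sd, amp_sd = amp_sd, mod_depth = mod_depth,
    mod_sd = mod_sd, f_slow = f_slow, network_loading = network_loading,
    signal_band = signal_band, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Per-group clinical score distributions (mean_scd, sd_scd, mean_nc, sd_nc)
# used to dress simulated subjects; ranges come from clinical_score_ranges().
score_distributions <- function() {
  list(
    MMSE = c(28.13, 1.45, 28.38, 1.81), MoCA = c(23.85, 3.29, 26.31, 3.52),
    DSC = c(53.18, 17.31, 60.31, 22.83),
    DST_forward = c(12.18, 2.34, 12.42, 2.24),
    DST_backward = c(6.21, 3.12, 7.36, 2.64), LNS = c(8.26, 2.55, 9.76, 3.19),
    CF_animal = c(16.05, 4.81, 19.18, 4.86),
    CF_fruit = c(13.26, 3.39, 14.11, 3.02),
    CF_color = c(12.21, 4.09, 14.33, 4.58),
    CF_city = c(18.23, 5.81, 20.02, 5.64), FMT = c(34.03, 4.06, 35.89, 4.80),
    HADS_A = c(5.40, 3.21, 2.84, 2.84), HADS_D = c(5.45, 3.36, 2.80, 3.29))
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a subject phenotype table
#'
#' Ages are Normal(65.5, 5.7) truncated at 50 years, education Normal(10.1,
#' 4.2) truncated at 0, sex Bernoulli(female 0.58), mean frame displacement
#' |Normal(0.15, 0.07)| capped at 0.5 mm. AD8 separates the groups by
#' construction (SCD: Normal(4.03, 1.82) clipped to [2, 8] and rounded; NC:
#' Normal(0.18, 0.39) clipped to [0, 1] and rounded); the remaining scores
#' draw from their per-group distributions clipped to the printed scale
#' ranges. Covariates are independent of group by default.
#'
#' @param spec A [simulation_spec()].
#' @return Phenotype data frame with `n_scd + n_nc` rows.
#' @export
simulate_phenotypes <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_scd + spec$n_nc
  group <- c(rep("SCD", spec$n_scd), rep("NC", spec$n_nc))
  phen <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group,
    age = round(rnorm_trunc(n, 65.5, 5.7, 50), 1),
    sex = ifelse(stats::runif(n) < 0.58, "female", "male"),
    education = round(rnorm_trunc(n, 10.1, 4.2, 0), 1),
    mean_fd = round(pmin(abs(stats::rnorm(n, 0.15, 0.07)), 0.5), 4),
    stringsAsFactors = FALSE)
  is_scd <- group == "SCD"
  ad8 <- numeric(n)
  ad8[is_scd] <- round(pmin(pmax(stats::rnorm(sum(is_scd), 4.03, 1.82), 2), 8))
  ad8[!is_scd] <- round(pmin(pmax(stats::rnorm(sum(!is_scd), 0.18, 0.39),
                                  0), 1))
  phen$AD8 <- ad8
  ranges <- clinical_score_ranges()
  for (sc in names(score_distributions())) {
    par <- score_distributions()[[sc]]
    v <- numeric(n)
    v[is_scd] <- stats::rnorm(sum(is_scd), par[1], par[2])
    v[!is_scd] <- stats::rnorm(sum(!is_scd), par[3], par[4])
    r <- ranges[[sc]]
    phen[[sc]] <- round(pmin(pmax(v, r[1]), r[2]), 2)
  }
  validate_phenotypes(phen)
}

# Band-limited Gaussian noise: white noise restricted to `band` on the DFT
# grid, each column rescaled to unit variance.
band_limited_noise <- function(n_timepoints, tr, band, n_cols) {
  w <- matrix(stats::rnorm(n_timepoints * n_cols), n_timepoints, n_cols)
  f <- (seq_len(n_timepoints) - 1L) / (n_timepoints * tr)
  f_alias <- pmin(f, 1 / tr - f)
  keep <- f_alias >= band[1] & f_alias <= band[2]
  y <- stats::mvfft(w)
  y[!keep, ] <- 0
  out <- Re(stats::mvfft(y, inverse = TRUE)) / n_timepoints
  sds <- sqrt(colMeans(out^2))
  sweep(out, 2L, pmax(sds, .Machine$double.eps), "/")
}

#' Simulate ROI time series for a cohort
#'
#' For subject i and ROI r the signal is
#' `x(t) = a0 * (1 + m * sin(2*pi*f_slow*t + phi)) * s(t) + L %*% g(t) +
#' noise`, where `s` (per ROI) and the network factors `g` are independent
#' band-limited unit-variance processes, `a0 ~ 1 + Normal(0, amp_sd)` and
#' `m ~ mod_depth + Normal(0, mod_sd)` vary between subjects, and loadings
#' `L` follow the atlas network blocks. Group effects are injected as
#' described in [simulation_spec()]; coupling (`dfc_effects`) effects add a
#' shared extra factor to the seed/target pair whose loading is constant for
#' NC but gated on and off by a slow square wave for SCD (variance effects)
#' or rescaled between groups (mean effects).
#'
#' @param spec A [simulation_spec()].
#' @param phenotypes Output of [simulate_phenotypes()].
#' @param atlas Parcellation atlas; the `"undefined"` network is excluded
#'   before simulation.
#' @return Named list (by subject) of ROI x timepoints matrices; attribute
#'   `"tr"` carries the sampling interval.
#' @export
simulate_timeseries <- function(spec, phenotypes,
                                atlas = synthetic_atlas()) {
  set.seed(spec$seed + 1L)
  atlas <- filter_defined_networks(atlas)
  n_roi <- nrow(atlas)
  if (n_roi == 0L) stop("no defined-network ROIs to simulate")
  for (tab in list(spec$effects,
                   if (!is.null(spec$dfc_effects))
                     data.frame(roi_id = c(spec$dfc_effects$seed,
                                           spec$dfc_effects$target)))) {
    if (!is.null(tab) && !all(tab$roi_id %in% atlas$roi_id)) {
      stop("effect roi_id not in the filtered atlas: ",
           paste(setdiff(tab$roi_id, atlas$roi_id), collapse = ", "))
    }
  }
  networks <- factor(atlas$network)
  n_net <- nlevels(networks)
  L <- matrix(0, n_roi, n_net)
  L[cbind(seq_len(n_roi), as.integer(networks))] <- spec$network_loading
  t_sec <- (seq_len(spec$n_timepoints) - 1L) * spec$tr
  n_dfc <- if (is.null(spec$dfc_effects)) 0L else nrow(spec$dfc_effects)
  roi_index <- stats::setNames(seq_len(n_roi), atlas$roi_id)

  series <- lapply(seq_len(nrow(phenotypes)), function(i) {
    grp <- phenotypes$group[i]
    s <- band_limited_noise(spec$n_timepoints, spec$tr, spec$signal_band,
                            n_roi)
    g <- band_limited_noise(spec$n_timepoints, spec$tr, spec$signal_band,
                            n_net)
    a0 <- pmax(1 + stats::rnorm(n_roi, 0, spec$amp_sd), 0.2)
    m <- pmin(pmax(spec$mod_depth + stats::rnorm(n_roi, 0, spec$mod_sd), 0),
              0.8)
    if (!is.null(spec$effects) && grp == "SCD") {
      for (j in seq_len(nrow(spec$effects))) {
        r <- roi_index[[as.character(spec$effects$roi_id[j])]]
        if (spec$effects$metric[j] == "mean") {
          a0[r] <- max(a0[r] + spec$effects$d[j] * spec$amp_sd, 0.2)
        } else {
          m[r] <- min(max(m[r] + spec$effects$d[j] * spec$mod_sd, 0), 0.8)
        }
      }
    }
    phi <- stats::runif(n_roi, 0, 2 * pi)
    env <- 1 + sweep(sin(outer(2 * pi * spec$f_slow * t_sec, phi, "+")),
                     2L, m, "*")
    x <- sweep(s * env, 2L, a0, "*") + g %*% t(L)
    if (n_dfc > 0L) {
      for (j in seq_len(n_dfc)) {
        eff <- spec$dfc_effects[j, ]
        e <- band_limited_noise(spec$n_timepoints, spec$tr,
                                spec$signal_band, 1L)[, 1L]
        lambda <- rep(0.4, spec$n_timepoints)
        if (grp == "SCD") {
          if (eff$metric == "var") {
            # slow on/off gating of the shared coupling for SCD subjects
            depth <- min(0.9, 0.3 * abs(eff$d))
            gate <- sign(sin(2 * pi * 0.008 * t_sec +
                               stats::runif(1, 0, 2 * pi)))
            lambda <- lambda * (1 + depth * gate)
          } else {
            lambda <- lambda * (1 + 0.3 * eff$d)
          }
        }
        pair <- roi_index[as.character(c(eff$seed, eff$target))]
        x[, pair] <- x[, pair] + (lambda * e)
      }
    }
    x <- x + spec$noise_sd *
      matrix(stats::rnorm(spec$n_timepoints * n_roi), spec$n_timepoints)
    out <- t(x)
    rownames(out) <- as.character(atlas$roi_id)
    out
  })
  names(series) <- phenotypes$subject_id
  attr(series, "tr") <- spec$tr
  series
}

#' Dress simulated phenotypes with metric-linked clinical scores
#'
#' For each correlation target `(roi_id, metric, score, rho)` the score is
#' rebuilt as `rho * z + sqrt(1 - rho^2) * noise`, where `z` is the
#' covariate-residualized, standardized mdALFF metric at that ROI, then
#' linearly rescaled to the score's pooled mean/SD and clipped to its scale
#' range — so the covariate-adjusted partial correlation targets `rho`
#' (clipping attenuates extreme targets; intended for `|rho| <= 0.6`).
#' Scores without a target keep their sampled values.
#'
#' @param spec A [simulation_spec()] with `correlation_targets`.
#' @param phenotypes Phenotype table.
#' @param mdalff Long mdALFF table from [cohort_mdalff()] for the same
#'   subjects.
#' @return Updated phenotype table.
#' @export
generate_clinical_scores <- function(spec, phenotypes, mdalff) {
  targets <- spec$correlation_targets
  if (is.null(targets) || nrow(targets) == 0L) return(phenotypes)
  set.seed(spec$seed + 2L)
  Z <- covariate_matrix(phenotypes, c("age", "sex", "education", "mean_fd"))
  qr_z <- qr(cbind(1, Z))
  dists <- score_distributions()
  ranges <- clinical_score_ranges()
  for (j in seq_len(nrow(targets))) {
    tg <- targets[j, ]
    if (abs(tg$rho) >= 1) stop("|rho| must be < 1")
    col <- paste0("mdalff_", tg$metric)
    sub <- mdalff[mdalff$roi_id == tg$roi_id, c("subject_id", col)]
    v <- sub[[col]][match(phenotypes$subject_id, sub$subject_id)]
    if (anyNA(v)) stop("mdALFF missing for target ROI ", tg$roi_id)
    z <- qr.resid(qr_z, v)
    z <- (z - mean(z)) / stats::sd(z)
    raw <- tg$rho * z + sqrt(1 - tg$rho^2) * stats::rnorm(length(z))
    par <- dists[[tg$score]]
    if (is.null(par)) {           # AD8 has no pooled Gaussian entry
      mu <- 2.0; sdv <- 2.2
    } else {
      w <- spec$n_scd / (spec$n_scd + spec$n_nc)
      mu <- w * par[1] + (1 - w) * par[3]
      sdv <- sqrt(w * par[2]^2 + (1 - w) * par[4]^2)
    }
    r <- ranges[[tg$score]]
    phenotypes[[tg$score]] <-
      round(pmin(pmax(mu + sdv * (raw - mean(raw)) / stats::sd(raw),
                      r[1]), r[2]), 2)
  }
  phenotypes
}

#' Simulate a full cohort dataset
#'
#' Runs [simulate_phenotypes()], [simulate_timeseries()] and — when
#' correlation targets are present — conditions the series, computes mdALFF
#' and rebuilds the targeted clinical scores with
#' [generate_clinical_scores()]. The result is a `cohort_dataset` ready for
#' [run_pipeline()] or direct analysis; identical specs give identical
#' cohorts.
#'
#' @param spec A [simulation_spec()].
#' @param atlas Parcellation atlas (default [synthetic_atlas()]).
#' @param trim_volumes,bandpass,alff_band,window_length,window_step
#'   Conditioning and windowing parameters used only for the
#'   correlation-target mdALFF pass.
#' @return A `cohort_dataset` with the raw (unconditioned) series.
#' @export
simulate_cohort <- function(spec, atlas = synthetic_atlas(),
                            trim_volumes = 10L, bandpass = c(0.01, 0.1),
                            alff_band = c(0.01, 0.08), window_length = 50L,
                            window_step = 10L) {
  phen <- simulate_phenotypes(spec)
  series <- simulate_timeseries(spec, phen, atlas)
  cohort <- structure(
    list(atlas = atlas, phenotypes = phen, series = series, tr = spec$tr,
         config_hash = hash_object(unclass(spec))),
    class = "cohort_dataset")
  if (!is.null(spec$correlation_targets) &&
      nrow(spec$correlation_targets) > 0L) {
    cond <- condition_cohort(cohort, trim_volumes = trim_volumes,
                             bandpass = bandpass)
    md <- cohort_mdalff(cond, window_length = window_length,
                        window_step = window_step, band = alff_band)
    cohort$phenotypes <- generate_clinical_scores(spec, phen, md)
  }
  validate_cohort(cohort)
}

#' Condition every series of a cohort
#'
#' @param cohort A `cohort_dataset`.
#' @param ... Passed to [condition_series()].
#' @return The cohort with conditioned series.
#' @export
condition_cohort <- function(cohort, ...) {
  cohort$series <- lapply(cohort$series, condition_series, tr = cohort$tr,
                          ...)
  cohort
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}
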
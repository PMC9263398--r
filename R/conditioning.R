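#' Delete initial volumes of a time series
#'
#' Scanner signal needs a few repetitions to reach steady state; the first
#' `n` timepoints (default 10) are discarded before any further processing.
#'
#' @param x Units x timepoints numeric matrix.
#' @param n Number of leading timepoints to drop.
#' @return Matrix with `ncol(x) - n` timepoints.
#' @export
delete_initial_volumes <- function(x, n = 10L) {
  x <- as_series_matrix(x)
  if (n < 0) stop("n must be >= 0")
  if (n >= ncol(x)) {
    stop("cannot delete ", n, " volumes from a series of ", ncol(x),
         " timepoints")
  }
  if (n == 0L) return(x)
  x[, -seq_len(n), drop = FALSE]
}

as_series_matrix <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Flag a subject for motion exclusion
#'
#' Summarizes a per-volume rigid-body motion table (three translations in mm,
#' three rotations in degrees) into maximum translation, maximum rotation and
#' mean frame displacement (FD), and applies the exclusion rule: excluded if
#' max translation > 2 mm, max rotation > 2 degrees, or mean FD > 0.5 mm.
#'
#' FD follows the Power convention: the sum of absolute backward differences
#' of the six parameters, with rotations converted to arc length on a
#' 50 mm sphere.
#'
#' @param motion Timepoints x 6 matrix: columns 1-3 translations (mm),
#'   columns 4-6 rotations (degrees).
#' @param subject_id Optional subject label carried into the summary.
#' @param limits List of thresholds `translation_mm`, `rotation_deg`,
#'   `mean_fd_mm`.
#' @param radius Sphere radius (mm) for the rotation-to-displacement
#'   conversion.
#' @return One-row data frame with `subject_id`, `max_translation`,
#'   `max_rotation`, `mean_fd`, `excluded`.
#' @export
flag_motion_exclusion <- function(motion, subject_id = NA_character_,
                                  limits = list(translation_mm = 2,
                                                rotation_deg = 2,
                                                mean_fd_mm = 0.5),
                                  radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns")
  if (nrow(motion) < 2L) {
    stop("frame displacement undefined for fewer than 2 volumes")
  }
  trans <- motion[, 1:3, drop = FALSE]
  rot_deg <- motion[, 4:6, drop = FALSE]
  rot_mm <- rot_deg * pi / 180 * radius
  fd <- rowSums(abs(diff(cbind(trans, rot_mm))))
  out <- data.frame(
    subject_id = subject_id,
    max_translation = max(abs(trans)),
    max_rotation = max(abs(rot_deg)),
    mean_fd = mean(fd),
    stringsAsFactors = FALSE)
  out$excluded <- out$max_translation > limits$translation_mm ||
    out$max_rotation > limits$rotation_deg ||
    out$mean_fd > limits$mean_fd_mm
  out
}

#' Remove a least-squares linear trend from each unit
#'
#' @param x Units x timepoints matrix (>= 3 timepoints).
#' @return Matrix of residuals after removing each row's intercept and slope.
#' @export
linear_detrend <- function(x) {
  x <- as_series_matrix(x)
  n <- ncol(x)
  if (n < 3L) stop("need at least 3 timepoints to detrend")
  tc <- seq_len(n) - (n + 1) / 2
  xm <- rowMeans(x)
  beta <- (x %*% tc) / sum(tc^2)
  x - xm - tcrossprod(drop(beta), tc)
}

#' Regress nuisance confounds out of each unit's time series
#'
#' Projects every row of `x` onto the orthogonal complement of
#' `[intercept, confounds]`. With no confounds this reduces to mean
#' centering.
#'
#' @param x Units x timepoints matrix.
#' @param confounds Timepoints x k numeric matrix (or NULL for intercept
#'   only). Must be of full column rank jointly with the intercept.
#' @return Residual matrix, same shape as `x`.
#' @export
regress_nuisance <- function(x, confounds = NULL) {
  x <- as_series_matrix(x)
  n <- ncol(x)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n) {
      stop("confounds must have one row per timepoint")
    }
    if (is.null(colnames(confounds))) {
      colnames(confounds) <- paste0("confound", seq_len(ncol(confounds)))
    }
    X <- cbind(X, confounds)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("confound matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  t(qr.resid(qr_x, t(x)))
}

#' Zero-phase band-pass filter on the DFT grid
#'
#' Ideal (rectangular) frequency-domain filter: the series is transformed
#' with the FFT, bins whose frequency falls outside `[low, high]` are zeroed
#' (including DC), and the series is inverse transformed. The filter is a
#' linear projection — exactly zero phase, exactly idempotent — which is the
#' convention of the dynamic-connectivity toolboxes this pipeline mirrors.
#'
#' @param x Units x timepoints matrix.
#' @param tr Sampling interval in seconds.
#' @param low,high Pass band edges in Hz; `0 < low < high < 1/(2*tr)`.
#' @return Filtered matrix, same shape; row means are removed (DC is outside
#'   any positive pass band).
#' @export
bandpass_filter <- function(x, tr, low = 0.01, high = 0.1) {
  x <- as_series_matrix(x)
  nyquist <- 1 / (2 * tr)
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  if (high >= nyquist) {
    stop("high edge ", high, " Hz is at or above the Nyquist frequency ",
         signif(nyquist, 4), " Hz")
  }
  n <- ncol(x)
  f <- (seq_len(n) - 1L) / (n * tr)
  f_alias <- pmin(f, 1 / tr - f)       # fold the mirrored half of the grid
  keep <- f_alias >= low & f_alias <= high
  y <- stats::mvfft(t(x))
  y[!keep, ] <- 0
  t(Re(stats::mvfft(y, inverse = TRUE)) / n)
}

#' Condition a subject's ROI time series
#'
#' Applies the deterministic conditioning chain in its fixed order: delete
#' initial volumes, linear detrend, nuisance regression, band-pass filter.
#' Every step is linear and leaves the sampling interval and unit count
#' unchanged.
#'
#' @param x Units x timepoints matrix.
#' @param tr Sampling interval (s).
#' @param trim_volumes Leading volumes to drop (default 10).
#' @param bandpass Pass band in Hz (default `c(0.01, 0.1)`).
#' @param confounds Optional timepoints-after-trim x k confound matrix.
#' @return Conditioned matrix.
#' @export
condition_series <- function(x, tr, trim_volumes = 10L,
                             bandpass = c(0.01, 0.1), confounds = NULL) {
  x <- delete_initial_volumes(x, trim_volumes)
  x <- linear_detrend(x)
  x <- regress_nuisance(x, confounds)
  bandpass_filter(x, tr, bandpass[1], bandpass[2])
}

#' Conditioning provenance report
#'
#' Records what the conditioning chain did to a cohort: volumes deleted,
#' filter band, nuisance columns, steps that act on raw volumes and are
#' therefore not applied at ROI grain (despiking, slice timing), and the
#' per-subject motion summaries.
#'
#' @param n_volumes_deleted Count of trimmed volumes.
#' @param filter_band Length-2 Hz vector.
#' @param nuisance_columns Character vector of confound names (may be empty).
#' @param motion_summaries Data frame of [flag_motion_exclusion()] rows, or
#'   NULL.
#' @return A `conditioning_report` list.
#' @export
conditioning_report <- function(n_volumes_deleted, filter_band,
                                nuisance_columns = character(),
                                motion_summaries = NULL) {
  stopifnot(n_volumes_deleted >= 0, filter_band[1] < filter_band[2])
  structure(list(
    n_volumes_deleted = as.integer(n_volumes_deleted),
    filter_band = as.numeric(filter_band),
    nuisance_columns = nuisance_columns,
    despiking = "not applied",
    slice_timing = "not applied",
    motion_summaries = motion_summaries
  ), class = "conditioning_report")
}
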
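#' Sliding-window index ranges
#'
#' Windows of `length` timepoints advanced by `step`; the trailing partial
#' window is discarded, so `n = floor((T - length)/step) + 1` windows are
#' produced. Indices are 1-based and inclusive; window `w` covers
#' `[(w-1)*step + 1, (w-1)*step + length]`, the 1-based equivalent of the
#' 0-based half-open range `[w*step, w*step + length)`.
#'
#' @param n_timepoints Series length `T`.
#' @param length Window length in timepoints (TR units), default 50.
#' @param step Window step in timepoints, default 10.
#' @return Data frame with columns `window`, `start`, `end`.
#' @examples
#' make_windows(190, 50, 10) # 15 windows: [1,50] ... [141,190]
#' @export
make_windows <- function(n_timepoints, length = 50L, step = 10L) {
  if (step < 1L) stop("step must be >= 1")
  if (length > n_timepoints) {
    stop("window length ", length, " exceeds the series length ",
         n_timepoints)
  }
  n <- (n_timepoints - length) %/% step + 1L
  start <- (seq_len(n) - 1L) * step + 1L
  data.frame(window = seq_len(n), start = start, end = start + length - 1L)
}

# One-sided amplitude spectrum of each column of a timepoints x units matrix.
# Scaling is amplitude-calibrated: a pure sinusoid of amplitude A lying on
# bin k (0 < k < N/2) contributes A at that bin; DC and Nyquist carry 1/N.
amplitude_spectrum <- function(y, tr) {
  n <- nrow(y)
  k <- 0:(n %/% 2L)
  amp <- Mod(stats::mvfft(y)[k + 1L, , drop = FALSE]) / n
  interior <- k > 0L & k < n / 2
  amp[interior, ] <- 2 * amp[interior, , drop = FALSE]
  list(amp = amp, freq = k / (n * tr))
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' ALFF of a series is the mean, over the DFT bins whose frequency lies in
#' `band` (endpoints inclusive), of the square root of the power spectrum.
#' The spectrum is one-sided and amplitude-calibrated (no taper, FFT length =
#' series length), so a pure in-band sinusoid of amplitude A yields A at its
#' bin; any fixed scaling cancels in the mALFF normalization.
#'
#' @param x Numeric vector, or units x timepoints matrix (one ALFF per row).
#' @param tr Sampling interval in seconds.
#' @param band Frequency band in Hz, default `c(0.01, 0.08)`.
#' @return Scalar (vector input) or named numeric vector (matrix input).
#' @export
compute_alff <- function(x, tr, band = c(0.01, 0.08)) {
  vec <- is.null(dim(x))
  x <- as_series_matrix(x)
  if (any(!is.finite(x))) stop("series contains non-finite values")
  sp <- amplitude_spectrum(t(x), tr)
  inband <- which(sp$freq >= band[1] & sp$freq <= band[2])
  if (length(inband) == 0L) {
    stop("no DFT bin falls in the band [", band[1], ", ", band[2],
         "] Hz; bin spacing is ", signif(1 / (ncol(x) * tr), 6),
         " Hz over [0, ", signif(max(sp$freq), 6), "] Hz")
  }
  out <- colMeans(sp$amp[inband, , drop = FALSE])
  if (vec) unname(out) else stats::setNames(out, rownames(x))
}

#' Normalize ALFF to mean ALFF (mALFF)
#'
#' Divides each unit's ALFF by the global mean ALFF over the included units,
#' so that the masked mean of mALFF equals 1.
#'
#' @param alff Per-unit nonnegative ALFF values.
#' @param mask Logical or integer index of units entering the global mean
#'   (default: all).
#' @return Per-unit mALFF (dimensionless).
#' @export
normalize_malff <- function(alff, mask = NULL) {
  if (is.null(mask)) mask <- seq_along(alff)
  gm <- mean(alff[mask])
  if (!is.finite(gm) || gm <= 0) {
    stop("degenerate global mean ALFF (", gm, ")")
  }
  alff / gm
}

#' Average unit-level values into ROI-level values
#'
#' Unweighted arithmetic mean of all units mapped to each ROI. Units mapped
#' to `NA` ("outside" the atlas) are dropped; ROIs receiving no units come
#' back as `NA` and are reported via the `"empty_rois"` attribute.
#'
#' @param values Per-unit numeric vector.
#' @param unit_to_roi Integer ROI id per unit (`NA` to drop the unit).
#' @param roi_ids ROI frame to report on (default: the ids present in
#'   `unit_to_roi`).
#' @return Named numeric vector over `roi_ids`.
#' @export
aggregate_units_to_roi <- function(values, unit_to_roi, roi_ids = NULL) {
  keep <- !is.na(unit_to_roi)
  g <- factor(unit_to_roi[keep],
              levels = if (is.null(roi_ids)) sort(unique(unit_to_roi[keep]))
                       else roi_ids)
  out <- as.numeric(tapply(values[keep], g, mean)) # empty levels give NA
  counts <- tabulate(g, nbins = nlevels(g))
  names(out) <- levels(g)
  attr(out, "empty_rois") <- as.integer(levels(g)[counts == 0L])
  out
}

#' Sliding-window dynamic ALFF (mdALFF) per ROI
#'
#' For each window the per-unit ALFF is computed on the windowed segment,
#' normalized to mALFF by that window's global mean over the included units
#' (the default; set `window_norm = FALSE` to divide every window by the
#' full-series global mean instead), and averaged into ROI values. The mean
#' and the sample variance (denominator `n_windows - 1`) of the windowed
#' ROI-wise mALFF are returned as `mdalff_mean` and `mdalff_var`; a single
#' window yields zero variance.
#'
#' @param x Conditioned units x timepoints matrix. If `unit_to_roi` is NULL,
#'   units are taken to be ROIs (identified by rownames, else 1..n).
#' @param tr Sampling interval (s).
#' @param window_length,window_step Sliding-window parameters in TR units.
#' @param band ALFF band in Hz.
#' @param unit_to_roi Optional integer ROI id per unit (`NA` drops a unit).
#' @param window_norm Normalize mALFF within each window (default TRUE).
#' @return Data frame with `roi_id`, `mdalff_mean`, `mdalff_var`; the window
#'   table is attached as attribute `"windows"` and the per-window ROI-wise
#'   mALFF matrix as attribute `"windowed"`.
#' @export
compute_mdalff <- function(x, tr, window_length = 50L, window_step = 10L,
                           band = c(0.01, 0.08), unit_to_roi = NULL,
                           window_norm = TRUE) {
  x <- as_series_matrix(x)
  if (is.null(unit_to_roi)) {
    unit_to_roi <- if (!is.null(rownames(x))) as.integer(rownames(x))
                   else seq_len(nrow(x))
  }
  mask <- which(!is.na(unit_to_roi))
  windows <- make_windows(ncol(x), window_length, window_step)
  roi_ids <- sort(unique(unit_to_roi[mask]))
  if (!window_norm) {
    global_alff <- tryCatch(compute_alff(x, tr, band),
                            error = function(e) stop("full series: ",
                                                     conditionMessage(e)))
    gm <- mean(global_alff[mask])
    if (!is.finite(gm) || gm <= 0) stop("degenerate global mean ALFF")
  }
  per_window <- matrix(NA_real_, nrow(windows), length(roi_ids),
                       dimnames = list(NULL, roi_ids))
  for (w in seq_len(nrow(windows))) {
    seg <- x[, windows$start[w]:windows$end[w], drop = FALSE]
    alff <- tryCatch(compute_alff(seg, tr, band),
                     error = function(e) stop("window ", w, ": ",
                                              conditionMessage(e)))
    malff <- if (window_norm) normalize_malff(alff, mask) else alff / gm
    per_window[w, ] <- aggregate_units_to_roi(malff, unit_to_roi, roi_ids)
  }
  n_w <- nrow(windows)
  res <- data.frame(
    roi_id = roi_ids,
    mdalff_mean = colMeans(per_window),
    mdalff_var = if (n_w > 1L) apply(per_window, 2L, stats::var) else
      rep(0, length(roi_ids)))
  rownames(res) <- NULL
  attr(res, "windows") <- windows
  attr(res, "windowed") <- per_window
  res
}

#' mdALFF for every subject of a cohort
#'
#' @param cohort A `cohort_dataset` (series already conditioned).
#' @param ... Passed to [compute_mdalff()].
#' @return Long data frame `subject_id`, `roi_id`, `mdalff_mean`,
#'   `mdalff_var`.
#' @export
cohort_mdalff <- function(cohort, ...) {
  out <- lapply(names(cohort$series), function(sid) {
    tab <- compute_mdalff(cohort$series[[sid]], cohort$tr, ...)
    cbind(subject_id = sid, tab)
  })
  do.call(rbind, out)
}

#' Reshape a long metric table into a subjects x units matrix
#'
#' @param table Long data frame with `subject_id`, a unit column and the
#'   metric column.
#' @param metric Metric column name (e.g. `"mdalff_mean"`).
#' @param unit Unit column name (default `"roi_id"`).
#' @return Subjects x units numeric matrix with dimnames.
#' @export
metric_matrix <- function(table, metric, unit = "roi_id") {
  subjects <- unique(table$subject_id)
  units <- unique(table[[unit]])
  m <- matrix(NA_real_, length(subjects), length(units),
              dimnames = list(subjects, units))
  m[cbind(match(table$subject_id, subjects),
          match(table[[unit]], units))] <- table[[metric]]
  m
}
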
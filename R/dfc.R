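#' Seed-based sliding-window dynamic functional connectivity
#'
#' For each window the Pearson correlation between the seed ROI's series and
#' every target ROI's series is computed on the window samples, clipped to
#' `|r| <= 1 - 1e-7`, and Fisher-Z transformed (`atanh`). The mean and sample
#' variance of the windowed Z values are returned as `dfc_mean` and
#' `dfc_var`. The seed-to-seed entry is excluded.
#'
#' @param x Conditioned ROI x timepoints matrix with ROI-id rownames.
#' @param seed_roi ROI id of the seed.
#' @param targets ROI ids of the targets (default: all non-seed ROIs).
#' @param window_length,window_step Sliding-window parameters in TR units.
#' @param clip Correlation clipping bound before `atanh`.
#' @return Data frame `seed_roi`, `target_roi`, `dfc_mean`, `dfc_var`
#'   (Fisher-Z and squared Fisher-Z units); windowed Z matrix attached as
#'   attribute `"windowed"`.
#' @export
compute_dfc_seed <- function(x, seed_roi, targets = NULL,
                             window_length = 50L, window_step = 10L,
                             clip = 1 - 1e-7) {
  x <- as_series_matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  seed_key <- as.character(seed_roi)
  if (!seed_key %in% ids) stop("seed ROI ", seed_roi, " not in series")
  if (is.null(targets)) targets <- ids[ids != seed_key]
  targets <- as.character(targets)
  targets <- targets[targets != seed_key]
  miss <- setdiff(targets, ids)
  if (length(miss) > 0L) {
    stop("target ROI(s) not in series: ", paste(miss, collapse = ", "))
  }
  windows <- make_windows(ncol(x), window_length, window_step)
  z <- matrix(NA_real_, nrow(windows), length(targets),
              dimnames = list(NULL, targets))
  for (w in seq_len(nrow(windows))) {
    seg <- x[, windows$start[w]:windows$end[w], drop = FALSE]
    sds <- apply(seg[c(seed_key, targets), , drop = FALSE], 1L, stats::sd)
    if (any(sds == 0)) {
      stop("zero-variance segment in window ", w, " for ROI(s): ",
           paste(names(sds)[sds == 0], collapse = ", "))
    }
    r <- drop(stats::cor(seg[seed_key, ], t(seg[targets, , drop = FALSE])))
    z[w, ] <- atanh(pmin(pmax(r, -clip), clip))
  }
  n_w <- nrow(windows)
  res <- data.frame(
    seed_roi = as.integer(seed_key),
    target_roi = as.integer(targets),
    dfc_mean = colMeans(z),
    dfc_var = if (n_w > 1L) apply(z, 2L, stats::var) else
      rep(0, length(targets)))
  rownames(res) <- NULL
  attr(res, "windows") <- windows
  attr(res, "windowed") <- z
  res
}

#' Seed dFC tables for every subject of a cohort
#'
#' @param cohort A `cohort_dataset` (series already conditioned).
#' @param seeds Integer vector of seed ROI ids.
#' @param ... Passed to [compute_dfc_seed()].
#' @return Long data frame `subject_id`, `seed_roi`, `target_roi`,
#'   `dfc_mean`, `dfc_var`.
#' @export
cohort_dfc <- function(cohort, seeds, ...) {
  out <- lapply(names(cohort$series), function(sid) {
    per_seed <- lapply(seeds, function(s) {
      compute_dfc_seed(cohort$series[[sid]], s, ...)
    })
    cbind(subject_id = sid, do.call(rbind, per_seed))
  })
  do.call(rbind, out)
}

#' Edge frame of a long dFC table
#'
#' @param dfc_table Output of [cohort_dfc()].
#' @return Data frame of unique `seed_roi`/`target_roi` pairs with an
#'   `edge` label column.
#' @export
dfc_edges <- function(dfc_table) {
  e <- unique(dfc_table[c("seed_roi", "target_roi")])
  e$edge <- paste(e$seed_roi, e$target_roi, sep = "-")
  rownames(e) <- NULL
  e
}
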
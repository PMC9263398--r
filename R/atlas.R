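#' Parcellation atlas I/O and filtering
#'
#' A parcellation atlas is a data frame with one row per region of interest
#' (ROI) and columns `roi_id` (integer, 1-based, unique), `network`
#' (resting-state network label, possibly `"undefined"`), `anatomy` (free-text
#' anatomical label), `hemisphere` (`"left"`, `"right"` or `"midline"`) and
#' MNI millimetre coordinates `x`, `y`, `z`. It is the frame shared by every
#' per-ROI map the package produces.
#'
#' @param path Path to a tab-separated atlas file with exactly the columns
#'   named above.
#' @return A `parcellation_atlas` data frame ordered by `roi_id`.
#' @seealso [filter_defined_networks()], [synthetic_atlas()]
#' @export
load_atlas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (nrow(df) == 0L) stop("no ROIs in atlas file: ", path)
  unknown <- setdiff(names(df), atlas_columns)
  if (length(unknown) > 0L) {
    stop("unknown atlas column(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(atlas_columns, names(df))
  if (length(missing) > 0L) {
    stop("missing atlas column(s): ", paste(missing, collapse = ", "))
  }
  df$roi_id <- as.integer(df$roi_id)
  as_atlas(df[atlas_columns])
}

atlas_columns <- c("roi_id", "network", "anatomy", "hemisphere", "x", "y", "z")

as_atlas <- function(df) {
  dup <- unique(df$roi_id[duplicated(df$roi_id)])
  if (length(dup) > 0L) {
    stop("duplicated roi_id: ", paste(dup, collapse = ", "))
  }
  bad_hemi <- setdiff(unique(df$hemisphere), c("left", "right", "midline"))
  if (length(bad_hemi) > 0L) {
    stop("invalid hemisphere value(s): ", paste(bad_hemi, collapse = ", "))
  }
  df <- df[order(df$roi_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("parcellation_atlas", "data.frame")
  df
}

#' Write a parcellation atlas to a TSV file
#'
#' Field-for-field inverse of [load_atlas()].
#'
#' @param atlas A `parcellation_atlas` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas)[atlas_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop ROIs of the undefined network
#'
#' Removes every ROI whose network label equals `undefined_label`, leaving the
#' analysis set (for the default 300-ROI synthetic atlas: 273 ROIs in 13
#' defined networks). The number of removed ROIs is recorded in the
#' `"n_removed"` attribute. Idempotent.
#'
#' @param atlas A `parcellation_atlas`.
#' @param undefined_label Network label marking unassigned ROIs.
#' @return The filtered atlas, with attribute `n_removed`.
#' @export
filter_defined_networks <- function(atlas, undefined_label = "undefined") {
  drop <- atlas$network == undefined_label
  if (all(drop)) {
    warning("all ROIs belong to the '", undefined_label,
            "' network; returning an empty atlas")
  }
  out <- atlas[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parcellation_atlas", "data.frame")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Synthetic 300-ROI parcellation atlas
#'
#' Deterministic stand-in for a published whole-brain parcellation: 273 ROIs
#' spread over 13 named resting-state networks plus 27 ROIs labelled
#' `"undefined"`, with pseudo-MNI coordinates. ROI ids are laid out in
#' contiguous network blocks so that a handful of ids used throughout the
#' package examples carry fixed network/anatomy labels (e.g. ROI 194 is the
#' right inferior parietal lobule of the frontoparietal network).
#'
#' @param n_undefined Number of trailing `"undefined"` ROIs (default 27).
#' @return A `parcellation_atlas` with `273 + n_undefined` rows.
#' @export
synthetic_atlas <- function(n_undefined = 27L) {
  blocks <- c(DMN = 55L, AUD = 20L, SMd = 25L, SMl = 8L, DAN = 15L,
              MTL = 10L, VIS = 35L, FPN = 35L, VAN = 15L, SAL = 10L,
              PMN = 5L, REW = 15L, CON = 25L)
  network <- c(rep(names(blocks), times = blocks),
               rep("undefined", n_undefined))
  n <- length(network)
  roi_id <- seq_len(n)
  hemisphere <- ifelse(roi_id %% 2L == 1L, "left", "right")
  # deterministic pseudo-MNI grid, sign of x follows hemisphere
  x <- ifelse(hemisphere == "left", -1, 1) * (18 + (roi_id * 7L) %% 50L)
  y <- -90 + (roi_id * 11L) %% 160L
  z <- -40 + (roi_id * 13L) %% 110L
  anatomy <- paste(hemisphere, "area", roi_id)
  named <- list(
    `75`  = c("left", "STG"),   # superior temporal gyrus, AUD
    `159` = c("right", "CAL"),  # calcarine cortex, VIS
    `164` = c("right", "LING"), # lingual gyrus, VIS
    `194` = c("right", "IPL"),  # inferior parietal lobule, FPN
    `211` = c("right", "MTG"),  # middle temporal gyrus, VAN
    `260` = c("right", "PAL")   # pallidum, CON
  )
  for (id in names(named)) {
    i <- as.integer(id)
    hemisphere[i] <- named[[id]][1L]
    anatomy[i] <- paste(named[[id]][1L], named[[id]][2L])
    x[i] <- abs(x[i]) * ifelse(named[[id]][1L] == "left", -1, 1)
  }
  as_atlas(data.frame(roi_id = roi_id, network = network, anatomy = anatomy,
                      hemisphere = hemisphere, x = x, y = y, z = z,
                      stringsAsFactors = FALSE))
}
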
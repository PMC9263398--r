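#' Clinical score names used by the phenotype table
#'
#' Column names of the neuropsychological and affective scores carried by a
#' subject phenotype table: AD8 (subjective cognitive complaints), MMSE and
#' MoCA (global cognition), DSC (digit symbol coding), forward/backward digit
#' span, LNS (letter-number sequencing), category fluency (animal, fruit,
#' color, city), FMT (facial memory test), and the HADS anxiety/depression
#' subscales.
#'
#' @format Character vector of length 14.
#' @export
clinical_score_names <- c(
  "AD8", "MMSE", "MoCA", "DSC", "DST_forward", "DST_backward", "LNS",
  "CF_animal", "CF_fruit", "CF_color", "CF_city", "FMT", "HADS_A", "HADS_D"
)

phenotype_base_columns <- c("subject_id", "group", "age", "sex",
                            "education", "mean_fd")

#' Read a subject phenotype table
#'
#' @param path CSV file with header columns `subject_id`, `group` (`SCD` or
#'   `NC`), `age` (years), `sex` (`female`/`male`), `education` (years),
#'   `mean_fd` (mm), plus any of the [clinical_score_names] columns. Missing
#'   values are empty cells.
#' @return A validated phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype data frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

validate_phenotypes <- function(df) {
  missing <- setdiff(phenotype_base_columns, names(df))
  if (length(missing) > 0L) {
    stop("missing phenotype column(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(df$group) || any(!df$group %in% c("SCD", "NC"))) {
    stop("phenotype 'group' must be 'SCD' or 'NC' and non-missing")
  }
  if (any(duplicated(df$subject_id))) {
    stop("duplicated subject_id in phenotype table")
  }
  if (any(df$mean_fd < 0, na.rm = TRUE)) stop("mean_fd must be >= 0")
  ranges <- clinical_score_ranges()
  for (sc in intersect(clinical_score_names, names(df))) {
    v <- df[[sc]]
    r <- ranges[[sc]]
    if (any(v < r[1] | v > r[2], na.rm = TRUE)) {
      stop("clinical score '", sc, "' outside its range [",
           r[1], ", ", r[2], "]")
    }
  }
  df
}

clinical_score_ranges <- function() {
  list(AD8 = c(0, 8), MMSE = c(0, 30), MoCA = c(0, 30), DSC = c(0, 135),
       DST_forward = c(0, 16), DST_backward = c(0, 14), LNS = c(0, 21),
       CF_animal = c(0, 60), CF_fruit = c(0, 60), CF_color = c(0, 60),
       CF_city = c(0, 60), FMT = c(0, 50), HADS_A = c(0, 21),
       HADS_D = c(0, 21))
}

#' Read and write per-subject ROI time-series matrices
#'
#' Series files are plain tab-separated matrices, one row per unit (ROI), with
#' a leading `roi_id` column and one column per timepoint. The sampling
#' interval is not stored in the file; it is supplied by the caller (usually
#' from the run configuration).
#'
#' @param path File path.
#' @return `read_series`: a numeric units x timepoints matrix with `roi_id`
#'   rownames.
#' @export
read_series <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  if (!"roi_id" %in% names(df)) stop("series file lacks a roi_id column: ", path)
  m <- as.matrix(df[setdiff(names(df), "roi_id")])
  rownames(m) <- as.character(as.integer(df$roi_id))
  dimnames(m)[[2]] <- NULL
  m
}

#' @rdname read_series
#' @param x Units x timepoints matrix with ROI-id rownames.
#' @export
write_series <- function(x, path) {
  df <- data.frame(roi_id = rownames(x), x, check.names = FALSE)
  names(df) <- c("roi_id", paste0("t", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble and validate a cohort dataset
#'
#' Binds an atlas, a phenotype table and one ROI time-series matrix per
#' subject into a single validated object. Every phenotype row must have a
#' series file named `<subject_id>.tsv` in `series_dir`; all series must share
#' the atlas ROI frame and the same number of timepoints, and contain no
#' missing values.
#'
#' @param atlas_path Atlas TSV (see [load_atlas()]).
#' @param phenotype_path Phenotype CSV (see [read_phenotypes()]).
#' @param series_dir Directory of per-subject series TSV files.
#' @param tr Sampling interval in seconds.
#' @return A `cohort_dataset` list with elements `atlas`, `phenotypes`,
#'   `series` (named list of matrices), `tr` and `config_hash`.
#' @export
load_cohort <- function(atlas_path, phenotype_path, series_dir, tr = 2.5) {
  atlas <- load_atlas(atlas_path)
  phen <- read_phenotypes(phenotype_path)
  paths <- file.path(series_dir, paste0(phen$subject_id, ".tsv"))
  absent <- phen$subject_id[!file.exists(paths)]
  if (length(absent) > 0L) {
    stop("missing series file for subject(s): ",
         paste(absent, collapse = ", "))
  }
  series <- lapply(paths, read_series)
  names(series) <- phen$subject_id
  hash <- unname(tools::md5sum(c(atlas_path, phenotype_path, paths)))
  cohort <- structure(
    list(atlas = atlas, phenotypes = phen, series = series, tr = tr,
         config_hash = paste(hash, collapse = "")),
    class = "cohort_dataset")
  validate_cohort(cohort)
}

#' @rdname load_cohort
#' @param cohort A `cohort_dataset` to validate.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (cohort$tr <= 0) stop("tr must be positive")
  phen <- cohort$phenotypes
  if (!setequal(names(cohort$series), phen$subject_id)) {
    stop("series/phenotype subject mismatch: ",
         paste(c(setdiff(phen$subject_id, names(cohort$series)),
                 setdiff(names(cohort$series), phen$subject_id)),
               collapse = ", "))
  }
  tp <- vapply(cohort$series, ncol, integer(1))
  if (length(unique(tp)) > 1L) {
    stop("timepoint count differs across subjects: ",
         paste(unique(tp), collapse = ", "))
  }
  bad <- names(cohort$series)[vapply(cohort$series,
                                     function(m) any(!is.finite(m)),
                                     logical(1))]
  if (length(bad) > 0L) {
    stop("non-finite values in series for subject(s): ",
         paste(bad, collapse = ", "))
  }
  roi_frames <- vapply(cohort$series,
                       function(m) paste(rownames(m), collapse = ","),
                       character(1))
  if (length(unique(roi_frames)) > 1L) {
    stop("series do not share a common ROI frame")
  }
  cohort
}

#' Construct a cohort dataset from in-memory components
#'
#' Convenience constructor for analyses that build their inputs in code
#' (e.g. from the synthetic generator) rather than from files.
#'
#' @param atlas A `parcellation_atlas`.
#' @param phenotypes Phenotype data frame.
#' @param series Named list (by `subject_id`) of units x timepoints
#'   matrices.
#' @param tr Sampling interval in seconds.
#' @param config_hash Optional provenance string.
#' @return A validated `cohort_dataset`.
#' @export
cohort_dataset <- function(atlas, phenotypes, series, tr,
                           config_hash = "") {
  validate_cohort(structure(
    list(atlas = atlas, phenotypes = phenotypes, series = series, tr = tr,
         config_hash = config_hash),
    class = "cohort_dataset"))
}

#' Enrollment bookkeeping
#'
#' Applies a vector of screening exclusion counts to a screened sample size
#' and returns the analyzable count, erroring if the arithmetic goes negative.
#'
#' @param n_screened Number of screened subjects.
#' @param exclusions Named integer vector of exclusion counts.
#' @return Integer number of analyzable subjects.
#' @examples
#' apply_enrollment_exclusions(136, c(mdd = 29, mci = 3, lesion = 9, motion = 10))
#' @export
apply_enrollment_exclusions <- function(n_screened, exclusions) {
  stopifnot(n_screened >= 0, all(exclusions >= 0))
  n <- n_screened - sum(exclusions)
  if (n < 0) stop("exclusions exceed the screened count")
  as.integer(n)
}
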
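make_toy_inputs <- function(dir, n_subjects = 3L, n_roi = 5L, n_t = 12L) {
  atlas <- as.data.frame(synthetic_atlas())[seq_len(n_roi), ]
  atlas_path <- file.path(dir, "atlas.tsv")
  utils::write.table(atlas, atlas_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phen <- make_phenotypes(ceiling(n_subjects / 2),
                          floor(n_subjects / 2))[seq_len(n_subjects), ]
  phen_path <- file.path(dir, "phen.csv")
  write_phenotypes(phen, phen_path)
  series_dir <- file.path(dir, "series")
  dir.create(series_dir)
  set.seed(99)
  for (sid in phen$subject_id) {
    m <- matrix(rnorm(n_roi * n_t), n_roi, n_t)
    rownames(m) <- as.character(atlas$roi_id)
    write_series(m, file.path(series_dir, paste0(sid, ".tsv")))
  }
  list(atlas = atlas_path, phen = phen_path, series = series_dir,
       subjects = phen$subject_id)
}

test_that("phenotype and series files round-trip", {
  dir <- withr::local_tempdir()
  phen <- make_phenotypes(4, 4)
  phen$AD8 <- c(rep(4, 4), rep(0, 4))
  path <- file.path(dir, "p.csv")
  write_phenotypes(phen, path)
  back <- read_phenotypes(path)
  expect_equal(back$subject_id, phen$subject_id)
  expect_equal(back$mean_fd, phen$mean_fd)
  expect_equal(back$AD8, phen$AD8)

  m <- matrix(rnorm(20), 4, 5, dimnames = list(c(3, 7, 9, 12), NULL))
  spath <- file.path(dir, "s.tsv")
  write_series(m, spath)
  expect_equal(read_series(spath), m, tolerance = 1e-12)
})

test_that("phenotype validation enforces group and score ranges", {
  phen <- make_phenotypes(3, 3)
  bad <- phen
  bad$group[2] <- "XX"
  expect_error(validate_phenotypes(bad), "group")
  bad <- phen
  bad$AD8 <- c(2, 3, 9, 0, 0, 1) # 9 is outside [0, 8]
  expect_error(validate_phenotypes(bad), "AD8")
  bad <- phen
  bad$mean_fd[1] <- -0.1
  expect_error(validate_phenotypes(bad), "mean_fd")
})

test_that("load_cohort assembles and validates a cohort", {
  dir <- withr::local_tempdir()
  inp <- make_toy_inputs(dir)
  cohort <- load_cohort(inp$atlas, inp$phen, inp$series)
  expect_s3_class(cohort, "cohort_dataset")
  expect_length(cohort$series, 3L)
  expect_equal(names(cohort$series), inp$subjects)
})

test_that("load_cohort reports missing subjects, NaN and ragged series", {
  dir <- withr::local_tempdir()
  inp <- make_toy_inputs(dir)
  missing_sid <- inp$subjects[2]
  file.remove(file.path(inp$series, paste0(missing_sid, ".tsv")))
  expect_error(load_cohort(inp$atlas, inp$phen, inp$series), missing_sid)

  dir2 <- withr::local_tempdir()
  inp2 <- make_toy_inputs(dir2)
  bad <- read_series(file.path(inp2$series, paste0(inp2$subjects[1], ".tsv")))
  bad[1, 1] <- NaN
  write_series(bad, file.path(inp2$series, paste0(inp2$subjects[1], ".tsv")))
  expect_error(load_cohort(inp2$atlas, inp2$phen, inp2$series),
               "non-finite")

  dir3 <- withr::local_tempdir()
  inp3 <- make_toy_inputs(dir3)
  short <- read_series(file.path(inp3$series,
                                 paste0(inp3$subjects[1], ".tsv")))
  write_series(short[, 1:6], file.path(inp3$series,
                                       paste0(inp3$subjects[1], ".tsv")))
  expect_error(load_cohort(inp3$atlas, inp3$phen, inp3$series),
               "timepoint")
})

test_that("cohort validation accepts the generator's default output", {
  cohort <- simulate_cohort(simulation_spec(seed = 11))
  expect_s3_class(validate_cohort(cohort), "cohort_dataset")
  expect_length(cohort$series, 85L)
  expect_equal(nrow(cohort$series[[1]]), 273L)
  expect_equal(ncol(cohort$series[[1]]), 200L)
})

test_that("enrollment exclusion arithmetic is checked", {
  expect_equal(apply_enrollment_exclusions(10, c(a = 2, b = 3)), 5L)
  expect_error(apply_enrollment_exclusions(4, c(a = 5)), "exceed")
  expect_error(apply_enrollment_exclusions(4, c(a = -1)))
})
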
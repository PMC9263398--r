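#' Default pipeline configuration
#'
#' All analysis thresholds default to the pipeline's canonical values: trim
#' 10 volumes, band-pass 0.01-0.1 Hz, ALFF band 0.01-0.08 Hz, window 50 TRs
#' advanced by 10, primary significance p < 0.005 and marginal p < 0.01,
#' FDR q < 0.05, NBS with 1000 permutations at family-wise alpha 0.05.
#'
#' @param out_dir Run directory for all stage outputs.
#' @return Config list; pass to [run_pipeline()] directly or after editing,
#'   or serialize to YAML for the command-line wrapper.
#' @export
default_config <- function(out_dir = "dynfc-run") {
  list(
    out_dir = out_dir,
    seed = 1L,
    tr = 2.5,
    trim_volumes = 10L,
    bandpass = c(0.01, 0.1),
    alff_band = c(0.01, 0.08),
    window = list(length_tr = 50L, step_tr = 10L),
    window_norm = TRUE,
    motion_limits = list(translation_mm = 2, rotation_deg = 2,
                         mean_fd_mm = 0.5),
    stats = list(alpha_primary = 0.005, alpha_marginal = 0.01,
                 fdr_q = 0.05),
    nbs = list(n_perm = 1000L, alpha = 0.05, primary_p = 0.005),
    seed_rois = NULL,
    simulate = NULL,
    inputs = NULL
  )
}

#' Load a pipeline configuration
#'
#' @param config A config list, or the path of a YAML file whose keys
#'   override [default_config()].
#' @return Completed config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

run_paths <- function(config) {
  d <- config$out_dir
  list(dir = d,
       atlas = file.path(d, "atlas.tsv"),
       phenotypes = file.path(d, "phenotypes.csv"),
       series_dir = file.path(d, "series"),
       conditioned_dir = file.path(d, "conditioned"),
       conditioning = file.path(d, "conditioning.json"),
       mdalff = file.path(d, "mdalff.tsv"),
       contrasts_mdalff = file.path(d, "contrasts_mdalff.tsv"),
       seeds = file.path(d, "seeds.json"),
       dfc = file.path(d, "dfc.tsv"),
       contrasts_dfc = file.path(d, "contrasts_dfc.tsv"),
       nbs = file.path(d, "nbs.json"),
       correlations = file.path(d, "correlations.tsv"),
       report = file.path(d, "report.md"),
       manifest = file.path(d, "manifest.json"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from files in the run directory and writes
#' its outputs back there, so stages can be rerun independently (including
#' from the command-line wrapper). [run_pipeline()] chains them in fixed
#' order.
#'
#' @param config Completed config list (see [load_config()]).
#' @return Invisibly, a small list of row counts for the manifest.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  p <- run_paths(config)
  dir.create(p$series_dir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$simulate
  if (is.null(sim_args)) sim_args <- list()
  if (is.null(sim_args$seed)) sim_args$seed <- config$seed
  spec <- do.call(simulation_spec, sim_args)
  cohort <- simulate_cohort(
    spec, trim_volumes = config$trim_volumes, bandpass = config$bandpass,
    alff_band = config$alff_band,
    window_length = config$window$length_tr,
    window_step = config$window$step_tr)
  write_atlas(cohort$atlas, p$atlas)
  write_phenotypes(cohort$phenotypes, p$phenotypes)
  for (sid in names(cohort$series)) {
    write_series(cohort$series[[sid]],
                 file.path(p$series_dir, paste0(sid, ".tsv")))
  }
  invisible(list(subjects = length(cohort$series),
                 rois = nrow(cohort$atlas)))
}

read_run_cohort <- function(config, conditioned = FALSE) {
  p <- run_paths(config)
  load_cohort(p$atlas, p$phenotypes,
              if (conditioned) p$conditioned_dir else p$series_dir,
              tr = config$tr)
}

#' @rdname pipeline_stages
#' @export
stage_condition <- function(config) {
  p <- run_paths(config)
  cohort <- read_run_cohort(config)
  dir.create(p$conditioned_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$series)) {
    cond <- condition_series(cohort$series[[sid]], cohort$tr,
                             trim_volumes = config$trim_volumes,
                             bandpass = config$bandpass)
    write_series(cond, file.path(p$conditioned_dir, paste0(sid, ".tsv")))
  }
  rep <- conditioning_report(config$trim_volumes, config$bandpass)
  jsonlite::write_json(unclass(rep), p$conditioning, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(subjects = length(cohort$series)))
}

#' @rdname pipeline_stages
#' @export
stage_mdalff <- function(config) {
  p <- run_paths(config)
  cohort <- read_run_cohort(config, conditioned = TRUE)
  tab <- cohort_mdalff(cohort,
                       window_length = config$window$length_tr,
                       window_step = config$window$step_tr,
                       band = config$alff_band,
                       window_norm = config$window_norm)
  write_tsv(tab, p$mdalff)
  invisible(list(rows = nrow(tab)))
}

#' @rdname pipeline_stages
#' @export
stage_contrasts <- function(config) {
  p <- run_paths(config)
  tab <- read_tsv(p$mdalff)
  phen <- read_phenotypes(p$phenotypes)
  atlas <- filter_defined_networks(load_atlas(p$atlas))
  out <- lapply(c("mean", "var"), function(metric) {
    m <- metric_matrix(tab, paste0("mdalff_", metric))
    res <- fit_group_glm(m, phen)
    res <- annotate_contrasts(res, atlas,
                              alpha_primary = config$stats$alpha_primary,
                              alpha_marginal = config$stats$alpha_marginal)
    cbind(metric = paste0("mdalff_", metric), res)
  })
  out <- do.call(rbind, out)
  write_tsv(out, p$contrasts_mdalff)
  invisible(list(rows = nrow(out)))
}

select_seeds <- function(config) {
  if (!is.null(config$seed_rois)) return(as.integer(config$seed_rois))
  p <- run_paths(config)
  ct <- read_tsv(p$contrasts_mdalff)
  sort(unique(as.integer(ct$unit[ct$significance_tier == "significant"])))
}

#' @rdname pipeline_stages
#' @export
stage_dfc <- function(config) {
  p <- run_paths(config)
  seeds <- select_seeds(config)
  jsonlite::write_json(list(seeds = seeds), p$seeds, auto_unbox = FALSE,
                       digits = NA)
  if (length(seeds) == 0L) {
    write_tsv(data.frame(subject_id = character(), seed_roi = integer(),
                         target_roi = integer(), dfc_mean = numeric(),
                         dfc_var = numeric()), p$dfc)
    return(invisible(list(seeds = 0L, rows = 0L)))
  }
  cohort <- read_run_cohort(config, conditioned = TRUE)
  tab <- cohort_dfc(cohort, seeds,
                    window_length = config$window$length_tr,
                    window_step = config$window$step_tr)
  write_tsv(tab, p$dfc)
  invisible(list(seeds = length(seeds), rows = nrow(tab)))
}

#' @rdname pipeline_stages
#' @export
stage_dfc_stats <- function(config) {
  p <- run_paths(config)
  tab <- read_tsv(p$dfc)
  phen <- read_phenotypes(p$phenotypes)
  if (nrow(tab) == 0L) {
    write_tsv(data.frame(metric = character(), unit = character(),
                         beta_group = numeric(), t_stat = numeric(),
                         p_raw = numeric(), q_wholebrain = numeric(),
                         significance_tier = character()),
              p$contrasts_dfc)
    jsonlite::write_json(list(note = "no seeds; NBS not run"), p$nbs,
                         auto_unbox = TRUE)
    return(invisible(list(rows = 0L)))
  }
  tab$edge <- paste(tab$seed_roi, tab$target_roi, sep = "-")
  edges <- dfc_edges(tab)
  nbs_out <- list(seed = config$seed)
  ct <- lapply(c("dfc_mean", "dfc_var"), function(metric) {
    m <- metric_matrix(tab, metric, unit = "edge")
    res <- fit_group_glm(m, phen)
    res$q_wholebrain <- fdr_correct(res$p_raw)
    res$significance_tier <- ifelse(
      res$p_raw < config$stats$alpha_primary, "significant",
      ifelse(res$p_raw < config$stats$alpha_marginal, "marginal", "none"))
    nbs_res <- nbs_test(
      m, data.frame(node1 = edges$seed_roi, node2 = edges$target_roi),
      phen, n_perm = config$nbs$n_perm, primary_p = config$nbs$primary_p,
      seed = config$seed)
    nbs_out[[metric]] <<- list(
      component_size = nbs_res$component_size,
      component_edges = lapply(nbs_res$components,
                               function(i) edges$edge[i]),
      p_fwe = nbs_res$p_fwe,
      n_permutations = nbs_res$n_permutations,
      primary_threshold = nbs_res$primary_threshold,
      significant = any(nbs_res$p_fwe < config$nbs$alpha))
    cbind(metric = metric, res)
  })
  ct <- do.call(rbind, ct)
  write_tsv(ct, p$contrasts_dfc)
  jsonlite::write_json(nbs_out, p$nbs, auto_unbox = TRUE, digits = NA)
  invisible(list(rows = nrow(ct)))
}

#' @rdname pipeline_stages
#' @export
stage_correlations <- function(config) {
  p <- run_paths(config)
  seeds <- select_seeds(config)
  phen <- read_phenotypes(p$phenotypes)
  if (length(seeds) == 0L) {
    write_tsv(data.frame(metric = character(), score = character(),
                         r_all = numeric(), q_fdr = numeric()),
              p$correlations)
    return(invisible(list(rows = 0L)))
  }
  md <- read_tsv(p$mdalff)
  md <- md[md$roi_id %in% seeds, ]
  mats <- lapply(c("mean", "var"), function(metric) {
    m <- metric_matrix(md, paste0("mdalff_", metric))
    colnames(m) <- paste0(metric, "_", colnames(m))
    m
  })
  metrics <- do.call(cbind, mats)
  grid <- correlation_grid(metrics, phen, fdr_q = config$stats$fdr_q)
  write_tsv(grid, p$correlations)
  invisible(list(rows = nrow(grid)))
}

#' Run the full dynamic-connectivity pipeline
#'
#' Executes the stages in fixed order — simulate (when configured),
#' condition, mdALFF, group contrasts, seed selection, seed dFC, dFC
#' statistics (edge contrasts + NBS), clinical correlations, report — and
#' writes a reproducibility manifest with content hashes of every output.
#' Rerunning a completed run directory with an unchanged config is a no-op.
#'
#' @param config Config list or YAML path (see [load_config()]). The run
#'   must either configure `simulate` or point `inputs` at `atlas`,
#'   `phenotypes` and `series_dir` paths to copy in.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- load_config(config)
  p <- run_paths(config)
  cfg_hash <- hash_object(config)
  if (file.exists(p$manifest)) {
    old <- jsonlite::read_json(p$manifest)
    if (identical(old$config_hash, cfg_hash) &&
        all(vapply(names(old$outputs), function(f) {
          file.exists(file.path(p$dir, f)) &&
            unname(tools::md5sum(file.path(p$dir, f))) == old$outputs[[f]]
        }, logical(1)))) {
      message("run directory is up to date; nothing to do")
      return(invisible(old))
    }
  }
  dir.create(p$dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  counts <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(config), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    counts[[name]] <<- res
  }
  if (!is.null(config$simulate)) {
    stage("simulate", stage_simulate)
  } else if (!is.null(config$inputs)) {
    stage("ingest", function(cfg) {
      file.copy(cfg$inputs$atlas, p$atlas, overwrite = TRUE)
      file.copy(cfg$inputs$phenotypes, p$phenotypes, overwrite = TRUE)
      dir.create(p$series_dir, showWarnings = FALSE)
      file.copy(list.files(cfg$inputs$series_dir, full.names = TRUE),
                p$series_dir, overwrite = TRUE)
      invisible(list(files = length(list.files(p$series_dir))))
    })
  } else {
    stop("config must provide either 'simulate' or 'inputs'")
  }
  stage("condition", stage_condition)
  stage("mdalff", stage_mdalff)
  stage("contrasts", stage_contrasts)
  stage("dfc", stage_dfc)
  stage("dfc_stats", stage_dfc_stats)
  stage("correlations", stage_correlations)
  stage("report", write_report)
  outputs <- c("atlas.tsv", "phenotypes.csv", "conditioning.json",
               "mdalff.tsv", "contrasts_mdalff.tsv", "seeds.json",
               "dfc.tsv", "contrasts_dfc.tsv", "nbs.json",
               "correlations.tsv", "report.md")
  outputs <- outputs[file.exists(file.path(p$dir, outputs))]
  manifest <- list(
    package = "dynfc",
    version = as.character(utils::packageVersion("dynfc")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = cfg_hash,
    config = config,
    stage_counts = counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(p$dir, outputs))), outputs)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
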
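#' Render the run report
#'
#' Writes a markdown summary of a completed (or partially completed) run
#' directory: a demographic group comparison (Welch t-tests for continuous
#' variables, chi-square for sex), the significant and marginal ROI lists
#' with their network and anatomical annotation, the NBS outcome, and the
#' clinical correlation grid with FDR flags.
#'
#' @param config Config list or YAML path (see [load_config()]); the run
#'   directory must already contain the upstream tables.
#' @return Invisibly, a list with the report path.
#' @export
write_report <- function(config) {
  config <- load_config(config)
  p <- run_paths(config)
  need <- c(p$phenotypes, p$contrasts_mdalff)
  absent <- need[!file.exists(need)]
  if (length(absent) > 0L) {
    stop("missing upstream table(s): ", paste(absent, collapse = ", "))
  }
  phen <- read_phenotypes(p$phenotypes)
  ct <- read_tsv(p$contrasts_mdalff)
  lines <- c("# Dynamic connectivity run report", "")

  lines <- c(lines, "## Cohort", "",
             sprintf("%d subjects: %d SCD, %d NC.",
                     nrow(phen), sum(phen$group == "SCD"),
                     sum(phen$group == "NC")), "",
             "## Group comparison of demographics and scores", "",
             "| variable | SCD mean (sd) | NC mean (sd) | test | p |",
             "|---|---|---|---|---|")
  scd <- phen[phen$group == "SCD", ]
  nc <- phen[phen$group == "NC", ]
  cont <- c("age", "education", "mean_fd",
            intersect(clinical_score_names, names(phen)))
  for (v in cont) {
    tt <- stats::t.test(scd[[v]], nc[[v]])
    lines <- c(lines, sprintf(
      "| %s | %.2f (%.2f) | %.2f (%.2f) | Welch t | %.3g |",
      v, mean(scd[[v]]), stats::sd(scd[[v]]), mean(nc[[v]]),
      stats::sd(nc[[v]]), tt$p.value))
  }
  sex_tab <- table(phen$group, phen$sex)
  sex_p <- tryCatch(stats::chisq.test(sex_tab)$p.value,
                    warning = function(w)
                      suppressWarnings(stats::chisq.test(sex_tab)$p.value))
  lines <- c(lines, sprintf(
    "| sex (female) | %d/%d | %d/%d | chi-square | %.3g |",
    sum(scd$sex == "female"), nrow(scd), sum(nc$sex == "female"), nrow(nc),
    sex_p), "")

  lines <- c(lines, "## ROI group differences (mdALFF)", "")
  for (tier in c("significant", "marginal")) {
    sel <- ct[ct$significance_tier == tier, ]
    lines <- c(lines, sprintf("### %s ROIs (%s)", tools::toTitleCase(tier),
                              if (tier == "significant") "p < 0.005"
                              else "0.005 <= p < 0.01"), "")
    if (nrow(sel) == 0L) {
      lines <- c(lines,
                 if (tier == "significant") "No significant ROIs."
                 else "No marginal ROIs.", "")
    } else {
      lines <- c(lines,
                 "| metric | ROI | network | anatomy | beta | t | p | q(brain) | q(network) |",
                 "|---|---|---|---|---|---|---|---|---|")
      for (i in seq_len(nrow(sel))) {
        lines <- c(lines, sprintf(
          "| %s | %s | %s | %s | %.3g | %.2f | %.3g | %.3g | %.3g |",
          sel$metric[i], sel$unit[i], sel$network[i], sel$anatomy[i],
          sel$beta_group[i], sel$t_stat[i], sel$p_raw[i],
          sel$q_wholebrain[i], sel$q_network[i]))
      }
      lines <- c(lines, "")
    }
  }

  if (file.exists(p$nbs)) {
    nbs <- jsonlite::read_json(p$nbs)
    lines <- c(lines, "## Network-based statistic (dFC)", "")
    if (!is.null(nbs$note)) {
      lines <- c(lines, nbs$note, "")
    } else {
      for (metric in intersect(c("dfc_mean", "dfc_var"), names(nbs))) {
        m <- nbs[[metric]]
        lines <- c(lines, sprintf(
          "- %s: %d suprathreshold component(s); %s (%d permutations).",
          metric, length(m$component_size),
          if (isTRUE(m$significant)) "family-wise significant"
          else "no family-wise significant component",
          m$n_permutations))
      }
      lines <- c(lines, "")
    }
  }

  if (file.exists(p$correlations)) {
    cg <- read_tsv(p$correlations)
    lines <- c(lines, "## Clinical correlations (partial r)", "")
    if (nrow(cg) == 0L) {
      lines <- c(lines, "No seed ROIs; correlation grid not computed.", "")
    } else {
      sig <- cg[cg$significant | cg$group_diff_significant, ]
      lines <- c(lines, sprintf(
        "%d metric x score cells tested; %d significant after FDR; %d with significant group difference.",
        nrow(cg), sum(cg$significant), sum(cg$group_diff_significant)), "")
      if (nrow(sig) > 0L) {
        lines <- c(lines,
                   "| metric | score | r(all) | q | r(SCD) | r(NC) | diff z | diff q |",
                   "|---|---|---|---|---|---|---|---|")
        for (i in seq_len(nrow(sig))) {
          lines <- c(lines, sprintf(
            "| %s | %s | %.2f | %.3g | %.2f | %.2f | %.2f | %.3g |",
            sig$metric[i], sig$score[i], sig$r_all[i], sig$q_fdr[i],
            sig$r_scd[i], sig$r_nc[i], sig$group_diff_z[i],
            sig$group_diff_q[i]))
        }
        lines <- c(lines, "")
      }
    }
  }
  writeLines(lines, p$report)
  invisible(list(report = p$report))
}
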
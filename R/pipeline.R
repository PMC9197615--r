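# End-to-end drivers tying the stages into the full analysis: measurement
# tables, curvature profiles + pattern contingency, and cohort statistics.
# These are the programmatic counterparts of the command-line subcommands in
# inst/exec/femurmorph. All defaults used in a run are logged into the
# output directory for provenance.

#' Build or read a run configuration
#'
#' A run configuration lists the specimens (raw bundle / DICOM directories,
#' landmark slice indices, cohort labels, reference lengths) and the
#' analysis parameters. It can be given as a YAML file or as a list.
#'
#' Expected structure:
#' \preformatted{
#' output_dir: out
#' reference_length_kind: diaphyseal   # or total
#' levels_morphometrics: [2,3,4,5,6,7,8,9]
#' bin_width_hu: 10
#' epsilon_mm: 0.3
#' alpha: 0.05
#' seed: 1
#' specimens:
#'   - id: s1
#'     path: phantoms/s1
#'     cohort: modern
#'     z_upper: 1
#'     z_lower: 91
#'     reference_length_mm: 430
#' }
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(output_dir = "femurmorph_out",
                   reference_length_kind = "diaphyseal",
                   levels_morphometrics = 2:9,
                   bin_width_hu = 10, epsilon_mm = 0.3,
                   alpha = 0.05, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$specimens) || length(config$specimens) == 0)
    stopf("config lists no specimens")
  for (sp in config$specimens) {
    for (f in c("id", "path", "cohort", "z_upper", "z_lower",
                "reference_length_mm"))
      if (is.null(sp[[f]])) stopf("specimen entry missing field '%s'", f)
    if (!dir.exists(sp$path)) stopf("specimen input not found: %s", sp$path)
  }
  structure(config, class = "run_config")
}

log_line <- function(log, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
}

# load, plan, threshold and segment one configured specimen
prepare_specimen <- function(sp, config, levels) {
  vol <- load_volume(sp$path, side = sp$side)
  plan <- plan_levels(vol, sp$z_upper, sp$z_lower)
  sections10 <- extract_sections(vol, plan, 1:10)
  thr <- derive_threshold(pool_histogram(sections10,
                                         bin_width = config$bin_width_hu))
  list(volume = vol, plan = plan, sections = sections10, threshold = thr)
}

#' Measure all configured specimens
#'
#' Runs segmentation and the six morphometric parameters (plus their
#' length-standardized forms) for every specimen at the configured levels,
#' writing one tidy CSV (`morphometrics.csv`, one row per specimen x level;
#' units in column names) and a JSON provenance record into the output
#' directory. Per-specimen failures are logged and skipped; the run
#' continues.
#'
#' @param config A [run_config()] (or path/list accepted by it).
#' @return The combined measurement data.frame, invisibly.
#' @export
run_measure <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$output_dir, "run.log")
  jsonlite::write_json(unclass(config),
                       file.path(config$output_dir, "config_used.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  out <- list()
  for (sp in config$specimens) {
    t0 <- proc.time()["elapsed"]
    res <- try({
      prep <- prepare_specimen(sp, config, config$levels_morphometrics)
      rec <- measure_specimen(prep$sections, prep$threshold,
                              levels = config$levels_morphometrics)
      std <- standardize_record(rec, sp$reference_length_mm,
                                kind = config$reference_length_kind)
      rec$cohort <- sp$cohort
      cbind(rec, std[, c("csa_std", "acb_std", "pbl_std",
                         "mean_cbt_std", "max_cbt_std",
                         "reference_length_mm", "reference_length_kind")])
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      log_line(log, "measure %s: SKIPPED (%s)", sp$id,
               trimws(attr(res, "condition")$message %||% "error"))
      next
    }
    log_line(log, "measure %s: %d levels in %.1f s", sp$id, nrow(res),
             proc.time()["elapsed"] - t0)
    out[[sp$id]] <- res
  }
  if (length(out) == 0) stopf("no specimen could be measured")
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  names(tab)[names(tab) %in% c("csa", "acb")] <-
    paste0(c("csa", "acb"), "_mm2")
  names(tab)[names(tab) %in% c("pbl", "mean_cbt", "max_cbt",
                               "perimeter_geometric")] <-
    paste0(c("pbl", "mean_cbt", "max_cbt", "perimeter_geometric"), "_mm")
  utils::write.csv(tab, file.path(config$output_dir, "morphometrics.csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Curvature analysis of all configured specimens
#'
#' Computes per-level CMDs (levels 1-9), deviation profiles, the lateral
#' pattern of every specimen, the cohort x pattern contingency table, the
#' chi-squared independence test across cohorts, and per-level mean lateral
#' deviations with standard errors. Writes `cmd_profiles.csv`,
#' `patterns.csv`, `pattern_contingency.csv`, `dx_by_level.csv` and
#' `chisq_report.json`.
#'
#' @param config A [run_config()].
#' @return List with `profiles`, `patterns`, `contingency`, `chisq`
#'   (NULL when fewer than two cohorts), invisibly.
#' @export
run_curvature <- function(config) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$output_dir, "run.log")
  profiles <- list(); patterns <- list()
  for (sp in config$specimens) {
    t0 <- proc.time()["elapsed"]
    res <- try({
      vol <- load_volume(sp$path, side = sp$side)
      curvature_profile(vol, sp$z_upper, sp$z_lower,
                        reference_length = sp$reference_length_mm,
                        epsilon = config$epsilon_mm)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      log_line(log, "curvature %s: SKIPPED (%s)", sp$id,
               trimws(attr(res, "condition")$message %||% "error"))
      next
    }
    log_line(log, "curvature %s: pattern %s in %.1f s", sp$id, res$pattern,
             proc.time()["elapsed"] - t0)
    prof <- res$profile
    prof$specimen_id <- sp$id
    prof$cohort <- sp$cohort
    profiles[[sp$id]] <- prof
    patterns[[sp$id]] <- data.frame(
      specimen_id = sp$id, cohort = sp$cohort, pattern = res$pattern,
      anterior_degree = res$anterior_degree)
  }
  if (length(patterns) == 0) stopf("no specimen could be analyzed")
  prof_tab <- do.call(rbind, profiles); rownames(prof_tab) <- NULL
  pat_tab <- do.call(rbind, patterns); rownames(pat_tab) <- NULL
  cont <- pattern_table(pat_tab$pattern, pat_tab$cohort)

  # Fig-9-style per-level mean lateral deviation with standard errors
  agg <- do.call(rbind, lapply(split(prof_tab, list(prof_tab$cohort,
                                                    prof_tab$level),
                                     drop = TRUE), function(d)
    data.frame(cohort = d$cohort[1], level = d$level[1],
               mean_dx_mm = mean(d$dx),
               se_dx_mm = stats::sd(d$dx) / sqrt(nrow(d)),
               n = nrow(d))))
  agg <- agg[order(agg$cohort, agg$level), ]; rownames(agg) <- NULL

  chisq <- NULL
  cont4 <- cont[, lateral_patterns, drop = FALSE]
  cont4 <- cont4[rowSums(cont4) > 0, colSums(cont4) > 0, drop = FALSE]
  if (nrow(cont4) >= 2 && ncol(cont4) >= 2) {
    chisq <- chi_squared_independence(cont4)
    jsonlite::write_json(
      list(statistic = chisq$statistic, df = chisq$df,
           p_value = chisq$p_value, low_expected = chisq$low_expected),
      file.path(config$output_dir, "chisq_report.json"),
      auto_unbox = TRUE, digits = NA)
  } else {
    log_line(log, "chi-squared test skipped: need >= 2 non-empty cohorts and patterns")
  }
  utils::write.csv(prof_tab, file.path(config$output_dir, "cmd_profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(pat_tab, file.path(config$output_dir, "patterns.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cohort = rownames(cont), cont,
                              check.names = FALSE),
                   file.path(config$output_dir, "pattern_contingency.csv"),
                   row.names = FALSE)
  utils::write.csv(agg, file.path(config$output_dir, "dx_by_level.csv"),
                   row.names = FALSE)
  invisible(list(profiles = prof_tab, patterns = pat_tab,
                 contingency = cont, chisq = chisq))
}

#' Cohort statistics on a measurement table
#'
#' For every morphometric parameter: normality goodness of fit and the
#' repeated-measures ANOVA with Scheffe contrasts; then a correlation PCA of
#' the per-specimen means of the five length-standardized parameters plus
#' the cortical index. Writes `anova_<param>.csv`, `scheffe_<param>.csv`,
#' `gof.csv`, `pca_loadings.csv` and `pca_scores.csv`.
#'
#' @param config A [run_config()]; `measurements` may override the CSV
#'   produced by [run_measure()].
#' @param measurements Optional data.frame as returned by [run_measure()].
#' @return List with `anova` (per parameter), `gof`, `pca`, invisibly.
#' @export
run_stats <- function(config, measurements = NULL) {
  config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$output_dir, "run.log")
  if (is.null(measurements)) {
    f <- file.path(config$output_dir, "morphometrics.csv")
    if (!file.exists(f)) stopf("no measurement table found; run run_measure() first")
    measurements <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  params <- intersect(c("mean_cbt_mm", "max_cbt_mm", "pbl_mm", "acb_mm2",
                        "csa_mm2", "ci"), names(measurements))
  anovas <- list(); gofs <- list()
  for (p in params) {
    tab <- data.frame(specimen_id = measurements$specimen_id,
                      cohort = measurements$cohort,
                      level = measurements$level,
                      value = measurements[[p]])
    res <- try(rm_anova_scheffe(tab, alpha = config$alpha), silent = TRUE)
    if (inherits(res, "try-error")) {
      log_line(log, "stats %s: SKIPPED (%s)", p,
               trimws(attr(res, "condition")$message %||% "error"))
      next
    }
    anovas[[p]] <- res
    gofs[[p]] <- data.frame(parameter = p,
                            as.data.frame(normality_gof(tab$value)[
                              c("statistic", "df", "p_value")]))
    utils::write.csv(res$anova,
                     file.path(config$output_dir, sprintf("anova_%s.csv", p)),
                     row.names = FALSE)
    utils::write.csv(res$scheffe,
                     file.path(config$output_dir, sprintf("scheffe_%s.csv", p)),
                     row.names = FALSE)
  }
  if (length(gofs))
    utils::write.csv(do.call(rbind, gofs),
                     file.path(config$output_dir, "gof.csv"),
                     row.names = FALSE)

  # PCA on specimen means: five standardized parameters + CI
  std_cols <- intersect(c("mean_cbt_std", "max_cbt_std", "pbl_std",
                          "acb_std", "csa_std", "ci"), names(measurements))
  pca <- NULL
  if (length(std_cols) == 6 && length(unique(measurements$specimen_id)) >= 3) {
    agg <- stats::aggregate(measurements[std_cols],
                            by = list(specimen_id = measurements$specimen_id,
                                      cohort = measurements$cohort),
                            FUN = mean)
    pca <- try(pca_on_means(agg[std_cols]), silent = TRUE)
    if (inherits(pca, "try-error")) {
      log_line(log, "PCA skipped (%s)",
               trimws(attr(pca, "condition")$message %||% "error"))
      pca <- NULL
    } else {
      utils::write.csv(data.frame(parameter = std_cols, pca$loadings),
                       file.path(config$output_dir, "pca_loadings.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(specimen_id = agg$specimen_id,
                                  cohort = agg$cohort,
                                  Z1 = pca$scores[, 1], Z2 = pca$scores[, 2]),
                       file.path(config$output_dir, "pca_scores.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(anova = anovas, gof = if (length(gofs)) do.call(rbind, gofs),
                 pca = pca))
}
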
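# Recovery and calibration studies: seeded simulation drivers used to
# validate the pipeline end to end (pattern classification accuracy on noisy
# phantoms; type-I error and power of the cohort ANOVA).

#' Lateral-pattern recovery study on noisy phantoms
#'
#' Renders seeded replicate phantoms for each lateral-curvature mode, runs
#' the full pipeline (histogram threshold, segmentation, CMD, deviation
#' profile, classification) and scores the classification against the
#' generating mode.
#'
#' @param n_reps Replicates per mode.
#' @param amplitude Lateral amplitude A_x in mm (default 2).
#' @param noise_sd HU noise SD (default 50).
#' @param epsilon Classification deadband in mm (default 0.3).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param modes Modes to study (default: all four).
#' @param reference_length Normalizing length in mm (default 430).
#' @return data.frame with `mode`, `rep`, `pattern`, `correct`.
#' @export
pattern_recovery_study <- function(n_reps = 50, amplitude = 2, noise_sd = 50,
                                   epsilon = 0.3, seed = 1,
                                   modes = c("primary_lateral", "primary_medial",
                                             "s_lateral_medial", "s_medial_lateral"),
                                   reference_length = 430) {
  rows <- vector("list", length(modes) * n_reps)
  k <- 0L
  for (mode in modes) {
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sp <- phantom_spec(lateral_mode = mode, lateral_mm = amplitude,
                         noise_sd = noise_sd, seed = derive_seed(seed, k),
                         specimen_id = sprintf("%s_%03d", mode, r))
      ph <- render_phantom(sp)
      prof <- curvature_profile(ph$volume, sp$z_upper, sp$z_lower,
                                reference_length = reference_length,
                                epsilon = epsilon)
      rows[[k]] <- data.frame(mode = mode, rep = r, pattern = prof$pattern,
                              correct = identical(prof$pattern, mode))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort-effect rejection rate of the repeated-measures ANOVA
#'
#' Simulates replicate cohort tables ([simulate_cohort_table()]) and reports
#' how often the between-subjects cohort effect is rejected at `alpha`.
#' With `shift = 0` this estimates the type-I error; with a planted shift
#' (in units of the between-specimen SD of specimen means,
#' `sqrt(specimen_sd^2 + resid_sd^2 / n_levels)`) it estimates power. The
#' shift is applied to the first cohort.
#'
#' @param n_reps Number of simulated datasets.
#' @param shift Cohort mean shift in pooled-SD units (default 0).
#' @param alpha Significance level (default 0.05).
#' @param n_per_cohort,n_levels,specimen_sd,resid_sd Passed to
#'   [simulate_cohort_table()].
#' @param seed Master seed.
#' @return List with `rate`, `n_reps`, `p_values`.
#' @export
anova_rejection_rate <- function(n_reps = 1000, shift = 0, alpha = 0.05,
                                 n_per_cohort = c(A = 10, B = 10, C = 5),
                                 n_levels = 8, specimen_sd = 1, resid_sd = 1,
                                 seed = 1) {
  pooled_sd <- sqrt(specimen_sd^2 + resid_sd^2 / n_levels)
  shifts <- c(shift * pooled_sd, rep(0, length(n_per_cohort) - 1L))
  p <- vapply(seq_len(n_reps), function(i) {
    tab <- simulate_cohort_table(n_per_cohort = n_per_cohort,
                                 n_levels = n_levels,
                                 cohort_shift = shifts,
                                 specimen_sd = specimen_sd,
                                 resid_sd = resid_sd,
                                 seed = derive_seed(seed, i))
    res <- rm_anova_scheffe(tab, alpha = alpha)
    res$anova$p[res$anova$effect == "cohort"]
  }, numeric(1))
  list(rate = mean(p < alpha), n_reps = n_reps, p_values = p)
}
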
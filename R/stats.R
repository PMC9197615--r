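# Cohort statistics: chi-squared goodness of fit for normality, split-plot
# (repeated-measures two-factor) ANOVA with Scheffe post hoc contrasts,
# correlation-matrix PCA of specimen means, chi-squared independence for the
# curvature-pattern contingency table, and period grouping from calibrated
# radiocarbon ages.

#' Chi-squared goodness-of-fit test for normality
#'
#' Bins the sample into equal-probability classes of a normal distribution
#' with the sample mean and standard deviation; the statistic is
#' `sum((O - E)^2 / E)` with `df = bins - 3` (two estimated parameters).
#'
#' @param x Numeric sample, `n >= 8`.
#' @param bins Number of equal-probability bins; default
#'   `max(4, ceiling(2 * n^0.4))`.
#' @return List with `statistic`, `df`, `p_value`, `bins`, `expected`
#'   (common expected count per bin).
#' @export
normality_gof <- function(x, bins = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stopf("goodness-of-fit test needs n >= 8 (got %d)", n)
  s <- stats::sd(x)
  if (s == 0) stopf("sample has zero variance")
  if (is.null(bins)) bins <- max(4L, ceiling(2 * n^0.4))
  if (bins < 4) stopf("need at least 4 bins for df = bins - 3 >= 1")
  br <- stats::qnorm(seq(0, 1, length.out = bins + 1), mean = mean(x), sd = s)
  br[1] <- -Inf; br[bins + 1] <- Inf
  obs <- tabulate(findInterval(x, br, left.open = TRUE), nbins = bins)
  expd <- n / bins
  stat <- sum((obs - expd)^2 / expd)
  df <- bins - 3L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       bins = bins, expected = expd)
}

#' Repeated-measures two-factor ANOVA with Scheffe post hoc
#'
#' Split-plot decomposition: cohort is the between-subjects factor, level
#' the within-subjects (repeated) factor, and specimen the repeated unit
#' nested in cohort (its stratum provides the between-subjects error term).
#' Scheffe pairwise contrasts on the cohort means use the between-subjects
#' mean square and degrees of freedom; the Scheffe criterion compares the
#' contrast F against `(k - 1) * qf(1 - alpha, k - 1, df_between)`, so it is
#' never more liberal than an unadjusted pairwise F. Specimens with
#' incomplete level coverage are dropped listwise with a warning. An
#' optional Greenhouse-Geisser correction (off by default, matching the
#' uncorrected historical analysis) adjusts the within-subject p-values for
#' sphericity violations.
#'
#' @param table data.frame with columns `specimen_id`, `cohort`, `level`,
#'   `value` (one value per specimen x level).
#' @param alpha Significance level for the Scheffe criterion (default 0.05).
#' @param gg Apply the Greenhouse-Geisser epsilon correction to the
#'   within-subject effects (default `FALSE`).
#' @param scope `"pooled"` (Scheffe on level-pooled cohort means, default)
#'   or `"per_level"` (one-way ANOVA + Scheffe separately at each level).
#' @return An `anova_result`: `anova` table (effect, df, ss, ms, F, p),
#'   `scheffe` data.frame of pairwise contrasts, `means` per cohort,
#'   `alpha`, `gg_epsilon` (when `gg`), `dropped` specimen ids.
#' @export
rm_anova_scheffe <- function(table, alpha = 0.05, gg = FALSE,
                             scope = c("pooled", "per_level")) {
  scope <- match.arg(scope)
  need <- c("specimen_id", "cohort", "level", "value")
  if (!all(need %in% names(table)))
    stopf("table must have columns %s", paste(need, collapse = ", "))
  df <- data.frame(specimen_id = factor(table$specimen_id),
                   cohort = factor(table$cohort),
                   level = factor(table$level),
                   value = as.numeric(table$value))
  df <- df[is.finite(df$value), ]
  if (nlevels(droplevels(df$cohort)) < 2) stopf("need at least 2 cohorts")
  if (nlevels(droplevels(df$level)) < 2) stopf("need at least 2 levels")

  # listwise exclusion of specimens missing any level
  nlev <- nlevels(droplevels(df$level))
  cover <- tapply(df$level, df$specimen_id, function(l) length(unique(l)))
  dropped <- names(cover)[is.na(cover) | cover < nlev]
  if (length(dropped)) {
    warnf("dropping %d specimen(s) with incomplete level coverage: %s",
          length(dropped), paste(dropped, collapse = ", "))
    df <- df[!(df$specimen_id %in% dropped), ]
  }
  df <- droplevels(df)
  ns <- table(unique(df[c("specimen_id", "cohort")])$cohort)
  if (any(ns < 2)) stopf("need at least 2 specimens per cohort")

  fit <- stats::aov(value ~ cohort * level + Error(specimen_id), data = df)
  sm <- summary(fit)
  pull <- function(stratum) {
    tab <- sm[[stratum]][[1]]
    data.frame(effect = trimws(rownames(tab)), df = tab$Df,
               ss = tab$`Sum Sq`, ms = tab$`Mean Sq`,
               F = tab$`F value`, p = tab$`Pr(>F)`)
  }
  between <- pull("Error: specimen_id")
  within <- pull("Error: Within")
  between$effect[between$effect == "Residuals"] <- "specimen(cohort)"
  within$effect[within$effect == "Residuals"] <- "residual"
  anova_tab <- rbind(between, within)
  anova_tab$stratum <- rep(c("between", "within"),
                           c(nrow(between), nrow(within)))

  gg_eps <- NULL
  if (gg) {
    gg_eps <- gg_epsilon(df)
    wi <- anova_tab$stratum == "within" & anova_tab$effect != "residual"
    res <- anova_tab[anova_tab$effect == "residual", ]
    for (i in which(wi)) {
      anova_tab$p[i] <- stats::pf(anova_tab$F[i],
                                  gg_eps * anova_tab$df[i],
                                  gg_eps * res$df[1], lower.tail = FALSE)
    }
  }

  k <- nlevels(df$cohort)
  ms_b <- between$ms[between$effect == "specimen(cohort)"]
  df_b <- between$df[between$effect == "specimen(cohort)"]
  L <- nlev
  means <- tapply(df$value, df$cohort, mean)
  scheffe <- if (scope == "pooled") {
    scheffe_pairs(means, ns * L, ms_b, df_b, k, alpha)
  } else {
    do.call(rbind, lapply(levels(df$level), function(lv) {
      sub <- df[df$level == lv, ]
      f1 <- stats::aov(value ~ cohort, data = sub)
      s1 <- summary(f1)[[1]]
      i_res <- which(trimws(rownames(s1)) == "Residuals")
      ms_e <- s1[i_res, "Mean Sq"]
      df_e <- s1[i_res, "Df"]
      out <- scheffe_pairs(tapply(sub$value, sub$cohort, mean),
                           table(sub$cohort), ms_e, df_e, k, alpha)
      out$level <- lv
      out
    }))
  }

  structure(list(anova = anova_tab, scheffe = scheffe, means = means,
                 alpha = alpha, gg_epsilon = gg_eps, dropped = dropped,
                 n_per_cohort = as.vector(ns), n_levels = L),
            class = "anova_result")
}

scheffe_pairs <- function(means, n_obs, ms_err, df_err, k, alpha) {
  cohorts <- names(means)
  pairs <- utils::combn(cohorts, 2)
  crit <- (k - 1) * stats::qf(1 - alpha, k - 1, df_err)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- means[[a]] - means[[b]]
    se2 <- ms_err * (1 / n_obs[[a]] + 1 / n_obs[[b]])
    Fpair <- diff^2 / se2
    data.frame(cohort_a = a, cohort_b = b, diff = diff,
               F = Fpair, F_critical = crit,
               p = stats::pf(Fpair / (k - 1), k - 1, df_err,
                             lower.tail = FALSE),
               significant = Fpair > crit)
  })
  do.call(rbind, out)
}

# Greenhouse-Geisser epsilon from the specimen x level residual covariance
gg_epsilon <- function(df) {
  wide <- stats::reshape(df[, c("specimen_id", "level", "value")],
                         direction = "wide", idvar = "specimen_id",
                         timevar = "level")
  m <- as.matrix(wide[, -1])
  # remove cohort means so the covariance reflects within-cohort structure
  coh <- df$cohort[match(wide$specimen_id, df$specimen_id)]
  for (g in levels(coh)) {
    rows <- which(coh == g)
    m[rows, ] <- sweep(m[rows, , drop = FALSE], 2,
                       colMeans(m[rows, , drop = FALSE]))
  }
  S <- stats::cov(m)
  p <- ncol(S)
  num <- (sum(diag(S)) - sum(S) / p)^2 * p^2 / (p - 1)
  den <- p^2 * sum(S^2) - 2 * p * sum(rowSums(S)^2) + sum(S)^2
  max(1 / (p - 1), min(1, num / den))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Repeated-measures two-factor ANOVA (split-plot)\n")
  print(x$anova, digits = 4, row.names = FALSE)
  cat(sprintf("\nScheffe pairwise contrasts (alpha = %.2f):\n", x$alpha))
  print(x$scheffe, digits = 4, row.names = FALSE)
  invisible(x)
}

#' PCA of specimen-mean morphometric parameters
#'
#' Principal component analysis on the correlation matrix (columns centered
#' and scaled, since the parameters carry heterogeneous units even after
#' length standardization). For reproducibility each component's sign is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param x Numeric matrix or data.frame, specimens x parameters (typically
#'   the five length-standardized parameters plus the cortical index).
#' @return A `pca_result`: `loadings` (parameters x components,
#'   orthonormal), `eigenvalues` (nonincreasing, summing to the number of
#'   variables), `scores` (specimens x components), `center`, `scale`.
#' @export
pca_on_means <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stopf("PCA needs at least 3 specimens")
  if (any(!is.finite(x))) stopf("PCA input contains non-finite values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(loadings = rot, eigenvalues = pc$sdev^2, scores = scores,
                 center = pc$center, scale = pc$scale),
            class = "pca_result")
}

#' Chi-squared independence test for a contingency table
#'
#' Pearson statistic on a cohort x pattern count table. All-zero rows and
#' columns are removed first (they carry no information and would break the
#' expected counts); a low-expected-count flag is set when any expected
#' cell is below 5.
#'
#' @param tab Matrix of nonnegative integer counts.
#' @return A `chisq_result`: `statistic`, `df`, `p_value`, `expected`,
#'   `observed`, `low_expected` flag.
#' @export
chi_squared_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (any(!keep_r) || any(!keep_c))
    warnf("dropping %d all-zero row(s) and %d all-zero column(s)",
          sum(!keep_r), sum(!keep_c))
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("degenerate table: need at least 2 non-empty rows and columns")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic),
                 df = as.integer(ct$parameter),
                 p_value = unname(ct$p.value),
                 expected = ct$expected,
                 observed = tab,
                 low_expected = any(ct$expected < 5)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-squared independence: X^2 = %.3f, df = %d, p = %.3g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected) " (expected counts < 5 present)" else ""))
  invisible(x)
}

#' Assign specimens to period groups from calibrated radiocarbon ages
#'
#' Each specimen is summarized by the midpoint of its highest-probability
#' 68.3% calibrated interval and assigned to the Late group when the
#' midpoint is younger than the boundary (default 6,000 cal BP, the midpoint
#' of the gap between the two period ranges: Initial/Early ca. 10,200-6,500
#' cal BP, Late ca. 4,500-4,000 cal BP; any cut inside the gap gives the
#' same grouping). Midpoints outside both stated ranges are still assigned
#' by the cut, with a warning.
#'
#' @param ages data.frame with columns `specimen_id`, `cal_bp_older`,
#'   `cal_bp_younger`, `probability` (one row per 68.3% interval; specimens
#'   may have several intervals).
#' @param boundary Cut in cal BP (default 6000).
#' @return data.frame with one row per specimen: `specimen_id`,
#'   `midpoint_cal_bp`, `group` (`"initial_early_jomon"` / `"late_jomon"`),
#'   plus a `counts` attribute (named group sizes).
#' @export
assign_periods <- function(ages, boundary = 6000) {
  need <- c("specimen_id", "cal_bp_older", "cal_bp_younger", "probability")
  if (!all(need %in% names(ages)))
    stopf("ages must have columns %s", paste(need, collapse = ", "))
  ids <- unique(ages$specimen_id)
  rows <- lapply(ids, function(id) {
    sub <- ages[ages$specimen_id == id, ]
    best <- sub[which.max(sub$probability), ]
    mid <- (best$cal_bp_older + best$cal_bp_younger) / 2
    data.frame(specimen_id = id, midpoint_cal_bp = mid,
               group = if (mid < boundary) "late_jomon" else "initial_early_jomon")
  })
  out <- do.call(rbind, rows)
  in_range <- (out$midpoint_cal_bp >= 6500 & out$midpoint_cal_bp <= 10200) |
    (out$midpoint_cal_bp >= 4000 & out$midpoint_cal_bp <= 4500)
  if (any(!in_range))
    warnf("%d specimen(s) have calibrated midpoints outside both stated period ranges; assigned by the %d cal BP cut",
          sum(!in_range), boundary)
  attr(out, "counts") <- c(
    initial_early_jomon = sum(out$group == "initial_early_jomon"),
    late_jomon = sum(out$group == "late_jomon"))
  out
}

#' Calibrated radiocarbon ages of the Hegi cave femurs
#'
#' The published 68.3% calibrated intervals for the fifteen femurs (one row
#' per interval), as shipped in `inst/extdata/hegi_radiocarbon.csv`.
#'
#' @return data.frame with `specimen_id`, `period_label`, `c14_age_bp`,
#'   `c14_err_bp`, `lab_id`, `cal_bp_older`, `cal_bp_younger`,
#'   `probability`.
#' @export
hegi_radiocarbon <- function() {
  utils::read.csv(system.file("extdata", "hegi_radiocarbon.csv",
                              package = "femurmorph"),
                  stringsAsFactors = FALSE)
}

#' Published cohort-by-pattern curvature counts
#'
#' The reference contingency table of lateral-curvature pattern counts for
#' the modern, Initial/Early and Late cohorts, shipped in
#' `inst/extdata/curvature_pattern_counts.csv`.
#'
#' @return Integer matrix (3 cohorts x 4 patterns).
#' @export
curvature_pattern_counts <- function() {
  d <- utils::read.csv(system.file("extdata", "curvature_pattern_counts.csv",
                                   package = "femurmorph"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Simulate a balanced cohort measurement table
#'
#' Draws `value = mu_level[l] + cohort_shift + specimen effect + noise` for
#' each specimen x level cell: a simple additive model for calibrating the
#' repeated-measures ANOVA (type-I error under identical cohorts, power
#' under a planted cohort shift).
#'
#' @param n_per_cohort Integer vector of cohort sizes (names become cohort
#'   labels; default `c(A = 10, B = 10, C = 5)`).
#' @param n_levels Number of repeated levels (default 8).
#' @param mu_level Level means (recycled; default 0).
#' @param cohort_shift Numeric vector of per-cohort mean shifts (default all
#'   zero).
#' @param specimen_sd Between-specimen SD (default 1).
#' @param resid_sd Within-specimen residual SD (default 1).
#' @param seed Optional integer seed.
#' @return data.frame with `specimen_id`, `cohort`, `level`, `value`.
#' @export
simulate_cohort_table <- function(n_per_cohort = c(A = 10, B = 10, C = 5),
                                  n_levels = 8, mu_level = 0,
                                  cohort_shift = NULL,
                                  specimen_sd = 1, resid_sd = 1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(n_per_cohort)))
    names(n_per_cohort) <- LETTERS[seq_along(n_per_cohort)]
  if (is.null(cohort_shift)) cohort_shift <- rep(0, length(n_per_cohort))
  mu <- rep_len(mu_level, n_levels)
  rows <- list()
  for (g in seq_along(n_per_cohort)) {
    for (i in seq_len(n_per_cohort[g])) {
      id <- sprintf("%s_%02d", names(n_per_cohort)[g], i)
      eff <- stats::rnorm(1, sd = specimen_sd)
      rows[[id]] <- data.frame(
        specimen_id = id, cohort = names(n_per_cohort)[g],
        level = seq_len(n_levels),
        value = mu + cohort_shift[g] + eff +
          stats::rnorm(n_levels, sd = resid_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
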
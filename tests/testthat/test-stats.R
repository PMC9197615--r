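test_that("normality GOF accepts normal samples and rejects exponential ones", {
  set.seed(101)
  p_norm <- replicate(100, normality_gof(rnorm(1000))$p_value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_exp <- replicate(100, normality_gof(rexp(1000))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.90)
  expect_error(normality_gof(rep(2, 50)), "zero variance")
  expect_error(normality_gof(rnorm(5)), "n >= 8")
  g <- normality_gof(rnorm(200))
  expect_identical(g$df, g$bins - 3L)
})

test_that("split-plot ANOVA decomposes the total sum of squares", {
  tab <- simulate_cohort_table(seed = 77)
  res <- rm_anova_scheffe(tab)
  total_ss <- sum((tab$value - mean(tab$value))^2)
  expect_equal(sum(res$anova$ss), total_ss, tolerance = 1e-8)
  expect_equal(sum(res$anova$df), nrow(tab) - 1)
  expect_true(all(res$anova$ss >= 0))
  # effects present in both strata
  expect_setequal(res$anova$effect,
                  c("cohort", "specimen(cohort)", "level", "cohort:level",
                    "residual"))
})

test_that("identical cohorts give a zero cohort effect and no Scheffe hits", {
  one <- simulate_cohort_table(n_per_cohort = c(A = 6), seed = 5)
  two <- one
  two$cohort <- "B"
  two$specimen_id <- sub("^A", "B", two$specimen_id)
  res <- rm_anova_scheffe(rbind(one, two))
  f_cohort <- res$anova$F[res$anova$effect == "cohort"]
  expect_lt(f_cohort, 1e-20)
  expect_false(any(res$scheffe$significant))
})

test_that("Scheffe is never more liberal than an unadjusted pairwise F", {
  tab <- simulate_cohort_table(seed = 31, cohort_shift = c(0, 1, 2))
  res <- rm_anova_scheffe(tab, alpha = 0.05)
  df_b <- res$anova$df[res$anova$effect == "specimen(cohort)"]
  expect_true(all(res$scheffe$F_critical >= qf(0.95, 1, df_b)))
})

test_that("a planted cohort shift is detected; incomplete specimens are dropped", {
  tab <- simulate_cohort_table(seed = 13,
                               cohort_shift = c(3, 0, 0))  # huge effect
  res <- rm_anova_scheffe(tab)
  expect_lt(res$anova$p[res$anova$effect == "cohort"], 0.01)
  expect_true(any(res$scheffe$significant))

  # listwise exclusion with warning
  tab2 <- tab[!(tab$specimen_id == "A_01" & tab$level > 4), ]
  expect_warning(res2 <- rm_anova_scheffe(tab2), "incomplete")
  expect_identical(res2$dropped, "A_01")
})

test_that("per-level Scheffe mode reports contrasts at every level", {
  tab <- simulate_cohort_table(n_per_cohort = c(A = 4, B = 4), n_levels = 3,
                               seed = 3)
  res <- rm_anova_scheffe(tab, scope = "per_level")
  expect_identical(nrow(res$scheffe), 3L)     # 1 pair x 3 levels
  expect_true(all(c("level") %in% names(res$scheffe)))
})

test_that("Greenhouse-Geisser correction keeps epsilon in its admissible range", {
  tab <- simulate_cohort_table(seed = 8)
  res <- rm_anova_scheffe(tab, gg = TRUE)
  p <- res$anova$df[res$anova$effect == "level"] + 1
  expect_gte(res$gg_epsilon, 1 / (p - 1))
  expect_lte(res$gg_epsilon, 1)
  # for F > 1 the correction can only make the test more conservative
  res0 <- rm_anova_scheffe(tab, gg = FALSE)
  w <- res$anova$effect %in% c("level", "cohort:level") & res$anova$F > 1
  expect_true(all(res$anova$p[w] >= res0$anova$p[w]))
})

test_that("correlation PCA is orthonormal and reconstructs the scaled data", {
  set.seed(55)
  x <- matrix(rnorm(30 * 6), 30, 6)
  colnames(x) <- paste0("p", 1:6)
  pc <- pca_on_means(x)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(6))), 1e-10)
  expect_lt(abs(sum(pc$eigenvalues) - 6), 1e-10)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  z <- scale(x)
  recon <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
  # sign convention: largest-magnitude loading of each component positive
  for (k in 1:6) {
    v <- pc$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("PCA loads perfectly correlated columns equally on PC1", {
  set.seed(99)
  z <- rnorm(200)
  x <- cbind(a = z, b = z + rnorm(200, sd = 0.01),
             c = rnorm(200), d = rnorm(200))
  pc <- pca_on_means(x)
  l <- pc$loadings[, 1]
  expect_lt(abs(l["a"] - l["b"]) / max(abs(l[c("a", "b")])), 0.02)
  expect_error(pca_on_means(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
  expect_error(pca_on_means(x[1:2, ]), "at least 3")
})

test_that("chi-squared independence matches the hand computation on the reference counts", {
  tab <- curvature_pattern_counts()
  expect_identical(dim(tab), c(3L, 4L))
  expect_identical(unname(rowSums(tab)), c(46, 10, 5))
  res <- suppressWarnings(chi_squared_independence(tab))
  # independent spreadsheet-style computation from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat_hand <- sum((tab - E)^2 / E)
  expect_equal(res$statistic, stat_hand, tolerance = 1e-12)
  expect_identical(res$df, 6L)
  expect_lt(res$p_value, 0.05)
  expect_true(res$low_expected)
})

test_that("proportional tables give a zero statistic and p = 1", {
  tab <- rbind(c(10, 20, 30), c(5, 10, 15))
  res <- suppressWarnings(chi_squared_independence(tab))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- chi_squared_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(res2$statistic, 0)
  expect_warning(chi_squared_independence(rbind(c(5, 0, 3), c(2, 0, 1))),
                 "all-zero")
  expect_error(chi_squared_independence(rbind(c(1, 2))), "degenerate")
  expect_error(chi_squared_independence(rbind(c(1.5, 2), c(1, 2))),
               "nonnegative integers")
})

test_that("calibrated ages split the reference specimens 10 / 5", {
  ages <- hegi_radiocarbon()
  expect_identical(length(unique(ages$specimen_id)), 15L)
  res <- assign_periods(ages)
  counts <- attr(res, "counts")
  expect_identical(unname(counts["initial_early_jomon"]), 10L)
  expect_identical(unname(counts["late_jomon"]), 5L)
  # the grouping agrees with the published period labels
  lab <- unique(ages[c("specimen_id", "period_label")])
  merged <- merge(res, lab, by = "specimen_id")
  expect_true(all((merged$group == "late_jomon") ==
                    (merged$period_label == "Late Jomon")))
})

test_that("period assignment uses the highest-probability interval midpoint", {
  ages <- data.frame(specimen_id = c("a", "a", "b"),
                     cal_bp_older = c(4419, 4329, 7256),
                     cal_bp_younger = c(4352, 4298, 7166),
                     probability = c(46.0, 22.3, 68.3))
  res <- assign_periods(ages)
  expect_equal(res$midpoint_cal_bp[res$specimen_id == "a"], (4419 + 4352) / 2)
  expect_identical(res$group[res$specimen_id == "a"], "late_jomon")
  expect_identical(res$group[res$specimen_id == "b"], "initial_early_jomon")
  # out-of-range midpoint still assigned by the cut, with a warning
  odd <- data.frame(specimen_id = "c", cal_bp_older = 5100,
                    cal_bp_younger = 4900, probability = 68.3)
  expect_warning(res2 <- assign_periods(odd), "outside")
  expect_identical(res2$group, "late_jomon")
})
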
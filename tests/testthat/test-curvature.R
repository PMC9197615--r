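test_that("CMD of doubly symmetric shapes is the analytic center", {
  # centered disk
  n <- 101
  xx <- matrix(rep(1:n, n), n, n); yy <- t(xx)
  disk <- (xx - 51)^2 + (yy - 51)^2 <= 35^2
  cmd <- compute_cmd(make_mask(disk))
  expect_lt(abs(cmd$x_px - 50), 0.25)
  expect_lt(abs(cmd$y_px - 50), 0.25)
  # centered ellipse, different radii
  ell <- ((xx - 51) / 40)^2 + ((yy - 51) / 22)^2 <= 1
  cmde <- compute_cmd(make_mask(ell))
  expect_lt(abs(cmde$x_px - 50), 0.25)
  expect_lt(abs(cmde$y_px - 50), 0.25)
})

test_that("two disjoint equal lobes split at the midpoint between them", {
  m <- matrix(FALSE, 60, 20)
  m[1:5, 6:10] <- TRUE     # lobe centered at x_px = 2 (0-based)
  m[51:55, 6:10] <- TRUE   # lobe centered at x_px = 52
  cmd <- compute_cmd(make_mask(m, spacing = 1))
  expect_equal(cmd$x_px, 27)       # hand-derived: (4.5 + 49.5) / 2
  expect_equal(cmd$x_mm, 27)
})

test_that("CMD equals the brute-force equal-area split and differs from the centroid", {
  m <- matrix(FALSE, 40, 40)
  m[5:35, 5:12] <- TRUE            # L-shape
  m[5:12, 5:35] <- TRUE
  cmd <- compute_cmd(make_mask(m))
  oracle <- brute_cmd(m)
  expect_identical(cmd$x_px, unname(oracle["x"]))  # both 0-based pixel coords
  expect_identical(cmd$y_px, unname(oracle["y"]))
  centroid <- c(mean(which(m, arr.ind = TRUE)[, 1]),
                mean(which(m, arr.ind = TRUE)[, 2])) - 1
  expect_gt(abs(cmd$x_px - centroid[1]), 0.25)
})

test_that("CMD matches the brute-force oracle exactly on random blobs", {
  for (s in 1:6) {
    m <- random_blob(n = 120, n_disks = 3 + s %% 3, seed = s)
    cmd <- compute_cmd(make_mask(m))
    oracle <- brute_cmd(m)
    expect_identical(cmd$x_px, unname(oracle["x"]))
    expect_identical(cmd$y_px, unname(oracle["y"]))
  }
})

test_that("collinear CMDs give zero deviations and an indeterminate pattern", {
  cmds <- data.frame(level = 1:9, x = seq(2, 6, length.out = 9),
                     y = seq(10, 1, length.out = 9),
                     z = seq(0, 120, length.out = 9))
  prof <- deviation_profile(cmds, reference_length = 400)
  expect_equal(prof$profile$dx, rep(0, 9))
  expect_equal(prof$profile$dy, rep(0, 9))
  expect_identical(prof$pattern, "indeterminate")
  # baseline endpoints are exactly zero by construction, always
  set.seed(3)
  cmds$x <- cmds$x + rnorm(9); cmds$y <- cmds$y + rnorm(9)
  prof2 <- deviation_profile(cmds, reference_length = 400)
  expect_identical(prof2$profile$dx[c(1, 9)], c(0, 0))
  expect_identical(prof2$profile$dy[c(1, 9)], c(0, 0))
})

test_that("deviations are invariant under rigid translation of the volume", {
  set.seed(9)
  cmds <- data.frame(level = 1:9, x = rnorm(9), y = rnorm(9),
                     z = seq(0, 120, length.out = 9))
  p1 <- deviation_profile(cmds, reference_length = 400)
  cmds2 <- cmds
  cmds2$x <- cmds2$x + 12.5
  cmds2$y <- cmds2$y - 3.75
  p2 <- deviation_profile(cmds2, reference_length = 400)
  expect_equal(p2$profile$dx, p1$profile$dx)
  expect_equal(p2$profile$dy, p1$profile$dy)
})

test_that("anterior bow is recovered from the phantom within 5%", {
  sp <- phantom_spec(bow_mm = 4)
  ph <- render_phantom(sp)
  prof <- curvature_profile(ph$volume, 1, 91, reference_length = 430)
  expect_lt(abs(max(prof$profile$dy) - 4) / 4, 0.05)
  expect_true(all(abs(prof$profile$dx) < 0.3))
  expect_equal(prof$anterior_degree, max(prof$profile$dy) / 430)
})

test_that("an S-shaped lateral phantom deviates with the expected signs", {
  sp <- phantom_spec(lateral_mode = "s_lateral_medial", lateral_mm = 2)
  ph <- render_phantom(sp)
  prof <- curvature_profile(ph$volume, 1, 91, reference_length = 430)
  expect_true(all(prof$profile$dx[2:4] > 0))
  expect_true(all(prof$profile$dx[6:8] < 0))
  expect_identical(prof$pattern, "s_lateral_medial")
})

test_that("lateral patterns follow the sign taxonomy", {
  cases <- list(
    list(dx = c(1, 1, 1, 1, 1, 1, 1),        want = "primary_lateral"),
    list(dx = c(0, 0, 1, 1, 0, 0, 0),        want = "primary_lateral"),
    list(dx = c(-1, -1, -1, -1, -1, -1, -1), want = "primary_medial"),
    list(dx = c(-1, -1, -1, 0, 1, 1, 1),     want = "s_medial_lateral"),
    list(dx = c(1, 1, 0, -1, -1, -1, -1),    want = "s_lateral_medial"),
    list(dx = c(1, -1, 1, -1, 1, -1, 1),     want = "indeterminate"),
    list(dx = c(0, 0, 0, 0, 0, 0, 0),        want = "indeterminate"),
    list(dx = c(-1, 1, -1, 0, 0, 0, 0),      want = "indeterminate"))
  for (cs in cases)
    expect_identical(classify_lateral_pattern(cs$dx, epsilon = 0.3), cs$want)
  # deadband: shifts below epsilon count as zero
  expect_identical(classify_lateral_pattern(c(0.1, -0.2, 0.5, 0.6, 0.4, 0.1, -0.25),
                                            epsilon = 0.3),
                   "primary_lateral")
  # a 9-long vector is interpreted as levels 1..9
  expect_identical(classify_lateral_pattern(c(0, 1, 1, 1, 1, 1, 1, 1, 0)),
                   "primary_lateral")
  expect_error(classify_lateral_pattern(c(1, 2, 3)), "levels 2-8")
})

test_that("negating the lateral amplitude mirrors the pattern taxonomy", {
  swaps <- c(primary_lateral = "primary_medial",
             primary_medial = "primary_lateral",
             s_lateral_medial = "s_medial_lateral",
             s_medial_lateral = "s_lateral_medial")
  set.seed(21)
  for (i in 1:10) {
    dx <- rnorm(7, sd = 1.5)
    p <- classify_lateral_pattern(dx)
    q <- classify_lateral_pattern(-dx)
    if (p == "indeterminate") expect_identical(q, "indeterminate")
    else expect_identical(q, unname(swaps[p]))
  }
})

test_that("pattern tables count every cohort and keep indeterminate separate", {
  pats <- c("primary_lateral", "primary_lateral", "s_medial_lateral",
            "indeterminate", "primary_medial")
  coh <- factor(c("a", "a", "b", "b", "b"), levels = c("a", "b", "empty"))
  tab <- pattern_table(pats, coh)
  expect_identical(dim(tab), c(3L, 5L))
  expect_identical(tab["a", "primary_lateral"], 2L)
  expect_identical(tab["b", "indeterminate"], 1L)
  expect_identical(unname(rowSums(tab)["empty"]), 0)
  expect_identical(sum(tab), 5L)
  expect_error(pattern_table("nonsense", "a"), "unknown pattern")
})
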
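annulus_mask <- function(outer_px = 75, inner_px = 50, spacing = 0.2, ...) {
  segment_cortex(make_section(annulus_hu(outer_px, inner_px, ...),
                              spacing = spacing), 100)
}

test_that("areas and cortical index match the closed-form annulus within 1%", {
  mask <- annulus_mask()                     # 15 mm / 10 mm at 0.2 mm
  csa <- cross_sectional_area(mask)
  acb <- cortical_bone_area(mask)
  expect_lt(abs(csa - pi * 15^2) / (pi * 15^2), 0.01)
  expect_lt(abs(acb - pi * (15^2 - 10^2)) / (pi * 125), 0.01)
  expect_lt(abs(cortical_index(acb, csa) - 125 / 225) / (125 / 225), 0.01)
})

test_that("areas scale with the square of the pixel pitch", {
  m1 <- annulus_mask(outer_px = 30, inner_px = 18, spacing = 0.2)
  m2 <- m1
  m2$spacing <- 0.4
  expect_equal(cross_sectional_area(m2), 4 * cross_sectional_area(m1))
  expect_equal(cortical_bone_area(m2), 4 * cortical_bone_area(m1))
  # lengths scale linearly
  expect_equal(periosteal_border_length(m2)$pbl,
               2 * periosteal_border_length(m1)$pbl)
})

test_that("a single-pixel region measures one squared pixel", {
  hu <- matrix(-1000, 9, 9)
  hu[5, 5] <- 1200
  mask <- segment_cortex(make_section(hu, spacing = 0.2), 100)
  expect_equal(cross_sectional_area(mask), 0.04)
  expect_true(mask$solid)
  expect_equal(cortical_index(cortical_bone_area(mask),
                              cross_sectional_area(mask)), 1)
})

test_that("cortical index handles degenerate inputs", {
  expect_error(cortical_index(1, 0), "positive")
  expect_equal(cortical_index(0, 10), 0)
})

test_that("point-count PBL matches boundary-pixel enumeration", {
  # axis-aligned 100 x 100 px square: 4*100 - 4 = 396 boundary pixels
  hu <- matrix(-1000, 120, 120)
  hu[11:110, 11:110] <- 1200
  sq <- segment_cortex(make_section(hu, spacing = 0.2), 100)
  p <- periosteal_border_length(sq)
  expect_identical(p$n_points, 396L)
  expect_equal(p$pbl, 396 * 0.2)

  # digital circle r = 75 px: enumeration oracle gives exactly 424 boundary
  # pixels (84.80 mm at 0.2 mm/px, ~10% below the true 94.25 mm: the known
  # bias of the point-count convention on oblique boundaries). The geometric
  # (corrected chain-code) perimeter stays within 2% of the true value.
  circ <- annulus_mask(outer_px = 75, inner_px = 50)
  expect_identical(brute_boundary_count(circ$section_region), 424L)
  pc <- periosteal_border_length(circ)
  expect_identical(pc$n_points, 424L)
  expect_lt(abs(pc$perimeter_geometric - 2 * pi * 15) / (2 * pi * 15), 0.02)
})

test_that("PBL point count is invariant under 90-degree rotation", {
  hu <- annulus_hu(outer_px = 40, inner_px = 24, inner_center = c(55, 48))
  m1 <- segment_cortex(make_section(hu, spacing = 0.2), 100)
  rot <- t(hu)[ncol(hu):1, ]                # 90-degree lattice rotation
  m2 <- segment_cortex(make_section(rot, spacing = 0.2), 100)
  expect_identical(periosteal_border_length(m1)$n_points,
                   periosteal_border_length(m2)$n_points)
})

test_that("minimum-distance thickness matches the annulus closed forms", {
  conc <- annulus_mask(outer_px = 75, inner_px = 50)   # 5 mm wall
  th <- thickness_profile(conc)
  tol <- 0.2 + 1e-9                                    # 1 px, float slack
  expect_true(all(abs(th$thicknesses - 5) <= tol))
  expect_lte(abs(th$mean_cbt - 5), tol)
  expect_lte(abs(th$max_cbt - 5), tol)

  # inner circle offset +2 mm (10 px): wall runs from 3 mm to 7 mm
  ecc <- annulus_mask(outer_px = 75, inner_px = 50,
                      inner_center = c(91, 81))        # grid center (81,81) + 10 px in x
  the <- thickness_profile(ecc)
  expect_lte(abs(min(the$thicknesses) - 3), tol)
  expect_lte(abs(max(the$thicknesses) - 7), tol)
})

test_that("vectorized thickness equals the brute-force all-pairs minimum exactly", {
  hu <- annulus_hu(outer_px = 30, inner_px = 16, inner_center = c(45, 38))
  mask <- segment_cortex(make_section(hu, spacing = 0.2), 100)
  th <- thickness_profile(mask)
  brute <- brute_thickness(mask$periosteal_points, mask$endosteal_points, 0.2)
  expect_identical(th$thicknesses, brute)
})

test_that("thicker cortices raise acb, ci and thickness but not csa or pbl", {
  walls <- c(15, 25, 35, 45)                 # px, fixed outer radius 60 px
  recs <- lapply(walls, function(w) {
    measure_section(annulus_mask(outer_px = 60, inner_px = 60 - w))
  })
  acb <- vapply(recs, `[[`, numeric(1), "acb")
  ci <- vapply(recs, `[[`, numeric(1), "ci")
  mcbt <- vapply(recs, `[[`, numeric(1), "mean_cbt")
  xcbt <- vapply(recs, `[[`, numeric(1), "max_cbt")
  csa <- vapply(recs, `[[`, numeric(1), "csa")
  pblp <- vapply(recs, `[[`, numeric(1), "pbl_points")
  expect_true(all(diff(acb) > 0))
  expect_true(all(diff(ci) > 0))
  expect_true(all(diff(mcbt) > 0))
  expect_true(all(diff(xcbt) > 0))
  expect_true(all(abs(csa - csa[1]) <= 0.2^2 * max(pblp)))  # within 1 px band
  expect_true(all(abs(pblp - pblp[1]) == 0))
})

test_that("standardization divides every parameter by the reference length", {
  rec <- data.frame(specimen_id = "s", level = 5L, csa = 700, acb = 390,
                    ci = 390 / 700, pbl = 90, mean_cbt = 6, max_cbt = 8)
  std <- standardize_record(rec, 420, kind = "total")
  expect_equal(std$mean_cbt_std, 6 / 420)
  expect_equal(std$mean_cbt_std, 0.014286, tolerance = 1e-4)
  expect_equal(std$csa_std, 700 / 420)
  expect_equal(std$ci, rec$ci)               # dimensionless, untouched
  expect_identical(std$reference_length_kind, "total")

  ident <- standardize_record(rec, 1, kind = "diaphyseal")
  expect_equal(ident$max_cbt_std, rec$max_cbt)
  expect_error(standardize_record(rec, -10), "positive")
  expect_error(standardize_record(rec, 0), "positive")
})

test_that("measure_specimen returns one record per requested level", {
  sp <- phantom_spec(n_slices = 19, outer_rx = 8, outer_ry = 8, thickness = 3)
  vol <- render_phantom(sp)$volume
  secs <- extract_sections(vol, plan_levels(vol, 1, 19))
  tab <- measure_specimen(secs, 100)
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$level, 2:9)
  # constant tube: identical records at all levels
  for (col in c("csa", "acb", "ci", "pbl", "mean_cbt", "max_cbt"))
    expect_true(all(tab[[col]] == tab[[col]][1]))
  expect_error(measure_specimen(secs[1:3], 100, levels = 2:9), "missing")
})
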
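# Synthetic femur phantoms: a bent hollow cortical tube in air with a marrow
# cavity, bimodal HU distribution, controllable cortical-thickness profile,
# anterior bow, an optional posterior ridge emulating the linea aspera, and
# the four lateral-curvature modes. Ground truth (areas, thickness, CMD
# centerline, deviation profile, pattern label) is derived from the analytic
# geometry, never from the rendered voxels.
#
# Curvature profiles are parameterized over the level-1 -> level-9 span
# (u = 0 at the level-1 slice, u = 1 at the level-9 slice), so both
# endpoints of the deviation baseline are zeros of the profile and the true
# per-level deviations are simply the profile values: a half-sine of
# amplitude A peaks at exactly A at level 5.

lateral_modes <- c("none", lateral_patterns)

#' Specify a femur phantom
#'
#' @param n_slices Number of axial slices (default 91).
#' @param in_plane_spacing In-plane pixel pitch, mm (default 0.2).
#' @param slice_thickness Slice spacing, mm (default 0.5).
#' @param outer_rx,outer_ry Outer semi-axes in mm (default 15, circular);
#'   either scalars or functions of the fractional axial position v in
#'   [0, 1] over the whole volume (for tapering shafts).
#' @param thickness Cortical thickness in mm (default 5); scalar or function
#'   of v. Must stay below `min(outer_rx, outer_ry)`.
#' @param ridge Optional posterior thickness bump emulating the linea
#'   aspera: `list(angle, halfwidth, extra)` with the center angle in
#'   radians (posterior is `-pi/2`), angular half-width in radians and extra
#'   thickness in mm. Requires circular sections.
#' @param bow_mm Anterior bow amplitude A_y, mm (half-sine, apex at mid
#'   diaphysis).
#' @param lateral_mode One of `"none"`, `"primary_lateral"`,
#'   `"primary_medial"`, `"s_lateral_medial"`, `"s_medial_lateral"`.
#'   Primary modes are half-sine, S modes full-sine, signed so that +x is
#'   lateral and the mode name gives the proximal side.
#' @param lateral_mm Lateral amplitude A_x, mm (>= 0).
#' @param hu_air,hu_marrow,hu_bone Hounsfield levels (defaults -1000, 0,
#'   +1200).
#' @param noise_sd Gaussian HU noise standard deviation (default 0).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @param z_upper,z_lower Landmark slice indices bounding the diaphysis
#'   (defaults: first and last slice).
#' @param side,specimen_id Metadata carried into the volume.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 91L, in_plane_spacing = 0.2,
                         slice_thickness = 0.5,
                         outer_rx = 15, outer_ry = 15, thickness = 5,
                         ridge = NULL, bow_mm = 0,
                         lateral_mode = "none", lateral_mm = 0,
                         hu_air = -1000, hu_marrow = 0, hu_bone = 1200,
                         noise_sd = 0, seed = NULL,
                         z_upper = 1L, z_lower = n_slices,
                         side = "right", specimen_id = "phantom") {
  lateral_mode <- match.arg(lateral_mode, lateral_modes)
  stopifnot(n_slices >= 19, in_plane_spacing > 0, slice_thickness > 0,
            bow_mm >= 0, lateral_mm >= 0, noise_sd >= 0)
  if (!(hu_bone > hu_marrow && hu_marrow > hu_air))
    stopf("HU levels must satisfy bone > marrow > air")
  if (!is.null(ridge)) {
    stopifnot(is.list(ridge), all(c("angle", "halfwidth", "extra") %in% names(ridge)),
              ridge$halfwidth > 0, ridge$extra >= 0)
    if (is.function(outer_rx) || is.function(outer_ry) ||
        !isTRUE(all.equal(outer_rx, outer_ry)))
      stopf("the ridge model requires circular sections (outer_rx == outer_ry)")
  }
  spec <- list(n_slices = as.integer(n_slices),
               in_plane_spacing = in_plane_spacing,
               slice_thickness = slice_thickness,
               outer_rx = outer_rx, outer_ry = outer_ry,
               thickness = thickness, ridge = ridge,
               bow_mm = bow_mm, lateral_mode = lateral_mode,
               lateral_mm = lateral_mm,
               hu_air = hu_air, hu_marrow = hu_marrow, hu_bone = hu_bone,
               noise_sd = noise_sd, seed = seed,
               z_upper = as.integer(z_upper), z_lower = as.integer(z_lower),
               side = side, specimen_id = specimen_id)
  # validate the thickness invariant over the whole shaft
  v <- seq(0, 1, length.out = 101)
  rx <- eval_profile(spec$outer_rx, v); ry <- eval_profile(spec$outer_ry, v)
  tt <- eval_profile(spec$thickness, v)
  extra <- if (is.null(ridge)) 0 else ridge$extra
  if (any(tt + extra >= pmin(rx, ry)))
    stopf("cortical thickness (plus ridge) must stay below the outer radius everywhere")
  structure(spec, class = "phantom_spec")
}

eval_profile <- function(p, v) {
  if (is.function(p)) vapply(v, p, numeric(1)) else rep(p, length(v))
}

# signed lateral profile g(u) for a mode, on u in [0, 1] over levels 1..9
lateral_profile <- function(mode, u) {
  switch(mode,
         none = rep(0, length(u)),
         primary_lateral  =  sin(pi * u),
         primary_medial   = -sin(pi * u),
         s_lateral_medial =  sin(2 * pi * u),
         s_medial_lateral = -sin(2 * pi * u))
}

ridge_bump <- function(theta, ridge) {
  if (is.null(ridge)) return(rep(0, length(theta)))
  d <- atan2(sin(theta - ridge$angle), cos(theta - ridge$angle))
  ifelse(abs(d) < ridge$halfwidth,
         ridge$extra * cos(pi * d / (2 * ridge$halfwidth))^2, 0)
}

# numeric (analytic-curve, not raster) thickness truth: minimum distance
# from sampled periosteal curve points to a densely sampled endosteal curve
curve_thickness_truth <- function(rx, ry, t, ridge, n_out = 720L, n_in = 2880L) {
  if (is.null(ridge) && isTRUE(all.equal(rx, ry))) {
    return(list(mean = t, max = t))
  }
  th_o <- seq(0, 2 * pi, length.out = n_out + 1L)[-1L]
  P <- cbind(rx * cos(th_o), ry * sin(th_o))
  th_i <- seq(0, 2 * pi, length.out = n_in + 1L)[-1L]
  if (is.null(ridge)) {
    E <- cbind((rx - t) * cos(th_i), (ry - t) * sin(th_i))
  } else {
    rin <- (rx - t) - ridge_bump(th_i, ridge)
    E <- cbind(rin * cos(th_i), rin * sin(th_i))
  }
  d2 <- outer(P[, 1], E[, 1], "-")^2 + outer(P[, 2], E[, 2], "-")^2
  th <- sqrt(apply(d2, 1, min))
  list(mean = mean(th), max = max(th))
}

#' Render a femur phantom and its ground truth
#'
#' Each slice is an (optionally eccentric, via the curved centerline)
#' elliptical annulus: bone HU inside the cortical shell, marrow HU inside
#' the cavity, air outside, plus optional seeded Gaussian noise. The truth
#' table is computed from the analytic geometry.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]), `truth` (list: per-level
#'   data.frame `levels` with true csa/acb/ci/thickness/CMD, data.frame
#'   `deviation` with the true per-level dx/dy for levels 1-9, `pattern`,
#'   `level_positions`), and `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$n_slices
  sp <- spec$in_plane_spacing
  z_all <- seq_len(nz)
  pos <- as.integer(round_half_up(spec$z_upper +
                                    (1:10 - 1) * (spec$z_lower - spec$z_upper) / 9))
  u_all <- (z_all - pos[1]) / (pos[9] - pos[1])
  v_all <- (z_all - 1) / (nz - 1)

  rx <- eval_profile(spec$outer_rx, v_all)
  ry <- eval_profile(spec$outer_ry, v_all)
  tt <- eval_profile(spec$thickness, v_all)
  cx <- spec$lateral_mm * lateral_profile(spec$lateral_mode, u_all)
  cy <- spec$bow_mm * sin(pi * u_all)

  half <- max(rx, ry) + max(abs(cx), abs(cy)) + 3
  hw <- ceiling(half / sp)
  n <- 2L * hw + 1L
  c0 <- hw * sp                      # physical center of the grid, mm
  X <- (seq_len(n) - 1) * sp

  vol <- array(spec$hu_air, dim = c(n, n, nz))
  for (z in z_all) {
    dx <- X - (c0 + cx[z])
    dy <- X - (c0 + cy[z])
    DX <- matrix(dx, n, n)
    DY <- matrix(dy, n, n, byrow = TRUE)
    outer_in <- (DX / rx[z])^2 + (DY / ry[z])^2 <= 1
    if (is.null(spec$ridge)) {
      cav <- (DX / (rx[z] - tt[z]))^2 + (DY / (ry[z] - tt[z]))^2 < 1
    } else {
      r <- sqrt(DX^2 + DY^2)
      theta <- atan2(DY, DX)
      cav <- r < (rx[z] - tt[z]) - ridge_bump(theta, spec$ridge)
    }
    sl <- matrix(spec$hu_air, n, n)
    sl[outer_in] <- spec$hu_bone
    sl[cav] <- spec$hu_marrow
    vol[, , z] <- sl
  }
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    vol <- vol + array(stats::rnorm(length(vol), sd = spec$noise_sd), dim = dim(vol))
  }
  volume <- ct_volume(vol, in_plane_spacing = sp,
                      slice_thickness = spec$slice_thickness,
                      side = spec$side, specimen_id = spec$specimen_id,
                      side_normalized = TRUE, check_air = FALSE)

  # ---- analytic truth ----
  lv <- 1:10
  vz <- v_all[pos]; uz <- u_all[pos]
  rxl <- eval_profile(spec$outer_rx, vz); ryl <- eval_profile(spec$outer_ry, vz)
  tl <- eval_profile(spec$thickness, vz)
  csa <- pi * rxl * ryl
  if (is.null(spec$ridge)) {
    cav_area <- pi * (rxl - tl) * (ryl - tl)
  } else {
    rin <- rxl - tl; e <- spec$ridge$extra; W <- spec$ridge$halfwidth
    cav_area <- pi * rin^2 - rin * e * W + (3 / 8) * e^2 * W
  }
  acb <- csa - cav_area
  thick <- lapply(seq_along(lv), function(i)
    curve_thickness_truth(rxl[i], ryl[i], tl[i], spec$ridge))
  cmx <- c0 + spec$lateral_mm * lateral_profile(spec$lateral_mode, uz)
  cmy <- c0 + spec$bow_mm * sin(pi * uz)
  levels_df <- data.frame(
    level = lv, slice = pos, z_mm = (pos - 1) * spec$slice_thickness,
    csa = csa, acb = acb, ci = acb / csa,
    mean_cbt = vapply(thick, `[[`, numeric(1), "mean"),
    max_cbt = vapply(thick, `[[`, numeric(1), "max"),
    cmd_x = cmx, cmd_y = cmy)
  dev_df <- data.frame(
    level = 1:9,
    dx = spec$lateral_mm * lateral_profile(spec$lateral_mode, uz[1:9]),
    dy = spec$bow_mm * sin(pi * uz[1:9]))
  pattern <- if (spec$lateral_mode == "none") "indeterminate" else spec$lateral_mode

  list(volume = volume,
       truth = list(levels = levels_df, deviation = dev_df,
                    pattern = pattern, level_positions = pos),
       spec = spec)
}

#' Render a single analytic annulus cross-section
#'
#' A circular annulus (optionally with the inner circle offset) rendered as
#' a `cross_section`, for oracle tests against the closed-form geometry.
#'
#' @param outer_mm,inner_mm Outer/inner radius in mm.
#' @param inner_offset_mm Length-2 offset of the inner circle center, mm.
#' @param spacing Pixel pitch, mm.
#' @param hu_bone,hu_bg,hu_cavity HU of the shell, the exterior, and the
#'   cavity (cavity defaults to the background value).
#' @param margin_mm Air margin around the annulus.
#' @param level,specimen_id Metadata.
#' @return A `cross_section`.
#' @export
render_annulus_section <- function(outer_mm = 15, inner_mm = 10,
                                   inner_offset_mm = c(0, 0), spacing = 0.2,
                                   hu_bone = 1200, hu_bg = -1000,
                                   hu_cavity = hu_bg, margin_mm = 3,
                                   level = 1L, specimen_id = "annulus") {
  stopifnot(inner_mm < outer_mm,
            sqrt(sum(inner_offset_mm^2)) + inner_mm < outer_mm)
  hw <- ceiling((outer_mm + margin_mm) / spacing)
  n <- 2L * hw + 1L
  c0 <- hw * spacing
  X <- (seq_len(n) - 1) * spacing
  DX <- matrix(X - c0, n, n)
  DY <- matrix(X - c0, n, n, byrow = TRUE)
  m <- matrix(hu_bg, n, n)
  m[DX^2 + DY^2 <= outer_mm^2] <- hu_bone
  m[(DX - inner_offset_mm[1])^2 + (DY - inner_offset_mm[2])^2 < inner_mm^2] <- hu_cavity
  structure(list(pixels = m, spacing = spacing, level = as.integer(level),
                 z_mm = 0, specimen_id = specimen_id),
            class = "cross_section")
}

#' Render a reproducible cohort of phantoms
#'
#' Renders `n_per_cohort[i]` phantoms per cohort from the corresponding base
#' spec, with optional between-specimen variation; per-specimen seeds are
#' derived deterministically from the master seed, so the same seed gives
#' bit-identical volumes.
#'
#' @param specs Named list of [phantom_spec()] objects, one per cohort.
#' @param n_per_cohort Integer vector (recycled/matched by name) of cohort
#'   sizes.
#' @param seed Master integer seed.
#' @param vary Optional list with elements `thickness_sd`, `bow_sd`,
#'   `lateral_sd` (mm): per-specimen Gaussian jitter of the scalar spec
#'   parameters (amplitudes truncated at zero, thickness kept inside the
#'   outer radius).
#' @return List with `phantoms` (each as [render_phantom()] plus `$cohort`)
#'   and `truth` (data.frame: specimen_id, cohort, true mean/max thickness at
#'   mid-shaft, bow and lateral amplitudes, pattern).
#' @export
render_cohort <- function(specs, n_per_cohort, seed, vary = NULL) {
  stopifnot(is.list(specs), length(specs) >= 1, !is.null(names(specs)))
  if (is.null(names(n_per_cohort))) names(n_per_cohort) <- names(specs)
  phantoms <- list()
  truth_rows <- list()
  idx <- 0L
  for (coh in names(specs)) {
    base <- specs[[coh]]
    n <- n_per_cohort[[coh]]
    if (is.null(n) || n == 0) next
    for (i in seq_len(n)) {
      idx <- idx + 1L
      s <- base
      s$seed <- derive_seed(seed, idx)
      s$specimen_id <- sprintf("%s_%02d", coh, i)
      if (!is.null(vary)) {
        set.seed(derive_seed(seed, 100000L + idx))
        if (!is.null(vary$thickness_sd) && !is.function(s$thickness)) {
          rmin <- min(eval_profile(s$outer_rx, c(0, .5, 1)),
                      eval_profile(s$outer_ry, c(0, .5, 1)))
          s$thickness <- min(max(0.5, s$thickness +
                                   stats::rnorm(1, sd = vary$thickness_sd)),
                             rmin - 1)
        }
        if (!is.null(vary$bow_sd))
          s$bow_mm <- max(0, s$bow_mm + stats::rnorm(1, sd = vary$bow_sd))
        if (!is.null(vary$lateral_sd))
          s$lateral_mm <- max(0, s$lateral_mm + stats::rnorm(1, sd = vary$lateral_sd))
      }
      class(s) <- "phantom_spec"
      ph <- render_phantom(s)
      ph$cohort <- coh
      phantoms[[s$specimen_id]] <- ph
      mid <- 5L   # mid-shaft level
      truth_rows[[s$specimen_id]] <- data.frame(
        specimen_id = s$specimen_id, cohort = coh,
        true_mean_cbt = ph$truth$levels$mean_cbt[mid],
        true_max_cbt = ph$truth$levels$max_cbt[mid],
        bow_mm = s$bow_mm, lateral_mm = s$lateral_mm,
        pattern = ph$truth$pattern)
    }
  }
  list(phantoms = phantoms, truth = do.call(rbind, truth_rows))
}
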
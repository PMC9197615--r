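# The six per-section morphometric parameters and their length-standardized
# forms:
#   csa      total cross-sectional area (periosteal interior), mm^2
#   acb      area of cortical bone, mm^2
#   ci       cortical index = acb / csa
#   pbl      periosteal border length (point-count convention), mm
#   mean_cbt / max_cbt   mean / maximum minimum-distance cortical thickness, mm

#' Total cross-sectional area
#'
#' Count of pixels enclosed by the periosteal perimeter (cavity included)
#' times the squared pixel pitch.
#'
#' @param mask A [segment_cortex()] result.
#' @return Area in mm^2.
#' @export
cross_sectional_area <- function(mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  sum(mask$section_region) * mask$spacing^2
}

#' Cortical bone area
#'
#' Count of pixels between the periosteal and endosteal perimeters times the
#' squared pixel pitch.
#'
#' @param mask A [segment_cortex()] result.
#' @return Area in mm^2.
#' @export
cortical_bone_area <- function(mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  sum(mask$cortex_region) * mask$spacing^2
}

#' Cortical index
#'
#' Ratio of cortical bone area to total cross-sectional area.
#'
#' @param acb Cortical bone area, mm^2.
#' @param csa Total cross-sectional area, mm^2 (> 0).
#' @return Dimensionless ratio in (0, 1].
#' @export
cortical_index <- function(acb, csa) {
  if (any(csa <= 0)) stopf("cross-sectional area must be positive")
  acb / csa
}

#' Periosteal border length
#'
#' The point-count convention: the number of distinct pixels on the
#' periosteal boundary times the pixel pitch. This matches the historical
#' spreadsheet measurement but underestimates oblique (e.g. circular)
#' boundaries by up to ~10%; a geometric perimeter (Kulpa-corrected
#' chain-code length of the boundary loop, accurate to ~1-2% on smooth
#' shapes) is reported alongside for diagnostics.
#'
#' @param mask A [segment_cortex()] result.
#' @return List with `n_points`, `pbl` (mm, point-count) and
#'   `perimeter_geometric` (mm).
#' @export
periosteal_border_length <- function(mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  pts <- mask$periosteal_points
  list(n_points = nrow(pts),
       pbl = nrow(pts) * mask$spacing,
       perimeter_geometric = chain_perimeter(mask$periosteal_loop) * mask$spacing)
}

# Kulpa-corrected chain-code length (pixel units) of a closed ordered loop:
# (straight + sqrt(2) * diagonal steps) * pi/8 * (1 + sqrt(2)) ~ 0.948,
# unbiased for smooth convex contours.
chain_perimeter <- function(loop) {
  n <- nrow(loop)
  if (n < 2) return(0)
  d <- rbind(loop[-1, , drop = FALSE] - loop[-n, , drop = FALSE],
             loop[1, ] - loop[n, ])
  steps <- sqrt(rowSums(d^2))
  sum(steps) * pi / 8 * (1 + sqrt(2))
}

#' Cortical bone thickness profile
#'
#' For every point on the periosteal surface, the cortical thickness is the
#' minimum Euclidean distance to the endosteal surface (pixel centers, no
#' sub-pixel interpolation), scaled to mm. The mean and maximum over all
#' periosteal points summarize the section.
#'
#' @param mask A [segment_cortex()] result with a non-empty endosteal
#'   boundary. Solid sections (no cavity) have undefined thickness and raise
#'   an error; callers should check `mask$solid`.
#' @return List with `thicknesses` (mm, one per periosteal point),
#'   `mean_cbt`, `max_cbt`.
#' @export
thickness_profile <- function(mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  if (mask$solid || is.null(mask$endosteal_points))
    stopf("section is solid (no medullary cavity): thickness is undefined")
  P <- mask$periosteal_points
  E <- mask$endosteal_points
  # min over endosteal points of squared distance, vectorized per coordinate
  d2 <- outer(P[, 1], E[, 1], "-")^2 + outer(P[, 2], E[, 2], "-")^2
  th <- sqrt(apply(d2, 1, min)) * mask$spacing
  list(thicknesses = th, mean_cbt = mean(th), max_cbt = max(th))
}

#' Measure all six parameters for one section
#'
#' @param mask A [segment_cortex()] result.
#' @return One-row data.frame: `level`, `csa`, `acb`, `ci`, `pbl`,
#'   `pbl_points`, `perimeter_geometric`, `mean_cbt`, `max_cbt`, `solid`,
#'   `threshold`. Thickness columns are `NA` for solid sections.
#' @export
measure_section <- function(mask) {
  stopifnot(inherits(mask, "cortex_mask"))
  csa <- cross_sectional_area(mask)
  acb <- cortical_bone_area(mask)
  p <- periosteal_border_length(mask)
  if (mask$solid) {
    mean_cbt <- NA_real_; max_cbt <- NA_real_
  } else {
    th <- thickness_profile(mask)
    mean_cbt <- th$mean_cbt; max_cbt <- th$max_cbt
  }
  data.frame(level = mask$level %||% NA_integer_,
             csa = csa, acb = acb, ci = cortical_index(acb, csa),
             pbl = p$pbl, pbl_points = p$n_points,
             perimeter_geometric = p$perimeter_geometric,
             mean_cbt = mean_cbt, max_cbt = max_cbt,
             solid = mask$solid, threshold = mask$threshold_used)
}

#' Measure a specimen across diaphyseal levels
#'
#' Segments and measures the requested levels (default 2-9, the eight
#' interior cross-sections used for morphometrics; curvature uses levels
#' 1-9 separately). Solid sections are measured but flagged, with a warning,
#' and excluded from thickness statistics downstream.
#'
#' @param sections List of `cross_section` objects covering the requested
#'   levels (as from [extract_sections()]).
#' @param threshold HU threshold from [derive_threshold()].
#' @param levels Integer levels to measure (default `2:9`).
#' @return data.frame with one row per requested level (columns as
#'   [measure_section()], plus `specimen_id`).
#' @export
measure_specimen <- function(sections, threshold, levels = 2:9) {
  lev_avail <- vapply(sections, function(s) s$level, integer(1))
  if (!all(levels %in% lev_avail))
    stopf("sections for levels %s are missing",
          paste(setdiff(levels, lev_avail), collapse = ", "))
  rows <- lapply(levels, function(l) {
    s <- sections[[which(lev_avail == l)[1]]]
    rec <- measure_section(segment_cortex(s, threshold))
    rec$specimen_id <- s$specimen_id
    rec
  })
  out <- do.call(rbind, rows)
  if (any(out$solid))
    warnf("specimen %s: %d solid section(s) at level(s) %s; thickness undefined there",
          out$specimen_id[1], sum(out$solid),
          paste(out$level[out$solid], collapse = ", "))
  out[, c("specimen_id", setdiff(names(out), "specimen_id"))]
}

#' Length-standardize a morphometric record
#'
#' Divides every parameter (areas included, following the direct-division
#' convention: standardized areas keep one leftover length dimension,
#' mm^2/mm) by a stated reference length. The cortical index is
#' dimensionless and is not divided.
#'
#' @param record data.frame from [measure_section()] / [measure_specimen()].
#' @param reference_length Femoral total length or diaphyseal length, mm (> 0).
#' @param kind `"total"` or `"diaphyseal"` -- which reference length is used;
#'   recorded in the output so analyses state their choice explicitly.
#' @return data.frame with columns `csa_std`, `acb_std`, `pbl_std`,
#'   `mean_cbt_std`, `max_cbt_std`, `ci` plus `reference_length_mm`,
#'   `reference_length_kind`, carried `specimen_id`/`level` when present.
#' @export
standardize_record <- function(record, reference_length,
                               kind = c("total", "diaphyseal")) {
  kind <- match.arg(kind)
  if (!is.numeric(reference_length) || length(reference_length) != 1L ||
      !is.finite(reference_length) || reference_length <= 0)
    stopf("reference_length must be a single positive number (mm)")
  out <- data.frame(
    csa_std = record$csa / reference_length,
    acb_std = record$acb / reference_length,
    pbl_std = record$pbl / reference_length,
    mean_cbt_std = record$mean_cbt / reference_length,
    max_cbt_std = record$max_cbt / reference_length,
    ci = record$ci,
    reference_length_mm = reference_length,
    reference_length_kind = kind)
  for (col in c("specimen_id", "level"))
    if (!is.null(record[[col]])) out[[col]] <- record[[col]]
  out
}
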
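# CT volume container, raw-bundle I/O, diaphyseal level planning and
# cross-section extraction.
#
# Conventions (used throughout the package):
#   * array axes are (x, y, z): x medial -> lateral after side normalization,
#     y posterior -> anterior, z proximal -> distal;
#   * indices are 1-based; the physical position of pixel i is
#     (i - 1) * spacing mm, i.e. pixel centers sit on the grid
#     0, spacing, 2*spacing, ...;
#   * left femurs are mirrored about the sagittal (x) axis on load so that
#     +x is lateral for every specimen.

#' Construct a CT volume
#'
#' Bundles a 3-D grid of Hounsfield units with its physical voxel spacing and
#' side label. Axes are ordered (x, y, z) with z running proximal to distal,
#' y posterior to anterior, and x medial to lateral once side-normalized.
#'
#' @param intensities 3-D numeric array of Hounsfield units, dim = (nx, ny, nz).
#' @param in_plane_spacing In-plane pixel pitch in mm (isotropic within slice).
#' @param slice_thickness Slice-to-slice spacing in mm.
#' @param side `"right"` or `"left"`. The constructor stores the label; side
#'   normalization (mirroring of left femurs) is performed by [load_volume()].
#' @param specimen_id Character label carried through all outputs.
#' @param side_normalized Logical; `TRUE` once +x is guaranteed lateral.
#' @param check_air If `TRUE`, verify that the modal intensity (the air
#'   background) lies within -1000 +/- 100 HU and warn otherwise.
#'
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(intensities, in_plane_spacing, slice_thickness,
                      side = c("right", "left"), specimen_id = "specimen",
                      side_normalized = FALSE, check_air = TRUE) {
  side <- match.arg(side)
  if (length(dim(intensities)) != 3L)
    stopf("intensities must be a 3-D array, got %d dimensions",
          length(dim(intensities)))
  if (!is.numeric(in_plane_spacing) || length(in_plane_spacing) != 1L ||
      !is.finite(in_plane_spacing) || in_plane_spacing <= 0)
    stopf("in_plane_spacing must be a single positive number")
  if (!is.numeric(slice_thickness) || length(slice_thickness) != 1L ||
      !is.finite(slice_thickness) || slice_thickness <= 0)
    stopf("slice_thickness must be a single positive number")
  if (in_plane_spacing < 0.158 || in_plane_spacing > 0.292)
    warnf("in-plane spacing %.3f mm is outside the usual clinical-CT range [0.158, 0.292] mm",
          in_plane_spacing)
  if (check_air) {
    # modal 10-HU bin of the whole volume should be the air background
    b <- round_half_up(intensities / 10) * 10
    tb <- table(b)
    air_mode <- as.numeric(names(tb)[which.max(tb)])
    if (abs(air_mode + 1000) > 100)
      warnf("background intensity mode %.0f HU is not within -1000 +/- 100 HU; check HU rescale",
            air_mode)
  }
  structure(
    list(intensities = intensities,
         in_plane_spacing = in_plane_spacing,
         slice_thickness = slice_thickness,
         side = side,
         side_normalized = side_normalized,
         specimen_id = specimen_id),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_volume> %s: %d x %d x %d voxels, %.3f mm/px, %.2f mm slices, side %s%s\n",
              x$specimen_id, d[1], d[2], d[3], x$in_plane_spacing,
              x$slice_thickness, x$side,
              if (x$side_normalized) " (side-normalized)" else ""))
  invisible(x)
}

# mirror about the sagittal plane so +x becomes lateral
mirror_x <- function(vol) {
  vol$intensities <- vol$intensities[rev(seq_len(dim(vol$intensities)[1])), , ,
                                     drop = FALSE]
  vol
}

#' Write a CT volume as a raw-array bundle
#'
#' A raw bundle is a directory with `volume.raw` (little-endian int16 HU) and
#' a JSON sidecar `volume.json` holding dims, spacing, slice thickness, side
#' and specimen id. This is the plain on-disk exchange format of the package;
#' [write_dicom_series()] offers DICOM export.
#'
#' @param volume A [ct_volume()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_raw_bundle <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  v <- as.integer(round_half_up(volume$intensities))
  if (any(v < -32768 | v > 32767)) stopf("HU values exceed int16 range")
  con <- file(file.path(path, "volume.raw"), "wb")
  on.exit(close(con))
  writeBin(v, con, size = 2L, endian = "little")
  sidecar <- list(specimen_id = volume$specimen_id,
                  dims = dim(volume$intensities),
                  spacing_mm = volume$in_plane_spacing,
                  slice_thickness_mm = volume$slice_thickness,
                  side = volume$side,
                  dtype = "int16", byte_order = "little")
  jsonlite::write_json(sidecar, file.path(path, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_raw_bundle <- function(path) {
  sc_path <- file.path(path, "volume.json")
  if (!file.exists(sc_path)) stopf("raw bundle sidecar not found: %s", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (f in c("dims", "spacing_mm", "slice_thickness_mm"))
    if (is.null(sc[[f]])) stopf("raw bundle sidecar is missing '%s'", f)
  dims <- as.integer(sc$dims)
  n <- prod(dims)
  con <- file(file.path(path, "volume.raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, what = "integer", n = n, size = 2L, signed = TRUE,
               endian = "little")
  if (length(v) != n)
    stopf("raw bundle has %d voxels, sidecar promises %d", length(v), n)
  ct_volume(array(as.numeric(v), dim = dims),
            in_plane_spacing = sc$spacing_mm,
            slice_thickness = sc$slice_thickness_mm,
            side = sc$side %||% "right",
            specimen_id = sc$specimen_id %||% basename(path))
}

#' Load a CT volume from disk
#'
#' Accepts either a raw-array bundle (directory containing `volume.raw` +
#' `volume.json`, see [write_raw_bundle()]) or a directory of uncompressed
#' explicit-VR little-endian DICOM slices. Slices are sorted proximal to
#' distal, the DICOM HU rescale (slope/intercept) is applied, and left femurs
#' are mirrored about the sagittal axis so that +x is lateral.
#'
#' @param path Directory holding the bundle or DICOM series.
#' @param side Optional override of the side label (`"right"`/`"left"`); by
#'   default taken from the sidecar (raw bundles) or assumed `"right"`
#'   (DICOM without a laterality tag).
#' @return A side-normalized [ct_volume()].
#' @export
load_volume <- function(path, side = NULL) {
  if (!dir.exists(path)) stopf("no such directory: %s", path)
  vol <- if (file.exists(file.path(path, "volume.json"))) {
    read_raw_bundle(path)
  } else {
    read_dicom_series(path)
  }
  if (!is.null(side)) vol$side <- match.arg(side, c("right", "left"))
  if (identical(vol$side, "left")) vol <- mirror_x(vol)
  vol$side_normalized <- TRUE
  vol
}

#' Plan the ten diaphyseal levels between two landmarks
#'
#' The span between the lower end of the lesser trochanter (`z_upper`) and
#' the adductor tubercle (`z_lower`) is divided into nine equal segments;
#' the ten bounding cross-sections are labeled level 1 (proximal) to level 10
#' (distal). Positions are rounded to the nearest slice (half up); with
#' 0.5 mm slices the rounding error in any morphometric parameter is well
#' under one percent, so no sub-slice interpolation is performed.
#'
#' @param volume A [ct_volume()].
#' @param z_upper,z_lower 1-based slice indices of the two landmarks,
#'   `z_upper < z_lower`.
#' @return A `level_plan`: list with `z_upper`, `z_lower`, integer
#'   `positions` (length 10), and `slice_thickness`.
#' @export
plan_levels <- function(volume, z_upper, z_lower) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$intensities)[3]
  if (z_upper < 1 || z_lower > nz)
    stopf("landmarks [%d, %d] fall outside the volume (1..%d)",
          z_upper, z_lower, nz)
  if (!(z_upper < z_lower))
    stopf("z_upper (%d) must lie above z_lower (%d)", z_upper, z_lower)
  if (z_lower - z_upper < 18)
    stopf("landmark span of %d slices is too short to place 10 distinct levels",
          z_lower - z_upper)
  k <- 1:10
  pos <- as.integer(round_half_up(z_upper + (k - 1) * (z_lower - z_upper) / 9))
  stopifnot(pos[1] == z_upper, pos[10] == z_lower, all(diff(pos) > 0))
  structure(list(z_upper = as.integer(z_upper), z_lower = as.integer(z_lower),
                 positions = pos, slice_thickness = volume$slice_thickness),
            class = "level_plan")
}

#' Extract per-level cross-sections
#'
#' @param volume A [ct_volume()].
#' @param plan A [plan_levels()] result.
#' @param levels Integer subset of 1..10 to extract (default all ten).
#' @return A list of `cross_section` objects (fields `pixels`, `spacing`,
#'   `level`, `z_mm`, `specimen_id`), one per requested level.
#' @export
extract_sections <- function(volume, plan, levels = 1:10) {
  stopifnot(inherits(volume, "ct_volume"), inherits(plan, "level_plan"))
  if (!all(levels %in% 1:10)) stopf("levels must be within 1..10")
  lapply(levels, function(l) {
    z <- plan$positions[l]
    structure(
      list(pixels = volume$intensities[, , z],
           spacing = volume$in_plane_spacing,
           level = as.integer(l),
           z_mm = (z - 1) * volume$slice_thickness,
           specimen_id = volume$specimen_id),
      class = "cross_section")
  })
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %s level %d: %d x %d px @ %.3f mm, z = %.1f mm\n",
              x$specimen_id, x$level, nrow(x$pixels), ncol(x$pixels),
              x$spacing, x$z_mm))
  invisible(x)
}
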
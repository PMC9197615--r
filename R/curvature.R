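# Central mass distribution (CMD) and diaphyseal curvature.
#
# The CMD of a section is the intersection of the vertical and horizontal
# lines that each split the section area into equal halves (an equal-area
# point, distinct from the centroid for asymmetric sections). Connecting the
# CMDs of levels 1-9 gives the CMD curve; per-level x/y shifts from the
# straight baseline through the level-1 and level-9 CMDs quantify lateral
# (x, + = lateral) and anterior (y, + = anterior) curvature.

# equal-area split along one margin of a pixel-count vector; pixel centers of
# index i sit at (i - 1), so column i spans [(i - 1.5), (i - 0.5)] + 0.5.
# The crossing is located from both ends and averaged, so a flat stretch of
# the cumulative sum (disjoint lobes) splits at its midpoint.
equal_area_split <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stopf("empty region")
  target <- total / 2
  cross <- function(cnt) {
    cs <- cumsum(cnt)
    j <- which(cs >= target)[1]
    prev <- if (j > 1) cs[j - 1] else 0
    f <- (target - prev) / cnt[j]       # cnt[j] > 0 since cs crossed here
    (j - 1) - 0.5 + f                   # 0-based physical pixel coordinate
  }
  lo <- cross(counts)
  hi <- (length(counts) - 1) - cross(rev(counts))
  (lo + hi) / 2
}

#' Central mass distribution of a section
#'
#' Computes the equal-area point of the filled section region (periosteal
#' interior): the abscissa of the vertical line and the ordinate of the
#' horizontal line that each divide the region's area into equal halves,
#' located with sub-pixel linear interpolation of the cumulative column/row
#' area sums. Computed on the filled section by default; set
#' `region = "cortex"` to use cortical pixels only.
#'
#' @param mask A [segment_cortex()] result.
#' @param region `"section"` (default) or `"cortex"`.
#' @return List with `x_mm`, `y_mm` (physical coordinates within the section
#'   grid, pixel i at (i-1)*spacing) and `x_px`, `y_px` (0-based pixel
#'   coordinates).
#' @export
compute_cmd <- function(mask, region = c("section", "cortex")) {
  stopifnot(inherits(mask, "cortex_mask"))
  region <- match.arg(region)
  m <- if (region == "section") mask$section_region else mask$cortex_region
  if (!any(m)) stopf("empty region")
  x_px <- equal_area_split(rowSums(m))
  y_px <- equal_area_split(colSums(m))
  list(x_px = x_px, y_px = y_px,
       x_mm = x_px * mask$spacing, y_mm = y_px * mask$spacing)
}

#' CMD deviation profile of a specimen
#'
#' Given the CMDs of levels 1-9, deviations are measured from the 3-D
#' straight line through the level-1 and level-9 CMDs, parameterized by z:
#' `dx` is the lateral (+) / medial (-) shift and `dy` the anterior (+) /
#' posterior (-) shift of each level's CMD from that baseline. Deviations at
#' levels 1 and 9 are zero by construction. Normalized shifts divide by a
#' stated reference length; the anterior-curvature degree is summarized as
#' the maximum normalized `dy` across levels.
#'
#' @param cmds data.frame with columns `level` (must cover exactly 1..9),
#'   `x` and `y` (mm, CMD coordinates) and `z` (mm along the bone axis).
#' @param reference_length Femoral (or diaphyseal) length in mm used for
#'   normalization.
#' @param epsilon Deadband (mm) below which a lateral shift is treated as
#'   zero when classifying the pattern; default 0.3 mm (one to two pixels at
#'   clinical CT resolution).
#' @return A `deviation_profile`: data.frame `profile` (level, z, x, y, dx,
#'   dy, dx_norm, dy_norm), scalar `anterior_degree` (max normalized dy),
#'   `pattern` (see [classify_lateral_pattern()]), `reference_length`,
#'   `epsilon`.
#' @export
deviation_profile <- function(cmds, reference_length, epsilon = 0.3) {
  need <- c("level", "x", "y", "z")
  if (!all(need %in% names(cmds))) stopf("cmds must have columns %s",
                                         paste(need, collapse = ", "))
  cmds <- cmds[order(cmds$level), , drop = FALSE]
  if (!identical(as.integer(cmds$level), 1:9))
    stopf("deviation profile requires CMDs for exactly levels 1..9")
  if (any(!is.finite(cmds$z)) || any(diff(cmds$z) <= 0))
    stopf("CMD z positions must be finite and strictly increasing")
  if (!is.numeric(reference_length) || reference_length <= 0)
    stopf("reference_length must be positive")

  w <- (cmds$z - cmds$z[1]) / (cmds$z[9] - cmds$z[1])
  dx <- cmds$x - ((1 - w) * cmds$x[1] + w * cmds$x[9])
  dy <- cmds$y - ((1 - w) * cmds$y[1] + w * cmds$y[9])
  dx[c(1L, 9L)] <- 0; dy[c(1L, 9L)] <- 0   # exact at baseline endpoints

  prof <- data.frame(level = 1:9, z = cmds$z, x = cmds$x, y = cmds$y,
                     dx = dx, dy = dy,
                     dx_norm = dx / reference_length,
                     dy_norm = dy / reference_length)
  structure(list(profile = prof,
                 anterior_degree = max(prof$dy_norm),
                 pattern = classify_lateral_pattern(dx, epsilon = epsilon),
                 reference_length = reference_length,
                 epsilon = epsilon),
            class = "deviation_profile")
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf("<deviation_profile> pattern %s, anterior degree %.4g (ref %.0f mm, eps %.2f mm)\n",
              x$pattern, x$anterior_degree, x$reference_length, x$epsilon))
  print(x$profile, digits = 4)
  invisible(x)
}

#' Four-way lateral curvature pattern
#'
#' Classifies the lateral deviation profile from the signs of `dx` at the
#' interior levels 2-8, after zeroing shifts smaller than `epsilon`:
#' all non-negative with at least one positive is a lateral primary curve;
#' all non-positive with at least one negative a medial primary curve; a
#' single sign change is S-shaped, named by the proximal sign
#' (`s_lateral_medial` = lateral at the top); all-zero or more than one sign
#' change is indeterminate.
#'
#' @param x A `deviation_profile`, or a numeric `dx` vector (length 9,
#'   levels 1-9, or length 7, levels 2-8) in mm.
#' @param epsilon Deadband in mm (default 0.3).
#' @return One of `"primary_lateral"`, `"primary_medial"`,
#'   `"s_lateral_medial"`, `"s_medial_lateral"`, `"indeterminate"`.
#' @export
classify_lateral_pattern <- function(x, epsilon = 0.3) {
  dx <- if (inherits(x, "deviation_profile")) x$profile$dx else x
  if (length(dx) == 9L) dx <- dx[2:8]
  if (length(dx) != 7L) stopf("expected dx for levels 2-8 (7 values) or 1-9 (9 values)")
  s <- sign(dx)
  s[abs(dx) < epsilon] <- 0
  if (all(s == 0)) return("indeterminate")
  if (all(s >= 0)) return("primary_lateral")
  if (all(s <= 0)) return("primary_medial")
  nz <- s[s != 0]
  changes <- sum(diff(nz) != 0)
  if (changes == 1L) {
    if (nz[1] > 0) "s_lateral_medial" else "s_medial_lateral"
  } else {
    "indeterminate"
  }
}

lateral_patterns <- c("primary_lateral", "primary_medial",
                      "s_lateral_medial", "s_medial_lateral")

#' Cohort-by-pattern contingency table
#'
#' Counts classified lateral patterns per cohort. The four defined patterns
#' are always present as columns (zero-filled); indeterminate profiles are
#' counted in a separate final column and reported, not silently dropped.
#'
#' @param patterns Character vector of pattern labels (from
#'   [classify_lateral_pattern()]).
#' @param cohorts Factor or character vector of cohort labels, same length.
#' @return Integer matrix, rows = cohorts, columns = the four patterns plus
#'   `indeterminate`.
#' @export
pattern_table <- function(patterns, cohorts) {
  stopifnot(length(patterns) == length(cohorts))
  pf <- factor(patterns, levels = c(lateral_patterns, "indeterminate"))
  if (anyNA(pf)) stopf("unknown pattern label(s): %s",
                       paste(unique(patterns[is.na(pf)]), collapse = ", "))
  cf <- if (is.factor(cohorts)) cohorts else factor(cohorts, levels = unique(cohorts))
  tab <- table(cohort = cf, pattern = pf)
  matrix(as.integer(tab), nrow = nlevels(cf),
         dimnames = list(levels(cf), levels(pf)))
}

#' End-to-end curvature profile of a CT volume
#'
#' Convenience wrapper: plans levels, extracts sections 1-9, derives the
#' pooled-histogram threshold (from all ten levels), segments, computes the
#' CMDs and returns the deviation profile.
#'
#' @param volume A side-normalized [ct_volume()].
#' @param z_upper,z_lower Landmark slice indices (see [plan_levels()]).
#' @param reference_length Normalizing length in mm.
#' @param epsilon Deadband in mm for pattern classification.
#' @param threshold Optional HU threshold; derived from the pooled histogram
#'   of levels 1-10 when `NULL`.
#' @return A `deviation_profile`.
#' @export
curvature_profile <- function(volume, z_upper, z_lower, reference_length,
                              epsilon = 0.3, threshold = NULL) {
  plan <- plan_levels(volume, z_upper, z_lower)
  if (is.null(threshold)) {
    sections10 <- extract_sections(volume, plan, 1:10)
    threshold <- derive_threshold(pool_histogram(sections10))
    sections <- sections10[1:9]
  } else {
    sections <- extract_sections(volume, plan, 1:9)
  }
  cmds <- do.call(rbind, lapply(sections, function(s) {
    cmd <- compute_cmd(segment_cortex(s, threshold))
    data.frame(level = s$level, x = cmd$x_mm, y = cmd$y_mm, z = s$z_mm)
  }))
  deviation_profile(cmds, reference_length = reference_length, epsilon = epsilon)
}
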
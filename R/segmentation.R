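# Cortical-bone segmentation: pooled HU histogram over the ten levels, the
# two-peak threshold, and per-section cortex masks with ordered periosteal
# and endosteal boundary loops.
#
# Connectivity convention: foreground (bone) regions are 8-connected, the
# background and interior holes are 4-connected -- the standard dual pairing
# that prevents both the region and the cavity from leaking through diagonal
# gaps.

# 8-connected labeling built on EBImage::bwlabel (which is 4-connected):
# label 4-connected components, then merge labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nrow(lab), -ncol(lab)]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nrow(lab), -1]), as.vector(lab[-1, -ncol(lab)])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

largest_label <- function(lab) {
  if (max(lab) == 0L) return(NULL)
  counts <- tabulate(lab[lab > 0])
  which.max(counts)
}

# ordered outer boundary loop of a single connected region, 1-based (x, y)
boundary_loop <- function(mask) {
  oc <- EBImage::ocontour(ifelse(mask, 1L, 0L))
  if (length(oc) == 0) return(NULL)
  loop <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1L  # 0-based -> 1-based
  colnames(loop) <- c("x", "y")
  loop
}

#' Pool the HU histogram over a set of cross-sections
#'
#' All pixels of all supplied sections are pooled into one Hounsfield-unit
#' frequency table. Two peaks are located: the air peak (highest-count bin at
#' or below -500 HU) and the bone peak (highest-count bin at or above
#' +200 HU), each refined as the count-weighted mean over +/- 5 neighbouring
#' bins so that the peak means are robust to bin placement.
#'
#' @param sections List of `cross_section` objects (or a single one).
#' @param bin_width Histogram bin width in HU (default 10).
#' @return An `hu_histogram`: list with `bin_width`, `bin_edges`, `counts`,
#'   `peak1_mean` (air), `peak2_mean` (bone).
#' @export
pool_histogram <- function(sections, bin_width = 10) {
  if (inherits(sections, "cross_section")) sections <- list(sections)
  if (length(sections) == 0) stopf("at least one cross-section is required")
  stopifnot(bin_width > 0)
  v <- unlist(lapply(sections, function(s) as.vector(s$pixels)),
              use.names = FALSE)
  # bins centered on multiples of bin_width, so a delta mass at -1000 HU
  # yields a peak mean of exactly -1000
  lo <- (round_half_up(min(v) / bin_width) - 0.5) * bin_width
  idx <- floor((v - lo) / bin_width) + 1L
  counts <- tabulate(idx)
  centers <- lo + (seq_along(counts) - 0.5) * bin_width
  edges <- lo + (0:length(counts)) * bin_width

  refine <- function(i) {
    win <- max(1L, i - 5L):min(length(counts), i + 5L)
    sum(centers[win] * counts[win]) / sum(counts[win])
  }
  air_bins <- which(centers <= -500)
  bone_bins <- which(centers >= 200)
  if (length(air_bins) == 0 || sum(counts[air_bins]) == 0)
    stopf("histogram has no air peak at or below -500 HU; check HU rescale")
  if (length(bone_bins) == 0 || sum(counts[bone_bins]) == 0)
    stopf("histogram is unimodal (no counts at or above +200 HU): no bone present")
  p1 <- refine(air_bins[which.max(counts[air_bins])])
  p2 <- refine(bone_bins[which.max(counts[bone_bins])])
  if (abs(p1 + 1000) > 150)
    warnf("air peak at %.0f HU is outside -1000 +/- 150 HU", p1)
  structure(list(bin_width = bin_width, bin_edges = edges, counts = counts,
                 peak1_mean = p1, peak2_mean = p2),
            class = "hu_histogram")
}

#' Derive the cortical-bone threshold from a pooled histogram
#'
#' The threshold is the midpoint of the air-peak and bone-peak means: a
#' symmetric, parameter-free rule. The value is carried in every mask's
#' metadata so alternative rules remain comparable.
#'
#' @param hist An [pool_histogram()] result.
#' @return Threshold in HU.
#' @export
derive_threshold <- function(hist) {
  stopifnot(inherits(hist, "hu_histogram"))
  if (!(hist$peak1_mean < hist$peak2_mean))
    stopf("air peak (%.0f HU) must lie below the bone peak (%.0f HU)",
          hist$peak1_mean, hist$peak2_mean)
  (hist$peak1_mean + hist$peak2_mean) / 2
}

#' Segment the cortical shell of one cross-section
#'
#' Pixels at or above the threshold are foreground; the largest 8-connected
#' foreground component is the cortical shell (isolated bone-valued specks
#' are discarded). The section region is that component with all interior
#' holes filled; the largest interior hole (4-connected) is the medullary
#' cavity, and smaller holes (trabecular voids) are merged into the cortex.
#' Periosteal and endosteal boundaries are returned as ordered, closed
#' 8-connected pixel loops. Sections without any interior cavity are flagged
#' `solid`; their thickness is undefined rather than invented.
#'
#' @param section A `cross_section`.
#' @param threshold HU threshold, typically from [derive_threshold()].
#' @return A `cortex_mask`: logical grids `section_region` and
#'   `cortex_region`, ordered loops `periosteal_loop` / `endosteal_loop`,
#'   unique point sets `periosteal_points` / `endosteal_points` (1-based
#'   pixel coordinates), `spacing`, `threshold_used`, `solid`, `level`,
#'   `specimen_id`.
#' @export
segment_cortex <- function(section, threshold) {
  stopifnot(inherits(section, "cross_section"))
  fg <- section$pixels >= threshold
  if (!any(fg)) stopf("no foreground at threshold %.1f HU", threshold)
  lab <- label8(fg)
  main <- largest_label(lab)
  cortex0 <- lab == main

  filled <- EBImage::fillHull(ifelse(cortex0, 1L, 0L)) > 0
  holes <- filled & !cortex0
  solid <- !any(holes)
  if (solid) {
    cavity <- matrix(FALSE, nrow(fg), ncol(fg))
    cortex <- filled
    endo_loop <- NULL
  } else {
    hlab <- EBImage::bwlabel(holes)           # 4-connected holes
    cavity <- hlab == largest_label(hlab)
    cortex <- filled & !cavity                # smaller holes merged into cortex
    endo_loop <- boundary_loop(cavity)
  }
  peri_loop <- boundary_loop(filled)

  structure(
    list(section_region = filled,
         cortex_region = cortex,
         periosteal_loop = peri_loop,
         endosteal_loop = endo_loop,
         periosteal_points = unique(peri_loop),
         endosteal_points = if (is.null(endo_loop)) NULL else unique(endo_loop),
         spacing = section$spacing,
         threshold_used = threshold,
         solid = solid,
         level = section$level,
         specimen_id = section$specimen_id),
    class = "cortex_mask")
}

#' @export
print.cortex_mask <- function(x, ...) {
  cat(sprintf("<cortex_mask> %s level %s: %d section px, %d cortex px, threshold %.1f HU%s\n",
              x$specimen_id, x$level %||% "?", sum(x$section_region),
              sum(x$cortex_region), x$threshold_used,
              if (x$solid) " [solid]" else ""))
  invisible(x)
}

#' Threshold report
#'
#' JSON-serializable summary of the threshold derivation for provenance.
#'
#' @param hist An [pool_histogram()] result.
#' @param file Optional path; when given, the report is written as JSON.
#' @return A list with peak means, bin width and threshold (invisibly when
#'   written to file).
#' @export
threshold_report <- function(hist, file = NULL) {
  rep <- list(peak_air_hu = hist$peak1_mean,
              peak_bone_hu = hist$peak2_mean,
              bin_width_hu = hist$bin_width,
              threshold_hu = derive_threshold(hist))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}

#' Export a cortex mask's boundary points as a data frame
#'
#' One row per boundary pixel in loop order, with pixel and physical (mm)
#' coordinates; suitable for writing to CSV.
#'
#' @param mask A [segment_cortex()] result.
#' @param which `"periosteal"` or `"endosteal"`.
#' @return A data.frame with `x_px`, `y_px`, `x_mm`, `y_mm`.
#' @export
boundary_points_df <- function(mask, which = c("periosteal", "endosteal")) {
  which <- match.arg(which)
  loop <- if (which == "periosteal") mask$periosteal_loop else mask$endosteal_loop
  if (is.null(loop)) stopf("mask has no %s boundary", which)
  data.frame(x_px = loop[, 1], y_px = loop[, 2],
             x_mm = (loop[, 1] - 1) * mask$spacing,
             y_mm = (loop[, 2] - 1) * mask$spacing)
}
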
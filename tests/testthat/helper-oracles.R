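# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive quantities with plain loops / enumeration so the
# implementation is checked against a second, independent route.

# wrap an HU matrix as a cross_section
make_section <- function(pixels, spacing = 0.2, level = 1L, id = "fixture") {
  structure(list(pixels = pixels, spacing = spacing, level = as.integer(level),
                 z_mm = 0, specimen_id = id),
            class = "cross_section")
}

# wrap a logical mask as a minimal cortex_mask (for CMD tests)
make_mask <- function(section_region, spacing = 1) {
  structure(list(section_region = section_region,
                 cortex_region = section_region,
                 spacing = spacing, threshold_used = NA_real_, solid = TRUE),
            class = "cortex_mask")
}

# loop-based equal-area split along a margin (same interpolation formula,
# independent implementation): crossing located from both ends and averaged
brute_split <- function(counts) {
  cross <- function(cnt) {
    target <- sum(cnt) / 2
    cum <- 0; j <- 0
    repeat {
      j <- j + 1
      cum <- cum + cnt[j]
      if (cum >= target) break
    }
    (j - 1) - 0.5 + (target - (cum - cnt[j])) / cnt[j]
  }
  lo <- cross(counts)
  hi <- (length(counts) - 1) - cross(rev(counts))
  (lo + hi) / 2
}

brute_cmd <- function(mask) {
  colcounts <- integer(nrow(mask))
  rowcounts <- integer(ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        colcounts[i] <- colcounts[i] + 1L
        rowcounts[j] <- rowcounts[j] + 1L
      }
    }
  c(x = brute_split(colcounts), y = brute_split(rowcounts))
}

# enumerate boundary pixels: region pixels with at least one 4-neighbour
# outside the region (or on the image border)
brute_boundary_count <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  cnt <- 0L
  for (i in seq_len(nx))
    for (j in seq_len(ny)) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
              if (i < nx) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE,
              if (j < ny) mask[i, j + 1] else FALSE)
      if (any(!nb)) cnt <- cnt + 1L
    }
  cnt
}

# all-pairs minimum distance, double loop
brute_thickness <- function(P, E, spacing) {
  th <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    best <- Inf
    for (j in seq_len(nrow(E))) {
      d <- sqrt((P[i, 1] - E[j, 1])^2 + (P[i, 2] - E[j, 2])^2)
      if (d < best) best <- d
    }
    th[i] <- best * spacing
  }
  th
}

# random blob mask: union of random disks on an n x n grid
random_blob <- function(n = 120, n_disks = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  xx <- matrix(rep(seq_len(n), n), n, n)
  yy <- t(xx)
  for (k in seq_len(n_disks)) {
    cx <- runif(1, 0.25 * n, 0.75 * n)
    cy <- runif(1, 0.25 * n, 0.75 * n)
    r <- runif(1, 0.08 * n, 0.2 * n)
    m <- m | ((xx - cx)^2 + (yy - cy)^2 <= r^2)
  }
  m
}

# HU image of a hollow blob (shell between two offset disks) for
# segmentation fixtures
annulus_hu <- function(outer_px, inner_px, n = NULL, center = NULL,
                       inner_center = NULL, bone = 1200, bg = -1000) {
  n <- n %||% (2L * outer_px + 11L)
  center <- center %||% c((n + 1) / 2, (n + 1) / 2)
  inner_center <- inner_center %||% center
  xx <- matrix(rep(seq_len(n), n), n, n)
  yy <- t(xx)
  m <- matrix(bg, n, n)
  m[(xx - center[1])^2 + (yy - center[2])^2 <= outer_px^2] <- bone
  m[(xx - inner_center[1])^2 + (yy - inner_center[2])^2 < inner_px^2] <- bg
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
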
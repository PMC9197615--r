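# Minimal DICOM support: uncompressed 16-bit MONOCHROME2 CT slices in the
# explicit-VR little-endian transfer syntax (1.2.840.10008.1.2.1). This
# covers the series this package writes and typical single-frame clinical CT
# exports; compressed or implicit-VR files are rejected with a clear error.
#
# Pixel order: DICOM PixelData is row-major (row = y, column = x); in-memory
# sections are (x, y) matrices, so Columns = nx and Rows = ny.

DICOM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_ROOT <- "1.2.826.0.1.3680043.10763"

uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("%s.%d.%d", UID_ROOT, as.integer(Sys.time()) %% 100000L, i)
  }
})

# ---- writing ---------------------------------------------------------------

pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

dcm_element <- function(group, elem, vr, value_raw) {
  value_raw <- pad_even(value_raw,
                        pad = if (vr %in% c("UI", "OB")) as.raw(0L)
                              else charToRaw(" "))
  head <- c(writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2L, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
      value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us  <- function(group, elem, v)
  dcm_element(group, elem, "US",
              writeBin(as.integer(v), raw(), size = 2L, endian = "little"))

#' Write a CT volume as a DICOM series
#'
#' Emits one uncompressed explicit-VR little-endian file per slice
#' (`slice_0001.dcm`, ...), 16-bit unsigned pixels with
#' RescaleIntercept -1024 / RescaleSlope 1 so stored values are HU + 1024.
#'
#' @param volume A [ct_volume()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dicom_series <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$intensities)
  series_uid <- uid_counter()
  study_uid <- uid_counter()
  for (z in seq_len(d[3])) {
    m <- volume$intensities[, , z]
    stored <- as.integer(round_half_up(m)) + 1024L
    if (any(stored < 0L | stored > 65535L))
      stopf("HU values outside the storable range [-1024, 64511]")
    write_dicom_slice(file.path(path, sprintf("slice_%04d.dcm", z)),
                      stored_matrix = matrix(stored, d[1], d[2]),
                      spacing = volume$in_plane_spacing,
                      slice_thickness = volume$slice_thickness,
                      z_mm = (z - 1) * volume$slice_thickness,
                      instance = z, series_uid = series_uid,
                      study_uid = study_uid,
                      side = volume$side,
                      rescale_intercept = -1024, rescale_slope = 1)
  }
  invisible(path)
}

# stored_matrix: (nx, ny) integer matrix of already-rescaled stored values
write_dicom_slice <- function(file, stored_matrix, spacing, slice_thickness,
                              z_mm, instance, series_uid, study_uid,
                              side = "right",
                              rescale_intercept = -1024, rescale_slope = 1) {
  nx <- nrow(stored_matrix); ny <- ncol(stored_matrix)
  sop_uid <- uid_counter()
  px <- writeBin(as.integer(stored_matrix), raw(), size = 2L, endian = "little")

  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_str(0x0008, 0x0018, "UI", sop_uid),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0018, 0x0050, "DS", format(slice_thickness)),
    dcm_str(0x0020, 0x000D, "UI", study_uid),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0013, "IS", format(instance)),
    dcm_str(0x0020, 0x0032, "DS", sprintf("0\\0\\%s", format(z_mm))),
    dcm_str(0x0020, 0x0060, "CS", if (identical(side, "left")) "L" else "R"),
    dcm_us (0x0028, 0x0002, 1L),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us (0x0028, 0x0010, ny),            # Rows
    dcm_us (0x0028, 0x0011, nx),            # Columns
    dcm_str(0x0028, 0x0030, "DS", sprintf("%s\\%s", format(spacing), format(spacing))),
    dcm_us (0x0028, 0x0100, 16L),
    dcm_us (0x0028, 0x0101, 16L),
    dcm_us (0x0028, 0x0102, 15L),
    dcm_us (0x0028, 0x0103, 0L),
    dcm_str(0x0028, 0x1052, "DS", format(rescale_intercept)),
    dcm_str(0x0028, 0x1053, "DS", format(rescale_slope)),
    dcm_element(0x7FE0, 0x0010, "OW", px))

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_str(0x0002, 0x0003, "UI", sop_uid),
    dcm_str(0x0002, 0x0010, "UI", DICOM_EXPLICIT_LE),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1")))
  group_len <- dcm_element(0x0002, 0x0000, "UL",
                           writeBin(length(meta), raw(), size = 4L,
                                    endian = "little"))

  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, ds), con)
  invisible(file)
}

# ---- reading ---------------------------------------------------------------

rd_u16 <- function(r, off) {
  as.integer(r[off]) + 256L * as.integer(r[off + 1L])
}
rd_u32 <- function(r, off) {
  sum(as.numeric(r[off + 0:3]) * c(1, 256, 65536, 16777216))
}

read_dicom_file <- function(file) {
  r <- readBin(file, "raw", n = file.info(file)$size)
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stopf("%s is not a DICOM part-10 file", basename(file))
  off <- 133L
  tags <- new.env(parent = emptyenv())
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    if (off + 7L > length(r)) break
    group <- rd_u16(r, off); elem <- rd_u16(r, off + 2L)
    vr <- rawToChar(r[off + 4:5])
    if (!grepl("^[A-Z]{2}$", vr))
      stopf("%s: implicit-VR or compressed transfer syntax is not supported",
            basename(file))
    if (vr %in% long_vrs) {
      len <- rd_u32(r, off + 8L); voff <- off + 12L
    } else {
      len <- rd_u16(r, off + 6L); voff <- off + 8L
    }
    val <- if (len > 0) r[voff:(voff + len - 1L)] else raw(0)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, raw = val)
    off <- voff + len
    if (group == 0x7FE0 && elem == 0x0010) break
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$raw[t$raw != as.raw(0L)]))
  }
  get_num <- function(key) {
    s <- get_str(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    rd_u16(t$raw, 1L)
  }

  ts <- get_str("0002,0010")
  if (!is.null(ts) && ts != DICOM_EXPLICIT_LE)
    stopf("%s: transfer syntax %s is not supported (explicit VR little endian only)",
          basename(file), ts)
  rows <- get_us("0028,0010"); cols <- get_us("0028,0011")
  spacing <- get_num("0028,0030")
  if (is.null(spacing)) stopf("%s: PixelSpacing (0028,0030) missing", basename(file))
  slope <- get_num("0028,1053"); intercept <- get_num("0028,1052")
  if (is.null(slope) || is.null(intercept))
    stopf("%s: HU rescale metadata (0028,1052/1053) missing", basename(file))
  pix <- tags[["7FE0,0010"]]
  if (is.null(pix)) stopf("%s: PixelData missing", basename(file))
  bits <- get_us("0028,0100") %||% 16L
  if (bits != 16L) stopf("%s: only 16-bit pixel data is supported", basename(file))
  signed <- isTRUE((get_us("0028,0103") %||% 0L) == 1L)
  n <- rows * cols
  stored <- readBin(pix$raw, "integer", n = n, size = 2L, signed = signed,
                    endian = "little")
  if (!signed) stored <- ifelse(stored < 0L, stored + 65536L, stored)
  ipp <- get_num("0020,0032")
  list(
    pixels = matrix(stored * slope + intercept, nrow = cols, ncol = rows),
    spacing = spacing,
    slice_thickness = get_num("0018,0050"),
    z_mm = if (!is.null(ipp)) ipp[3] else NA_real_,
    instance = get_num("0020,0013"),
    series_uid = get_str("0020,000E"),
    laterality = get_str("0020,0060"))
}

read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) {
    # accept extensionless DICOM files by magic number
    cand <- list.files(path, full.names = TRUE)
    files <- cand[vapply(cand, function(f) {
      r <- try(readBin(f, "raw", n = 132L), silent = TRUE)
      !inherits(r, "try-error") && length(r) == 132L &&
        rawToChar(r[129:132]) == "DICM"
    }, logical(1))]
  }
  if (length(files) == 0) stopf("no DICOM files found in %s", path)
  slices <- lapply(files, read_dicom_file)

  uids <- unique(vapply(slices, function(s) s$series_uid %||% "", character(1)))
  if (length(uids) > 1L) stopf("mixed DICOM series in %s: %s", path,
                               paste(uids, collapse = ", "))
  spac <- t(vapply(slices, function(s) s$spacing, numeric(2)))
  if (any(abs(spac - spac[1, 1]) > 1e-9))
    stopf("inconsistent or anisotropic PixelSpacing across slices")
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims != dims[, 1])) stopf("inconsistent slice dimensions")

  z <- vapply(slices, function(s) s$z_mm, numeric(1))
  ord <- if (all(is.finite(z))) order(z)
         else order(vapply(slices, function(s) s$instance %||% NA_real_, numeric(1)))
  slices <- slices[ord]
  z <- z[ord]
  if (length(z) > 2 && all(is.finite(z))) {
    gaps <- diff(z)
    if (max(gaps) - min(gaps) > 0.01 * mean(gaps))
      stopf("slice spacing varies by more than 1%% across the series")
  }
  thick <- slices[[1]]$slice_thickness
  if (is.null(thick) || !is.finite(thick)) {
    if (length(z) > 1 && all(is.finite(z))) thick <- mean(diff(z))
    else stopf("slice thickness metadata missing")
  }
  lat <- slices[[1]]$laterality
  arr <- array(NA_real_, dim = c(dims[1, 1], dims[2, 1], length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]$pixels
  ct_volume(arr, in_plane_spacing = spac[1, 1], slice_thickness = thick,
            side = if (identical(lat, "L")) "left" else "right",
            specimen_id = basename(path))
}
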
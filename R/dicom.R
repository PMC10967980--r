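# Minimal single-frame CT DICOM support: uncompressed little-endian transfer
# syntaxes only (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1),
# MONOCHROME2, 16-bit pixels. Enough to round-trip series written by
# write_dicom_series() and to read plain scanner exports; compressed or
# big-endian files are rejected with a format error.

TS_IMPLICIT <- "1.2.840.10008.1.2"
TS_EXPLICIT <- "1.2.840.10008.1.2.1"
CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

uint16_le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
uint32_le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# pad string to even length; UI pads with NUL, text VRs with space
dcm_str <- function(s, vr) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L)
    b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
  b
}

# one explicit-VR little-endian element
dcm_element <- function(group, elem, vr, bytes) {
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(uint16_le(group), uint16_le(elem), charToRaw(vr),
    if (long_form) c(as.raw(c(0, 0)), uint32_le(length(bytes)))
    else uint16_le(length(bytes)),
    bytes)
}

dcm_element_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, dcm_str(s, vr))
dcm_element_us  <- function(group, elem, x) dcm_element(group, elem, "US", uint16_le(x))

random_uid <- function(prefix = "2.25") {
  paste0(prefix, ".", paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

#' Write a CT slice stack as a DICOM series
#'
#' Writes one single-frame, explicit-VR little-endian MONOCHROME2 DICOM file
#' per slice into `dir`, with the given rescale metadata and axial slice
#' positions. Intended for building small synthetic series (fixtures,
#' phantoms); it emits only the core CT attributes.
#'
#' @param voxels 3-D integer array ordered slice x row x col; values must fit
#'   a signed 16-bit integer.
#' @param dir output directory (created if absent).
#' @param rescale_slope,rescale_intercept scanner rescale so that
#'   `HU = stored * slope + intercept`.
#' @param spacing mm along (slice, row, col).
#' @param series_uid series instance UID; one is generated by default.
#' @return invisibly, the written file paths in slice order.
#' @export
write_dicom_series <- function(voxels, dir, rescale_slope = 1,
                               rescale_intercept = -1024,
                               spacing = c(1, 1, 1),
                               series_uid = random_uid()) {
  stopifnot(length(dim(voxels)) == 3L)
  if (any(voxels < -32768) || any(voxels > 32767))
    stop("stored values must fit int16", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ns <- dim(voxels)[1L]
  study_uid <- random_uid()
  paths <- character(ns)
  for (i in seq_len(ns)) {
    slice <- voxels[i, , , drop = TRUE]
    if (is.null(dim(slice))) dim(slice) <- dim(voxels)[2:3]
    sop_uid <- random_uid()
    # pixel data is row-major top-left first: transpose the column-major matrix
    pix <- writeBin(as.integer(t(slice)), raw(), size = 2, endian = "little")
    ds <- c(
      dcm_element_str(0x0008, 0x0016, "UI", CT_SOP_CLASS),
      dcm_element_str(0x0008, 0x0018, "UI", sop_uid),
      dcm_element_str(0x0008, 0x0060, "CS", "CT"),
      dcm_element_str(0x0018, 0x0050, "DS", format(spacing[1])),
      dcm_element_str(0x0020, 0x000D, "UI", study_uid),
      dcm_element_str(0x0020, 0x000E, "UI", series_uid),
      dcm_element_str(0x0020, 0x0013, "IS", as.character(i)),
      dcm_element_str(0x0020, 0x0032, "DS",
                      paste(0, 0, format((i - 1) * spacing[1]), sep = "\\")),
      dcm_element_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcm_element_us(0x0028, 0x0002, 1L),
      dcm_element_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element_us(0x0028, 0x0010, nrow(slice)),
      dcm_element_us(0x0028, 0x0011, ncol(slice)),
      dcm_element_str(0x0028, 0x0030, "DS",
                      paste(format(spacing[2]), format(spacing[3]), sep = "\\")),
      dcm_element_us(0x0028, 0x0100, 16L),
      dcm_element_us(0x0028, 0x0101, 16L),
      dcm_element_us(0x0028, 0x0102, 15L),
      dcm_element_us(0x0028, 0x0103, 1L),
      dcm_element_str(0x0028, 0x1052, "DS", format(rescale_intercept)),
      dcm_element_str(0x0028, 0x1053, "DS", format(rescale_slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pix)
    )
    meta_body <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element_str(0x0002, 0x0002, "UI", CT_SOP_CLASS),
      dcm_element_str(0x0002, 0x0003, "UI", sop_uid),
      dcm_element_str(0x0002, 0x0010, "UI", TS_EXPLICIT),
      dcm_element_str(0x0002, 0x0012, "UI", "2.25.0.1")
    )
    meta <- c(dcm_element(0x0002, 0x0000, "UL", uint32_le(length(meta_body))),
              meta_body)
    paths[i] <- file.path(dir, sprintf("slice_%04d.dcm", i))
    con <- file(paths[i], "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
  }
  invisible(paths)
}

# ---- reading -----------------------------------------------------------

read_u16 <- function(b, at) readBin(b[at:(at + 1L)], "integer", size = 2,
                                    signed = FALSE, endian = "little")
read_u32 <- function(b, at) {
  v <- readBin(b[at:(at + 3L)], "integer", size = 4, endian = "little")
  if (v < 0) v + 2^32 else as.numeric(v)
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse elements of one dataset fragment; returns named list "gggg,eeee" -> raw
parse_dicom_elements <- function(b, at, end, explicit, stop_after_group = NULL) {
  out <- list()
  while (at + 7L <= end) {
    group <- read_u16(b, at); elem <- read_u16(b, at + 2L)
    if (!is.null(stop_after_group) && group > stop_after_group) break
    if (explicit && !(group == 0xFFFE)) {
      vr <- rawToChar(b[(at + 4L):(at + 5L)])
      if (vr %in% LONG_VRS) {
        len <- read_u32(b, at + 8L); hdr <- 12L
      } else {
        len <- read_u16(b, at + 6L); hdr <- 8L
      }
    } else {
      len <- read_u32(b, at + 4L); hdr <- 8L
      vr <- NA_character_
    }
    at <- at + hdr
    if (len == 0xFFFFFFFF || (!is.na(vr) && vr == "SQ")) {
      # undefined-length sequence: scan for the sequence delimitation item
      at <- skip_undefined(b, at, end)
      next
    }
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- if (len > 0L) b[at:(at + len - 1L)] else raw(0)
    at <- at + len
  }
  list(elements = out, at = at)
}

skip_undefined <- function(b, at, end) {
  while (at + 7L <= end) {
    g <- read_u16(b, at); e <- read_u16(b, at + 2L)
    len <- read_u32(b, at + 4L)
    at <- at + 8L
    if (g == 0xFFFE && e == 0xE0DD) return(at)
    if (g == 0xFFFE && e == 0xE000) {
      if (len == 0xFFFFFFFF) at <- skip_undefined(b, at, end) else at <- at + len
    } else {
      at <- at + len
    }
  }
  at
}

dcm_chr <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NA_character_)
  trimws(gsub("\\x00", "", rawToChar(v), fixed = TRUE))
}
dcm_num <- function(el, key) {
  s <- dcm_chr(el, key)
  if (is.na(s) || s == "") return(NA_real_)
  as.numeric(strsplit(s, "\\", fixed = TRUE)[[1]])
}
dcm_u16 <- function(el, key) {
  v <- el[[key]]
  if (is.null(v)) return(NA_integer_)
  read_u16(v, 1L)
}

read_dicom_file <- function(path) {
  b <- readBin(path, raw(), file.info(path)$size)
  if (length(b) < 140L) stop("too short to be DICOM", call. = FALSE)
  if (rawToChar(b[129:132]) == "DICM") {
    meta <- parse_dicom_elements(b, 133L, length(b), explicit = TRUE,
                                 stop_after_group = 0x0002)
    ts <- dcm_chr(meta$elements, "0002,0010")
    at <- meta$at
  } else {
    ts <- TS_IMPLICIT   # headerless implicit-VR stream
    at <- 1L
  }
  if (!ts %in% c(TS_IMPLICIT, TS_EXPLICIT))
    stop(sprintf("unsupported transfer syntax %s in %s", ts, path), call. = FALSE)
  el <- parse_dicom_elements(b, at, length(b), explicit = (ts == TS_EXPLICIT))$elements
  rows <- dcm_u16(el, "0028,0010"); cols <- dcm_u16(el, "0028,0011")
  bits <- dcm_u16(el, "0028,0100")
  if (is.na(rows) || is.na(cols) || is.null(el[["7FE0,0010"]]))
    stop("missing image attributes", call. = FALSE)
  if (!identical(bits, 16L))
    stop(sprintf("only 16-bit pixel data is supported (got %s)", bits), call. = FALSE)
  signed <- identical(dcm_u16(el, "0028,0103"), 1L)
  pix <- readBin(el[["7FE0,0010"]], "integer", n = rows * cols, size = 2,
                 signed = signed, endian = "little")
  if (length(pix) < rows * cols) stop("truncated pixel data", call. = FALSE)
  ipp <- dcm_num(el, "0020,0032")
  list(
    pixels = t(matrix(pix, nrow = cols, ncol = rows)),  # row-major on disk
    series_uid = dcm_chr(el, "0020,000E"),
    instance = suppressWarnings(as.integer(dcm_chr(el, "0020,0013"))),
    position_z = if (length(ipp) >= 3 && all(is.finite(ipp))) ipp[3] else NA_real_,
    slope = dcm_num(el, "0028,1053")[1],
    intercept = dcm_num(el, "0028,1052")[1],
    pixel_spacing = dcm_num(el, "0028,0030"),
    slice_thickness = dcm_num(el, "0018,0050")[1]
  )
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(read_dicom_file(f), error = function(e) NULL)
    if (!is.null(s)) { s$file <- f; slices[[length(slices) + 1L]] <- s }
  }
  if (!length(slices))
    stop(sprintf("no readable DICOM files in directory: %s", dir), call. = FALSE)
  uids <- vapply(slices, function(s) s$series_uid %||% NA_character_, character(1))
  if (length(unique(stats::na.omit(uids))) > 1L)
    stop(sprintf("directory %s mixes multiple DICOM series: %s",
                 dir, toString(unique(uids))), call. = FALSE)
  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1L)
    stop(sprintf("inconsistent slice shapes in %s: %s", dir, toString(unique(shapes))),
         call. = FALSE)
  z <- vapply(slices, function(s) s$position_z, numeric(1))
  inst <- vapply(slices, function(s) s$instance %||% NA_integer_, integer(1))
  ord <- order(ifelse(is.na(z), 0, z), ifelse(is.na(inst), 0L, inst))
  slices <- slices[ord]
  d <- dim(slices[[1]]$pixels)
  vox <- array(0L, c(length(slices), d[1], d[2]))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$pixels
  slope <- slices[[1]]$slope; if (!is.finite(slope)) slope <- 1
  inter <- slices[[1]]$intercept; if (!is.finite(inter)) inter <- 0
  ps <- slices[[1]]$pixel_spacing
  if (length(ps) < 2 || any(!is.finite(ps))) ps <- c(1, 1)
  zs <- sort(z[is.finite(z)])
  dz <- if (length(zs) >= 2) mean(diff(zs)) else slices[[1]]$slice_thickness
  if (!is.finite(dz) || dz <= 0) dz <- 1
  new_raw_volume(vox, slope, inter, c(dz, ps[1], ps[2]))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
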
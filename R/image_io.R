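#' Read a CT volume from a DICOM series directory or a NIfTI file
#'
#' Returns the stored scanner integers together with the rescale metadata
#' needed to convert them to Hounsfield units, as a `raw_volume` object. For a
#' DICOM series the slices are ordered by their spatial position along the
#' slice axis (ascending), ties broken by instance number; all files must
#' belong to the same series. For NIfTI the third array dimension is taken as
#' the slice axis and values are assumed to already carry no scanner rescale
#' unless the header's scl_slope/scl_inter say otherwise.
#'
#' @param path a directory containing one DICOM series, or a single
#'   `.nii`/`.nii.gz` file.
#' @return a `raw_volume`: list with `voxels` (3-D integer array ordered
#'   slice x row x col), `rescale_slope`, `rescale_intercept`, `spacing`
#'   (mm along slice, row, col) and `axis_order = "slice,row,col"`.
#' @seealso [to_hu()] to extract one slice in Hounsfield units.
#' @export
read_volume <- function(path) {
  if (length(path) != 1L || !is.character(path))
    stop("`path` must be a single file or directory path", call. = FALSE)
  if (dir.exists(path)) {
    return(read_dicom_series(path))
  }
  if (!file.exists(path))
    stop(sprintf("volume not found: %s", path), call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop(sprintf("unrecognized volume format (expected DICOM directory or NIfTI file): %s", path),
         call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("failed to read NIfTI file %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 2-D or 3-D NIfTI volume, got %d dimensions in %s",
                 length(dim(arr)), path), call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L) pd <- c(pd, rep(1, 3L - length(pd)))
  hdr <- RNifti::niftiHeader(img)
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  if (!is.finite(slope) || slope == 0) slope <- 1
  if (!is.finite(inter)) inter <- 0
  new_raw_volume(
    voxels = aperm(arr, c(3L, 1L, 2L)),
    rescale_slope = slope,
    rescale_intercept = inter,
    spacing = c(pd[3L], pd[1L], pd[2L])
  )
}

new_raw_volume <- function(voxels, rescale_slope, rescale_intercept, spacing) {
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L), all(spacing > 0))
  storage.mode(voxels) <- "integer"
  structure(
    list(voxels = voxels,
         rescale_slope = as.numeric(rescale_slope),
         rescale_intercept = as.numeric(rescale_intercept),
         spacing = as.numeric(spacing),
         axis_order = "slice,row,col"),
    class = "raw_volume"
  )
}

#' @export
print.raw_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<raw_volume> %d slice(s) of %dx%d, slope=%g intercept=%g, spacing=%s mm\n",
              d[1], d[2], d[3], x$rescale_slope, x$rescale_intercept,
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Number of slices in a raw volume
#' @param v a `raw_volume`.
#' @return integer slice count.
#' @export
n_slices <- function(v) {
  stopifnot(inherits(v, "raw_volume"))
  dim(v$voxels)[1L]
}

#' Convert one stored slice to Hounsfield units
#'
#' Applies the scanner rescale `HU = stored * slope + intercept` element-wise
#' to the requested slice.
#'
#' @param v a `raw_volume` from [read_volume()].
#' @param slice_index 1-based slice index.
#' @return numeric matrix of HU values (rows x cols).
#' @examples
#' v <- with(list(a = array(c(0L, 1024L), c(1, 1, 2))),
#'           ctenhance:::new_raw_volume(a, 1, -1024, c(1, 1, 1)))
#' to_hu(v, 1)  # -1024 and 0 HU
#' @export
to_hu <- function(v, slice_index) {
  stopifnot(inherits(v, "raw_volume"))
  ns <- n_slices(v)
  if (length(slice_index) != 1L || slice_index < 1L || slice_index > ns)
    stop(sprintf("slice_index %s out of range [1, %d]",
                 toString(slice_index), ns), call. = FALSE)
  slice <- v$voxels[slice_index, , , drop = TRUE]
  if (is.null(dim(slice))) dim(slice) <- dim(v$voxels)[2:3]
  slice * v$rescale_slope + v$rescale_intercept
}

#' Min-max normalization of an HU slice to 8-bit
#'
#' Affine map of the slice's own `[min, max]` onto `[0, 255]`, rounded
#' half-up. A constant slice maps to all zeros (any constant is equally
#' uninformative and this avoids 0/0). This is the plain "normalization"
#' conversion that serves as the unenhanced baseline of the pipeline.
#'
#' @param img numeric HU matrix.
#' @return integer byte-image matrix; on non-constant input both 0 and 255
#'   are attained.
#' @export
normalize_minmax <- function(img) {
  assert_hu_image(img)
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    out <- matrix(0L, nrow(img), ncol(img))
    return(out)
  }
  as_byte((img - lo) / (hi - lo) * 255)
}

#' Write / read an 8-bit grayscale PNG
#'
#' Lossless round-trip of a byte image through PNG.
#'
#' @param img integer matrix with values in 0..255.
#' @param path output `.png` path.
#' @return `write_png()` invisibly returns `path`; `read_png_byte()` returns
#'   the integer matrix.
#' @export
write_png <- function(img, path) {
  assert_byte_image(img)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png_byte <- function(path) {
  if (!file.exists(path)) stop(sprintf("PNG not found: %s", path), call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  as_byte(a * 255)
}

#' Write / read a binary segmentation mask
#'
#' Masks use 1 = foreground. On disk, PNG masks hold {0, 255} and NIfTI masks
#' hold {0, 1}; both read back to a {0, 1} integer matrix. Files holding any
#' other value are rejected.
#'
#' @param mask integer matrix with values in {0, 1}.
#' @param path a `.png` or `.nii`/`.nii.gz` path.
#' @return `write_mask()` invisibly returns `path`; `read_mask()` returns the
#'   {0, 1} integer matrix.
#' @export
write_mask <- function(mask, path) {
  assert_binary_mask(mask)
  if (grepl("\\.png$", path)) {
    png::writePNG(mask * 1.0, path)
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    m <- mask
    storage.mode(m) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(m, datatype = "uint8"), path)
  } else {
    stop(sprintf("unsupported mask format (use .png or .nii/.nii.gz): %s", path),
         call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("mask not found: %s", path), call. = FALSE)
  if (grepl("\\.png$", path)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    lv <- as_byte(a * 255)
    bad <- setdiff(unique(as.vector(lv)), c(0L, 255L))
    if (length(bad))
      stop(sprintf("PNG mask %s holds values other than {0, 255}: %s",
                   path, toString(utils::head(bad, 5))), call. = FALSE)
    out <- (lv == 255L) * 1L
  } else if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- as.array(RNifti::readNifti(path))
    a <- drop(a)
    if (length(dim(a)) != 2L)
      stop(sprintf("expected a 2-D NIfTI mask in %s", path), call. = FALSE)
    bad <- setdiff(unique(as.vector(a)), c(0, 1))
    if (length(bad))
      stop(sprintf("NIfTI mask %s holds values other than {0, 1}: %s",
                   path, toString(utils::head(bad, 5))), call. = FALSE)
    out <- matrix(as.integer(a), nrow(a), ncol(a))
  } else {
    stop(sprintf("unsupported mask format: %s", path), call. = FALSE)
  }
  storage.mode(out) <- "integer"
  out
}
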
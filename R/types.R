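#' Image conventions used throughout ctenhance
#'
#' Images are plain R matrices with pixel (1,1) at the top-left, rows indexed
#' top-to-bottom and columns left-to-right. Three kinds of matrix move through
#' the pipeline:
#'
#' * **HU image** — a numeric matrix of Hounsfield units, the native CT scale
#'   (water = 0, air about -1000, cortical bone up to about 3071). Diffusion
#'   and window leveling operate here.
#' * **byte image** — an integer matrix with every value in 0..255, the 8-bit
#'   display domain. Histogram equalization, blending and PNG export operate
#'   here.
#' * **binary mask** — an integer matrix with every value in {0, 1};
#'   1 marks foreground (e.g. liver).
#'
#' Whenever a real value becomes an 8-bit level anywhere in the package it is
#' rounded half-up and clamped to 0..255; one rule for the whole artifact.
#'
#' @name image-conventions
#' @keywords internal
NULL

#' Round half-up
#'
#' `round()` in R rounds half-to-even; every quantization to 8-bit in this
#' package instead rounds .5 upward so that e.g. 127.5 becomes 128.
#'
#' @param x numeric vector or matrix.
#' @return `x` rounded to the nearest integer, ties upward.
#' @examples
#' round_half_up(c(0.5, 1.5, 127.5, -0.5))
#' @export
round_half_up <- function(x) floor(x + 0.5)

clamp_byte <- function(x) pmin(pmax(x, 0), 255)

#' Quantize real values to 8-bit levels
#'
#' Round half-up, then clamp to 0..255. Returns an integer matrix (a byte
#' image) when given a matrix.
#'
#' @param x numeric vector or matrix.
#' @return integer vector or matrix with all values in 0..255.
#' @export
as_byte <- function(x) {
  out <- clamp_byte(round_half_up(x))
  storage.mode(out) <- "integer"
  out
}

assert_hu_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix of HU values", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(img)
}

assert_byte_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be an integer matrix", arg), call. = FALSE)
  if (any(img != as.integer(img)) || any(img < 0L) || any(img > 255L))
    stop(sprintf("`%s` must hold integers in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("`%s` must be an integer matrix", arg), call. = FALSE)
  if (!all(mask %in% c(0L, 1L)))
    stop(sprintf("`%s` must hold only 0 and 1", arg), call. = FALSE)
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}
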
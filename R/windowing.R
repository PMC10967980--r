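#' HU display window specification
#'
#' A window maps the HU interval `[center - width/2, center + width/2]`
#' linearly onto the 8-bit display range; HU values outside saturate to 0 or
#' 255. Narrow windows spend the whole gray range on a small HU interval and
#' therefore amplify contrast inside it. The default (center 60 HU, width
#' 200 HU) is a conventional liver window separating liver parenchyma
#' (~40-70 HU) from hypodense lesions and surrounding soft tissue.
#'
#' @param center window level in HU.
#' @param width window width in HU, > 0.
#' @return a `window_spec` list with `center`, `width` and `out_max = 255L`.
#' @export
window_spec <- function(center = 60, width = 200) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("window `width` must be a single positive number", call. = FALSE)
  if (!is.numeric(center) || length(center) != 1L)
    stop("window `center` must be a single number", call. = FALSE)
  structure(list(center = center, width = width, out_max = 255L),
            class = "window_spec")
}

#' Slope and intercept of the window's display mapping
#'
#' The linear branch of window leveling is `g/w * x + (w/2 - c) * g/w` with
#' `g = 255`; this returns that `(slope, intercept)` pair.
#'
#' @param spec a [window_spec()].
#' @return named numeric vector `c(slope, intercept)`.
#' @examples
#' display_affine(window_spec(center = 127.5, width = 255))  # identity
#' @export
display_affine <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  g <- spec$out_max
  slope <- g / spec$width
  c(slope = slope, intercept = (spec$width / 2 - spec$center) * slope)
}

#' Window leveling: map an HU slice to 8-bit through a display window
#'
#' Piecewise map: 0 below the window, 255 above it, and the linear
#' [display_affine()] branch inside (boundary HU values `c - w/2` and
#' `c + w/2` belong to the linear branch and map to exactly 0 and 255).
#' Results are rounded half-up to integer levels.
#'
#' @param img numeric HU matrix.
#' @param spec a [window_spec()].
#' @return integer byte-image matrix.
#' @examples
#' window_level(matrix(c(-1000, 60, 1200), 1), window_spec(60, 200))
#' @export
window_level <- function(img, spec = window_spec()) {
  assert_hu_image(img)
  stopifnot(inherits(spec, "window_spec"))
  af <- display_affine(spec)
  lo <- spec$center - spec$width / 2
  hi <- spec$center + spec$width / 2
  y <- af[["slope"]] * img + af[["intercept"]]
  y[img < lo] <- 0
  y[img > hi] <- spec$out_max
  as_byte(y)
}
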
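#' Gray-level histogram of an 8-bit image
#'
#' @param img integer matrix with values in 0..255.
#' @return list with `counts` (length-256 integer vector, `counts[k+1]` is
#'   the number of pixels at level `k`) and `total` (pixel count).
#' @export
gray_histogram <- function(img) {
  assert_byte_image(img)
  list(counts = tabulate(as.vector(img) + 1L, nbins = 256L),
       total = length(img))
}

#' Cumulative distribution of a gray-level histogram
#'
#' `s[k+1]` is the fraction of pixels at level `<= k`, computed as cumulative
#' counts divided once by the total so the last entry is exactly 1.
#'
#' @param h a histogram from [gray_histogram()].
#' @return length-256 numeric vector, non-decreasing, ending at 1.
#' @export
cumulative_distribution <- function(h) {
  if (!is.list(h) || is.null(h$counts) || is.null(h$total))
    stop("`h` must come from gray_histogram()", call. = FALSE)
  if (h$total <= 0) stop("cannot equalize an empty image", call. = FALSE)
  cumsum(h$counts) / h$total
}

#' Equalization lookup table from a cumulative distribution
#'
#' Maps level `k` to `round_half_up(s_k * 255)` over L = 256 levels. The LUT
#' is monotone non-decreasing and sends the highest occupied input level
#' to 255.
#'
#' @param s cumulative distribution from [cumulative_distribution()].
#' @return length-256 integer vector with entries in 0..255.
#' @export
equalization_map <- function(s) {
  if (length(s) != 256L || is.unsorted(s) || abs(s[256L] - 1) > 1e-12)
    stop("`s` must be a monotone length-256 cumulative distribution ending at 1",
         call. = FALSE)
  as.integer(as_byte(s * 255))
}

#' Global histogram equalization
#'
#' Remaps gray levels through the image's own cumulative distribution so the
#' output histogram is approximately uniform, revealing detail hidden in
#' crowded intensity ranges. All pixels participate (no background
#' exclusion): this is the deliberately global contrast path.
#'
#' @param img integer matrix with values in 0..255.
#' @return equalized byte-image matrix, same shape.
#' @examples
#' img <- matrix(c(0L, 0L, 1L, 255L), 2, 2, byrow = TRUE)
#' equalize(img)
#' @export
equalize <- function(img) {
  assert_byte_image(img)
  lut <- equalization_map(cumulative_distribution(gray_histogram(img)))
  out <- matrix(lut[img + 1L], nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  out
}
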
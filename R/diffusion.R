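#' Anisotropic diffusion parameters
#'
#' Perona-Malik diffusion is controlled by the edge-stopping scale `kappa`
#' (in HU, since diffusion runs on the HU slice before any 8-bit conversion),
#' the integration weight `lambda` and the iteration count. Gradients much
#' larger than `kappa` are treated as edges and conduct almost nothing, so
#' larger `kappa` smooths more aggressively. `lambda` is capped at 1/4: the
#' update sums four unit-bounded fluxes, and `lambda <= 1/4` makes every
#' updated pixel a convex combination of its neighbourhood, which guarantees
#' the min/max principle and unconditional stability.
#'
#' @param kappa edge-stopping scale in HU, > 0. Default 30.
#' @param lambda step weight in (0, 0.25]. Default 0.25.
#' @param iterations number of diffusion steps, >= 1. Default 15.
#' @return a `diffusion_params` list.
#' @export
diffusion_params <- function(kappa = 30, lambda = 0.25, iterations = 15L) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 0.25)
    stop("`lambda` must lie in (0, 0.25]", call. = FALSE)
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      iterations < 1 || iterations != as.integer(iterations))
    stop("`iterations` must be a positive integer", call. = FALSE)
  structure(list(kappa = kappa, lambda = lambda,
                 iterations = as.integer(iterations)),
            class = "diffusion_params")
}

# shift with replicate (Neumann) padding; border-facing gradients become 0
shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

#' Four-direction nearest-neighbour differences
#'
#' For each pixel, the difference `I(neighbour) - I(pixel)` toward the north
#' (row above), south (row below), east (column right) and west (column left)
#' neighbour. Borders use replicate padding, so gradients that face outward
#' are exactly zero.
#'
#' @param img numeric matrix.
#' @return named list of four matrices: `north`, `south`, `east`, `west`.
#' @export
directional_gradients <- function(img) {
  assert_hu_image(img)
  list(north = shift_up(img) - img,
       south = shift_down(img) - img,
       east  = shift_right(img) - img,
       west  = shift_left(img) - img)
}

#' Perona-Malik conduction coefficients
#'
#' The exponential edge-stopping function `exp(-(g/kappa)^2)` applied
#' element-wise to a gradient array. Values lie in (0, 1]: 1 on flat regions,
#' near 0 across strong edges, so diffusion halts where it would blur
#' structure.
#'
#' @param grad numeric gradient array.
#' @param kappa edge-stopping scale, > 0.
#' @return array of coefficients in (0, 1].
#' @export
conduction <- function(grad, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("`kappa` must be a single positive number", call. = FALSE)
  exp(-(grad / kappa)^2)
}

#' One Jacobi step of anisotropic diffusion
#'
#' Updates every pixel simultaneously from the same input image:
#' `I + lambda * sum over 4 directions of c_dir * grad_dir`, with conduction
#' coefficients recomputed from the current gradients. With replicate
#' borders, opposing fluxes cancel pairwise, so the total image intensity is
#' conserved exactly (up to floating-point error).
#'
#' @param img numeric HU matrix.
#' @param p a [diffusion_params()] object.
#' @return the diffused matrix, same shape.
#' @export
diffuse_step <- function(img, p) {
  assert_hu_image(img)
  stopifnot(inherits(p, "diffusion_params"))
  g <- directional_gradients(img)
  flux <- conduction(g$north, p$kappa) * g$north +
          conduction(g$south, p$kappa) * g$south +
          conduction(g$east,  p$kappa) * g$east +
          conduction(g$west,  p$kappa) * g$west
  img + p$lambda * flux
}

#' Edge-preserving anisotropic diffusion
#'
#' Applies [diffuse_step()] `p$iterations` times. Operates in HU so that
#' `kappa` keeps its physical meaning as the gradient magnitude (in HU)
#' beyond which a transition is treated as an anatomical edge.
#'
#' @inheritParams diffuse_step
#' @return the denoised HU matrix.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 100
#' out <- diffuse(img, diffusion_params(kappa = 30, lambda = 0.25, iterations = 2))
#' sum(out) - sum(img)  # conservation: ~0
#' @export
diffuse <- function(img, p = diffusion_params()) {
  assert_hu_image(img)
  stopifnot(inherits(p, "diffusion_params"))
  for (i in seq_len(p$iterations)) img <- diffuse_step(img, p)
  img
}
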
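#' Noise level under a reduced-dose CT model
#'
#' CT quantum noise scales with the inverse square root of the photon count,
#' hence of the dose: `sigma(dose) = sigma_full / sqrt(dose_fraction)`.
#' Halving the dose raises noise by `sqrt(2) - 1`, about 41%, matching the
#' familiar rule of thumb that a 50% dose cut costs roughly 40% more noise.
#'
#' @param sigma_full noise standard deviation at full dose (HU).
#' @param dose_fraction fraction of full dose, in (0, 1\].
#' @return noise standard deviation in HU.
#' @examples
#' noise_sigma(10, 0.25)  # 20
#' @export
noise_sigma <- function(sigma_full, dose_fraction) {
  if (!is.numeric(dose_fraction) || any(dose_fraction <= 0) || any(dose_fraction > 1))
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(sigma_full) || any(sigma_full < 0))
    stop("`sigma_full` must be non-negative", call. = FALSE)
  sigma_full / sqrt(dose_fraction)
}

#' Synthetic liver CT slice specification
#'
#' Describes a single axial CT slice in HU: an elliptical body of soft
#' tissue (default 20 HU) ringed by cortical bone (1200 HU) on an air
#' background (-1000 HU), containing an elliptical liver (default 55 HU)
#' with hypodense circular lesions (default 25 HU), plus additive zero-mean
#' Gaussian noise whose standard deviation follows the [noise_sigma()]
#' dose model. All geometry is in pixels; `NULL` geometry arguments scale
#' with `shape`. Tissue HU defaults sit inside standard abdominal ranges so
#' the default liver display window separates liver from lesions and
#' background.
#'
#' @param shape `c(rows, cols)` of the slice. Default 128 x 128.
#' @param liver_center,liver_axes liver ellipse centre and semi-axes
#'   (pixels).
#' @param liver_hu mean liver attenuation, HU.
#' @param lesions data frame with `row`, `col`, `radius`, `hu` per circular
#'   lesion; pass a zero-row frame for none.
#' @param background_hu soft-tissue attenuation inside the body, HU.
#' @param air_hu,bone_hu air background and bone-rim attenuation, HU.
#' @param noise_sigma_full_dose Gaussian noise sd at full dose, HU.
#' @param dose_fraction fraction of full dose in (0, 1\].
#' @param seed integer RNG seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         liver_center = NULL, liver_axes = NULL,
                         liver_hu = 55,
                         lesions = NULL,
                         background_hu = 20, air_hu = -1000, bone_hu = 1200,
                         noise_sigma_full_dose = 12,
                         dose_fraction = 1, seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 16L))
  if (!is.numeric(dose_fraction) || dose_fraction <= 0 || dose_fraction > 1)
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  ctr <- (shape + 1) / 2
  if (is.null(liver_center)) liver_center <- ctr + c(-0.05, -0.10) * shape
  if (is.null(liver_axes))   liver_axes   <- c(0.20, 0.25) * shape
  if (is.null(lesions))
    lesions <- data.frame(
      row = liver_center[1] + c(-0.06, 0.08) * shape[1],
      col = liver_center[2] + c(0.07, -0.05) * shape[2],
      radius = c(0.045, 0.03) * mean(shape),
      hu = c(25, 25))
  structure(list(shape = as.integer(shape),
                 body_center = ctr, body_axes = 0.42 * shape,
                 rim_fraction = 0.94,
                 liver_center = liver_center, liver_axes = liver_axes,
                 liver_hu = liver_hu, lesions = lesions,
                 background_hu = background_hu, air_hu = air_hu,
                 bone_hu = bone_hu,
                 noise_sigma_full_dose = noise_sigma_full_dose,
                 dose_fraction = dose_fraction, seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_radius2 <- function(shape, center, axes) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2
}

#' Generate a phantom slice with ground-truth masks
#'
#' Geometry is deterministic from the spec; only the additive Gaussian noise
#' consumes randomness, seeded from `spec$seed` (the caller's RNG state is
#' left untouched). Masks are derived from the noiseless geometry.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_case`: list with `image` (noisy HU matrix),
#'   `clean` (noiseless HU matrix), `liver_mask`, `lesion_mask`
#'   (lesions are a subset of the liver), `body_mask`, and `spec`.
#' @examples
#' case <- make_phantom(phantom_spec(seed = 42))
#' mean(case$image[case$liver_mask == 1])  # ~55 HU
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  body_r2 <- ellipse_radius2(sh, spec$body_center, spec$body_axes)
  inside_body <- body_r2 <= 1
  interior <- body_r2 <= spec$rim_fraction^2
  rim <- inside_body & !interior

  liver <- ellipse_radius2(sh, spec$liver_center, spec$liver_axes) <= 1
  if (any(liver & !interior))
    stop("liver ellipse extends outside the soft-tissue interior of the body",
         call. = FALSE)
  lesion <- matrix(FALSE, sh[1], sh[2])
  les <- spec$lesions
  if (!is.null(les) && nrow(les)) {
    for (i in seq_len(nrow(les)))
      lesion <- lesion | ellipse_radius2(sh, c(les$row[i], les$col[i]),
                                         rep(les$radius[i], 2)) <= 1
    if (any(lesion & !liver))
      stop("a lesion extends outside the liver ellipse", call. = FALSE)
  }

  clean <- matrix(spec$air_hu, sh[1], sh[2])
  clean[interior] <- spec$background_hu
  clean[rim] <- spec$bone_hu
  clean[liver] <- spec$liver_hu
  if (!is.null(les) && nrow(les)) {
    for (i in seq_len(nrow(les))) {
      inles <- ellipse_radius2(sh, c(les$row[i], les$col[i]),
                               rep(les$radius[i], 2)) <= 1
      clean[inles] <- les$hu[i]
    }
  }

  sigma <- noise_sigma(spec$noise_sigma_full_dose, spec$dose_fraction)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  noisy <- clean + if (sigma > 0) matrix(stats::rnorm(prod(sh), 0, sigma), sh[1], sh[2]) else 0

  mk <- function(b) { m <- b * 1L; storage.mode(m) <- "integer"; m }
  structure(list(image = noisy, clean = clean,
                 liver_mask = mk(liver), lesion_mask = mk(lesion),
                 body_mask = mk(inside_body), spec = spec),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %dx%d, dose %.2f, sigma %.2f HU, seed %d; liver %d px, lesions %d px\n",
              x$spec$shape[1], x$spec$shape[2], x$spec$dose_fraction,
              noise_sigma(x$spec$noise_sigma_full_dose, x$spec$dose_fraction),
              x$spec$seed, sum(x$liver_mask), sum(x$lesion_mask)))
  invisible(x)
}

#' Export a phantom case as NIfTI plus a JSON manifest
#'
#' Writes `image.nii.gz` (HU rounded to int16; exact to within 0.5 HU),
#' `liver_mask.nii.gz`, `lesion_mask.nii.gz` and `manifest.json` echoing the
#' spec (including the seed). Files read back through [read_volume()] /
#' [read_mask()].
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if absent).
#' @return invisibly, the written paths.
#' @export
export_phantom <- function(case, dir) {
  stopifnot(inherits(case, "phantom_case"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, "image.nii.gz")
  img <- round(case$image)
  storage.mode(img) <- "integer"
  RNifti::writeNifti(RNifti::asNifti(img, datatype = "int16"), img_path)
  p2 <- write_mask(case$liver_mask, file.path(dir, "liver_mask.nii.gz"))
  p3 <- write_mask(case$lesion_mask, file.path(dir, "lesion_mask.nii.gz"))
  sp <- case$spec
  manifest <- list(shape = sp$shape, liver_hu = sp$liver_hu,
                   background_hu = sp$background_hu, air_hu = sp$air_hu,
                   bone_hu = sp$bone_hu,
                   noise_sigma_full_dose = sp$noise_sigma_full_dose,
                   dose_fraction = sp$dose_fraction, seed = sp$seed)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, p2, p3, mp))
}

# 4-connected components via igraph; returns integer label matrix (0 = bg)
label_components <- function(mask) {
  idx <- which(mask != 0L)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(idx)) return(lab)
  nr <- nrow(mask)
  map <- integer(length(mask)); map[idx] <- seq_along(idx)
  edges <- integer(0)
  # down-neighbour: same column, row + 1
  down <- idx[(idx %% nr) != 0L & mask[idx + 1L] != 0L]
  # right-neighbour: same row, col + 1
  right <- idx[idx + nr <= length(mask)]
  right <- right[mask[right + nr] != 0L]
  edges <- c(rbind(map[down], map[down + 1L]), rbind(map[right], map[right + nr]))
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Toy liver segmenter: fixed threshold, largest component, hole filling
#'
#' Thresholds an enhanced 8-bit slice at a fixed level, keeps the largest
#' 4-connected foreground component, and fills enclosed holes (so hypodense
#' lesions inside the organ stay part of the segment). This deliberately
#' simple segmenter exists to exercise the enhancement pipeline end-to-end
#' on phantoms with known truth; it is not a clinical segmentation model.
#'
#' @param img integer byte-image matrix.
#' @param threshold byte level; pixels `>= threshold` are foreground.
#'   Default 150, chosen once for the default liver window and equal-weight
#'   blend, where liver parenchyma lands above mid-gray and background
#'   tissue below.
#' @return a {0, 1} integer mask.
#' @export
segment_liver <- function(img, threshold = 150) {
  assert_byte_image(img)
  fg <- (img >= threshold) * 1L
  lab <- label_components(fg)
  if (!any(lab > 0L)) return(matrix(0L, nrow(img), ncol(img)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- (lab == which.max(sizes)) * 1L
  fill_holes(keep)
}

# holes = complement components that do not touch the image border
fill_holes <- function(mask) {
  comp <- label_components(1L - mask)
  if (!any(comp > 0L)) return(mask)
  border_labels <- unique(c(comp[1L, ], comp[nrow(comp), ],
                            comp[, 1L], comp[, ncol(comp)]))
  hole <- comp > 0L & !(comp %in% border_labels)
  out <- mask
  out[hole] <- 1L
  storage.mode(out) <- "integer"
  out
}
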
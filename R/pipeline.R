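#' Enhancement pipeline configuration
#'
#' The pipeline denoises the HU slice once with anisotropic diffusion, then
#' splits into two paths: a *global* path (min-max normalization to 8-bit
#' followed by histogram equalization) that reveals detail across the whole
#' dynamic range, and a *local* path (window leveling) that spends the gray
#' range on the tissue of interest. The `proposed` variant blends the two
#' 8-bit results with weight `alpha` on the local path. The `normalization`
#' variant is the unenhanced baseline: plain min-max conversion with no
#' diffusion.
#'
#' @param diffusion a [diffusion_params()].
#' @param window a [window_spec()].
#' @param alpha blend weight on the local (window) path, in \[0, 1\].
#'   Default 0.5: with no task-specific reason to favour either path, equal
#'   weighting is the symmetric choice; tune per task.
#' @param variant one of `"normalization"`, `"histeq"`, `"window"`,
#'   `"proposed"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(diffusion = diffusion_params(),
                            window = window_spec(),
                            alpha = 0.5,
                            variant = c("proposed", "normalization",
                                        "histeq", "window")) {
  variant <- match.arg(variant)
  stopifnot(inherits(diffusion, "diffusion_params"),
            inherits(window, "window_spec"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  structure(list(diffusion = diffusion, window = window,
                 alpha = alpha, variant = variant),
            class = "pipeline_config")
}

#' Weighted blend of the local and global 8-bit paths
#'
#' Element-wise `alpha * local + (1 - alpha) * global`, rounded half-up and
#' clamped to 0..255. `alpha = 1` returns the local image bit-exactly,
#' `alpha = 0` the global one.
#'
#' @param local,global_img byte-image matrices of equal shape.
#' @param alpha weight on `local`, in \[0, 1\].
#' @return blended byte-image matrix.
#' @export
blend <- function(local, global_img, alpha) {
  assert_byte_image(local, "local")
  assert_byte_image(global_img, "global_img")
  assert_same_shape(local, global_img, "blend inputs")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  as_byte(alpha * local + (1 - alpha) * global_img)
}

#' Enhance one HU slice
#'
#' Runs the configured variant:
#' * `normalization` — [normalize_minmax()] only (no diffusion; the baseline
#'   standard conversion),
#' * `histeq` — diffusion, normalization, then [equalize()],
#' * `window` — diffusion then [window_level()],
#' * `proposed` — [blend()] of the window path (weight `alpha`) and the
#'   histeq path (weight `1 - alpha`), both fed by the same single
#'   diffusion pass.
#'
#' The pipeline is fully deterministic: no stage consumes randomness.
#'
#' @param img numeric HU matrix.
#' @param cfg a [pipeline_config()].
#' @return integer byte-image matrix.
#' @examples
#' img <- matrix(rep(c(-1000, 20, 55), each = 12), 6, 6)
#' enhance(img, pipeline_config(variant = "proposed"))
#' @export
enhance <- function(img, cfg = pipeline_config()) {
  assert_hu_image(img)
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$variant == "normalization") return(normalize_minmax(img))
  den <- diffuse(img, cfg$diffusion)
  switch(cfg$variant,
    histeq = equalize(normalize_minmax(den)),
    window = window_level(den, cfg$window),
    proposed = blend(window_level(den, cfg$window),
                     equalize(normalize_minmax(den)),
                     cfg$alpha)
  )
}

#' Contrast-to-noise ratio between two regions
#'
#' `|mean(fg) - mean(bg)| / sqrt(sd(fg)^2 + sd(bg)^2)` over the pixels
#' selected by two masks. CNR is the standard way to score how well an
#' enhancement separates a target tissue from its surround once noise is
#' taken into account: a map that brightens everything (raising the mean
#' difference and the spread together) does not gain CNR.
#'
#' @param img numeric or integer image matrix.
#' @param fg_mask,bg_mask {0, 1} masks selecting the two regions; must be
#'   non-empty and have the image's shape.
#' @return a single non-negative number.
#' @export
region_cnr <- function(img, fg_mask, bg_mask) {
  assert_binary_mask(fg_mask, "fg_mask")
  assert_binary_mask(bg_mask, "bg_mask")
  assert_same_shape(img, fg_mask, "image and fg_mask")
  assert_same_shape(img, bg_mask, "image and bg_mask")
  fg <- img[fg_mask == 1L]; bg <- img[bg_mask == 1L]
  if (!length(fg) || !length(bg))
    stop("both regions must contain at least one pixel", call. = FALSE)
  abs(mean(fg) - mean(bg)) / sqrt(stats::sd(fg)^2 + stats::sd(bg)^2)
}

#' Enhance a whole volume slice-by-slice to PNG
#'
#' Reads a DICOM series or NIfTI volume, enhances each requested slice with
#' [enhance()], and writes one 8-bit grayscale PNG per slice
#' (`slice_0001.png`, ...) plus a JSON run manifest (`manifest.json`)
#' echoing the configuration and recording per-slice output min/max.
#'
#' @param input path to a DICOM directory or NIfTI file.
#' @param output_dir directory for the PNGs and manifest; must exist and be
#'   writable (checked before any processing).
#' @param cfg a [pipeline_config()].
#' @param slices 1-based slice indices; default all.
#' @param quiet suppress per-slice progress messages on stderr.
#' @return invisibly, the manifest as a list.
#' @export
enhance_volume <- function(input, output_dir, cfg = pipeline_config(),
                           slices = NULL, quiet = FALSE) {
  if (!dir.exists(output_dir))
    stop(sprintf("output directory does not exist: %s", output_dir), call. = FALSE)
  if (file.access(output_dir, 2L) != 0L)
    stop(sprintf("output directory is not writable: %s", output_dir), call. = FALSE)
  v <- read_volume(input)
  if (is.null(slices)) slices <- seq_len(n_slices(v))
  entries <- vector("list", length(slices))
  for (i in seq_along(slices)) {
    s <- slices[i]
    if (!quiet) message(sprintf("slice %d/%d (index %d)", i, length(slices), s))
    out <- enhance(to_hu(v, s), cfg)
    fn <- sprintf("slice_%04d.png", s)
    write_png(out, file.path(output_dir, fn))
    entries[[i]] <- list(slice = s, file = fn,
                         min = min(out), max = max(out))
  }
  manifest <- list(
    tool = "ctenhance",
    version = as.character(utils::packageVersion("ctenhance")),
    input = input,
    config = list(
      variant = cfg$variant, alpha = cfg$alpha,
      kappa = cfg$diffusion$kappa, lambda = cfg$diffusion$lambda,
      iterations = cfg$diffusion$iterations,
      window_center = cfg$window$center, window_width = cfg$window$width
    ),
    slices = entries
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
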
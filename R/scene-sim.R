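#' Default cow patches for a synthetic winter scene
#'
#' Three rectangular hide patches (white, red, black) with the absolute
#' albedos measured for winter cattle coats: 0.69, 0.16 and 0.04.
#'
#' @return A list of patch descriptors, each with `label`, `albedo` and a
#'   rectangle (`x`, `y`, `w`, `h`, in pixels, 1-based, column-major).
#' @export
default_patches <- function() {
  list(
    list(label = "white", albedo = 0.69, x = 10L,  y = 10L, w = 35L, h = 35L),
    list(label = "red",   albedo = 0.16, x = 60L,  y = 10L, w = 35L, h = 35L),
    list(label = "black", albedo = 0.04, x = 110L, y = 10L, w = 35L, h = 35L)
  )
}

#' Specify a synthetic winter scene
#'
#' Describes an 8-bit grayscale image of a snow field containing rectangular
#' animal-hide patches of known absolute albedo. Patch brightness follows the
#' linear model `gray = base_gray * albedo / snow_albedo`, the unique
#' brightness model under which snow-referenced albedo estimation is unbiased.
#'
#' @param width,height Image dimensions in pixels.
#' @param base_gray Mean gray level of unshadowed snow (0-255). The default
#'   170 makes the default patch albedos land exactly on integer gray levels,
#'   so 8-bit quantization does not perturb noise-free albedo recovery.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   gray levels.
#' @param patches List of patch descriptors as in [default_patches()].
#' @param shadow_frac Proportion of snow pixels darkened to emulate shadows.
#' @param shadow_factor Multiplicative darkening applied to shadowed pixels.
#' @param snow_albedo Assumed albedo of the snow reference (default 0.85).
#' @param seed Integer random seed; all scene randomness flows from it.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width = 160L, height = 120L, base_gray = 170,
                       noise_sd = 5, patches = default_patches(),
                       shadow_frac = 0, shadow_factor = 0.6,
                       snow_albedo = 0.85, seed = 1L) {
  stopifnot(width >= 1, height >= 1, noise_sd >= 0,
            shadow_frac >= 0, shadow_frac <= 1,
            shadow_factor > 0, shadow_factor <= 1,
            snow_albedo > 0, snow_albedo <= 1)
  if (base_gray < 0 || base_gray > 255)
    stopf("base_gray must lie in [0, 255], got %s", base_gray)
  for (p in patches) {
    if (!all(c("label", "albedo", "x", "y", "w", "h") %in% names(p)))
      stopf("each patch needs label, albedo, x, y, w, h")
    if (p$albedo < 0 || p$albedo > snow_albedo)
      stopf("patch '%s' albedo %.3f exceeds the snow reference %.2f",
            p$label, p$albedo, snow_albedo)
    if (p$x < 1 || p$y < 1 || p$x + p$w - 1 > width || p$y + p$h - 1 > height)
      stopf("patch '%s' extends outside the %dx%d image", p$label, width, height)
  }
  # reject overlapping patches: albedo truth would be ill-defined
  if (length(patches) > 1) {
    occ <- matrix(FALSE, nrow = height, ncol = width)
    for (p in patches) {
      rows <- p$y:(p$y + p$h - 1); cols <- p$x:(p$x + p$w - 1)
      if (any(occ[rows, cols])) stopf("patch '%s' overlaps another patch", p$label)
      occ[rows, cols] <- TRUE
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 base_gray = base_gray, noise_sd = noise_sd, patches = patches,
                 shadow_frac = shadow_frac, shadow_factor = shadow_factor,
                 snow_albedo = snow_albedo, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic winter image with ground-truth masks
#'
#' Renders the scene described by a [scene_spec()]: snow at `base_gray`,
#' each patch at `base_gray * albedo / snow_albedo`, optional snow shadows,
#' additive Gaussian noise, then rounding (half-up) and clipping to `[0, 255]`.
#'
#' @param spec A `scene_spec`.
#'
#' @return An object of class `winter_scene`: a list with
#'   \describe{
#'     \item{image}{height x width integer matrix of gray values in 0-255.}
#'     \item{labels}{integer label matrix: 1 = snow, 2+ = patches in order.}
#'     \item{mapping}{data.frame mapping `label_id` to region `name`.}
#'     \item{truth}{list of every injected parameter, including per-patch
#'       true albedo and expected gray.}
#'   }
#' @export
generate_winter_image <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  expected <- matrix(spec$base_gray, nrow = h, ncol = w)
  labels <- matrix(1L, nrow = h, ncol = w)
  names_out <- "snow"
  for (i in seq_along(spec$patches)) {
    p <- spec$patches[[i]]
    rows <- p$y:(p$y + p$h - 1); cols <- p$x:(p$x + p$w - 1)
    expected[rows, cols] <- spec$base_gray * p$albedo / spec$snow_albedo
    labels[rows, cols] <- i + 1L
    names_out <- c(names_out, p$label)
  }
  if (spec$shadow_frac > 0) {
    snow_idx <- which(labels == 1L)
    k <- floor(spec$shadow_frac * length(snow_idx))
    if (k > 0) {
      sh <- sample(snow_idx, k)
      expected[sh] <- expected[sh] * spec$shadow_factor
    }
  }
  noisy <- expected
  if (spec$noise_sd > 0)
    noisy <- noisy + stats::rnorm(length(noisy), 0, spec$noise_sd)
  img <- matrix(as.integer(clip255(round_half_up(noisy))), nrow = h, ncol = w)
  truth <- list(spec = spec,
                expected_gray = vapply(spec$patches, function(p)
                  spec$base_gray * p$albedo / spec$snow_albedo, numeric(1)),
                albedo = vapply(spec$patches, function(p) p$albedo, numeric(1)),
                labels = vapply(spec$patches, function(p) p$label, character(1)))
  structure(list(image = img, labels = labels,
                 mapping = data.frame(label_id = seq_len(length(spec$patches) + 1L),
                                      name = names_out,
                                      stringsAsFactors = FALSE),
                 truth = truth),
            class = "winter_scene")
}

#' Write a winter scene to disk as plain 8-bit PNGs plus sidecar files
#'
#' Writes `image.png` (grayscale), `mask.png` (label image, 0-based labels),
#' `mapping.csv` (label id to region name) and `truth.txt` (key = value).
#'
#' @param scene A `winter_scene`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "winter_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, "image.png")
  mask_path <- file.path(dir, "mask.png")
  map_path <- file.path(dir, "mapping.csv")
  truth_path <- file.path(dir, "truth.txt")
  png::writePNG(scene$image / 255, img_path)
  png::writePNG(scene$labels / 255, mask_path)
  utils::write.csv(scene$mapping, map_path, row.names = FALSE)
  tr <- scene$truth
  lines <- c(sprintf("base_gray = %s", tr$spec$base_gray),
             sprintf("noise_sd = %s", tr$spec$noise_sd),
             sprintf("snow_albedo = %s", tr$spec$snow_albedo),
             sprintf("seed = %s", tr$spec$seed),
             sprintf("albedo_%s = %s", tr$labels, tr$albedo))
  writeLines(lines, truth_path)
  invisible(c(img_path, mask_path, map_path, truth_path))
}

#' Read an 8-bit grayscale (or RGB) PNG as a gray-value matrix
#'
#' RGB images are converted with [to_gray()].
#'
#' @param path PNG file path.
#' @param gray_method Conversion rule passed to [to_gray()] for RGB input.
#' @return Integer matrix of gray values in 0-255.
#' @export
read_gray_image <- function(path, gray_method = "mean") {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) return(to_gray(a[, , 1:3] * 255, method = gray_method))
    a <- a[, , 1]
  }
  matrix(as.integer(round_half_up(a * 255)), nrow = nrow(a), ncol = ncol(a))
}

#' Read a label-mask PNG and its sidecar mapping
#'
#' @param mask_path Label-image PNG written by [write_scene()].
#' @param mapping_path CSV with columns `label_id`, `name`.
#' @return List with `labels` (integer matrix) and `mapping` (data.frame).
#' @export
read_label_mask <- function(mask_path, mapping_path) {
  labels <- read_gray_image(mask_path)
  mapping <- utils::read.csv(mapping_path, stringsAsFactors = FALSE)
  stopifnot(all(c("label_id", "name") %in% names(mapping)))
  list(labels = labels, mapping = mapping)
}
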
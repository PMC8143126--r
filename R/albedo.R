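#' Convert an RGB image to 8-bit gray values
#'
#' @param image Numeric array `height x width x 3` with channel values in
#'   0-255.
#' @param method `"mean"` (unweighted channel mean, the default) or
#'   `"luminance"` (Rec. 601 weights 0.299, 0.587, 0.114).
#' @return Integer matrix of gray values in 0-255, rounded half-up.
#' @export
to_gray <- function(image, method = c("mean", "luminance")) {
  method <- match.arg(method)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stopf("expected a height x width x 3 array, got dims [%s]",
          paste(d, collapse = ", "))
  if (min(image) < 0 || max(image) > 255)
    stopf("channel values must lie in [0, 255]")
  w <- if (method == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  g <- image[, , 1] * w[1] + image[, , 2] * w[2] + image[, , 3] * w[3]
  matrix(as.integer(clip255(round_half_up(g))), nrow = d[1], ncol = d[2])
}

#' Summarize the gray values of a masked image region
#'
#' Computes the region mean (the brightness indicator the albedo ratio is
#' built from), sample SD, range and a 256-bin histogram, one bin per gray
#' level.
#'
#' @param image Integer matrix of gray values in 0-255.
#' @param mask Logical matrix with the same dimensions selecting the region.
#' @return Object of class `pixel_summary`: list with `n`, `mean`, `sd`,
#'   `min`, `max`, `hist` (length-256 integer vector of counts for gray
#'   values 0..255).
#' @export
pixel_summary <- function(image, mask) {
  if (!is.matrix(image) || !is.numeric(image)) stopf("image must be a numeric matrix")
  if (!is.logical(mask) || !identical(dim(mask), dim(image)))
    stopf("mask must be a logical matrix with the image's dimensions")
  vals <- image[mask]
  if (length(vals) == 0L) stopf("empty region mask")
  if (min(vals) < 0 || max(vals) > 255) stopf("gray values must lie in [0, 255]")
  structure(list(n = length(vals),
                 mean = mean(vals),
                 sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
                 min = min(vals),
                 max = max(vals),
                 hist = tabulate(as.integer(vals) + 1L, nbins = 256L)),
            class = "pixel_summary")
}

#' @export
print.pixel_summary <- function(x, ...) {
  cat(sprintf("Region of %d pixels: mean %.2f, sd %.2f, range [%d, %d]\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Relative albedo of a target region against a snow reference
#'
#' The brightness ratio `bright_target / bright_reference`. Ratios above 1
#' (target brighter than snow) are retained but flagged with a warning.
#'
#' @param bright_target Mean gray value of the target region.
#' @param bright_reference Mean gray value of the snow reference region;
#'   must be positive.
#' @return Relative albedo (unitless, >= 0).
#' @export
relative_albedo <- function(bright_target, bright_reference) {
  stopifnot(is_scalar_number(bright_target), is_scalar_number(bright_reference))
  if (bright_reference <= 0)
    stopf("reference brightness must be positive, got %s", bright_reference)
  if (bright_target < 0) stopf("target brightness must be non-negative")
  r <- bright_target / bright_reference
  if (r > 1)
    warning(sprintf("relative albedo %.3f exceeds 1: target brighter than the snow reference", r),
            call. = FALSE)
  r
}

#' Absolute albedo from a relative albedo
#'
#' Rescales a snow-relative brightness ratio by the assumed albedo of fresh
#' snow (0.85 by default).
#'
#' @param rel Relative albedo, >= 0.
#' @param snow_ref Snow reference albedo constant.
#' @return Absolute albedo, `rel * snow_ref`.
#' @export
absolute_albedo <- function(rel, snow_ref = 0.85) {
  stopifnot(is_scalar_number(rel), is_scalar_number(snow_ref), snow_ref > 0)
  if (rel < 0) stopf("relative albedo must be non-negative, got %s", rel)
  rel * snow_ref
}

#' Estimate per-region albedos of an image against its snow reference
#'
#' Every non-snow labeled region is scored as
#' `albedo_abs = (mean gray of region / mean gray of snow) * snow_ref`.
#'
#' @param image A `winter_scene` (in which case `labels`/`mapping` are taken
#'   from it) or an integer gray matrix.
#' @param labels Integer label matrix (ignored when `image` is a scene).
#' @param mapping data.frame with columns `label_id`, `name`; exactly one
#'   row must be named `"snow"`.
#' @param snow_ref Snow reference albedo constant.
#' @param image_id Optional identifier carried into the output.
#' @return data.frame with one row per target region: `image_id`, `color`,
#'   `n_pixels`, `bright_mean`, `bright_sd`, `albedo_rel`, `albedo_abs`,
#'   `snow_ref`, `flagged` (TRUE when the ratio exceeds 1).
#' @export
estimate_image_albedos <- function(image, labels = NULL, mapping = NULL,
                                   snow_ref = 0.85, image_id = NA_character_) {
  if (inherits(image, "winter_scene")) {
    labels <- image$labels
    mapping <- image$mapping
    image <- image$image
  }
  stopifnot(is.matrix(image), is.matrix(labels),
            identical(dim(image), dim(labels)), is.data.frame(mapping))
  snow_rows <- which(mapping$name == "snow")
  if (length(snow_rows) != 1L)
    stopf("mask set must contain exactly one snow region, found %d", length(snow_rows))
  targets <- mapping[-snow_rows, , drop = FALSE]
  if (nrow(targets) < 1L) stopf("mask set must contain at least one target region")
  snow_sum <- pixel_summary(image, labels == mapping$label_id[snow_rows])
  out <- lapply(seq_len(nrow(targets)), function(i) {
    s <- pixel_summary(image, labels == targets$label_id[i])
    rel <- relative_albedo(s$mean, snow_sum$mean)
    data.frame(image_id = image_id, color = targets$name[i],
               n_pixels = s$n, bright_mean = s$mean, bright_sd = s$sd,
               albedo_rel = rel, albedo_abs = absolute_albedo(rel, snow_ref),
               snow_ref = snow_ref, flagged = rel > 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize replicate albedo estimates per color
#'
#' @param estimates data.frame with columns `color` and `albedo_abs`
#'   (replicate images stacked).
#' @return data.frame with per-color `n`, `mean`, `se` (SD / sqrt(n); `NA`
#'   and flagged when a color has a single replicate).
#' @export
summarize_replicates <- function(estimates) {
  stopifnot(is.data.frame(estimates),
            all(c("color", "albedo_abs") %in% names(estimates)))
  if (nrow(estimates) == 0L) stopf("no estimates supplied")
  sp <- split(estimates$albedo_abs, estimates$color)
  out <- do.call(rbind, lapply(names(sp), function(col) {
    v <- sp[[col]]
    data.frame(color = col, n = length(v), mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               se_defined = length(v) > 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
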
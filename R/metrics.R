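#' Region-of-interest set for quality metrics
#'
#' @param background_mask Logical matrix marking the signal-free background
#'   region whose variance defines the noise term of both metrics.
#' @param region_masks List of logical matrices, one per homogeneous region
#'   of interest. Must be nonempty and disjoint from the background.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(background_mask, region_masks) {
  if (!is.matrix(background_mask) || !is.logical(background_mask))
    nchr_stop("nchr_invalid_roi", "background_mask must be a logical matrix")
  if (!is.list(region_masks) || length(region_masks) < 1L)
    nchr_stop("nchr_invalid_roi", "need at least one region mask")
  for (m in region_masks) {
    if (!is.matrix(m) || !is.logical(m) ||
        !all(dim(m) == dim(background_mask)))
      nchr_stop("nchr_invalid_roi", "region masks must match the background mask")
    if (!any(m)) nchr_stop("nchr_invalid_roi", "empty region mask")
    if (any(m & background_mask))
      nchr_stop("nchr_invalid_roi", "region mask overlaps the background mask")
  }
  if (!any(background_mask))
    nchr_stop("nchr_invalid_roi", "empty background mask")
  structure(list(background = background_mask, regions = region_masks),
            class = "roi_set")
}

# Optional log-compression of the display image before computing metrics.
metric_image <- function(image, scale) {
  if (scale == "linear") return(image)
  20 * log10(pmax(abs(image), 1e-8))
}

#' Signal-to-noise ratio of a B-scan
#'
#' `SNR = 10 log10( max(|image|)^2 / var(background) )` in decibels, where
#' the maximum magnitude is taken over the whole image and the variance is
#' the unbiased sample variance over the background mask.
#'
#' @param image Numeric matrix.
#' @param rois An [roi_set()]; only the background mask is used.
#' @param scale `"linear"` (default) computes the metric on the magnitude
#'   image; `"log"` first log-compresses to a dB display image.
#' @return SNR in dB.
#' @export
snr <- function(image, rois, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(rois, "roi_set"), all(dim(image) == dim(rois$background)))
  img <- metric_image(image, scale)
  bg <- img[rois$background]
  if (length(bg) < 2L)
    nchr_stop("nchr_undefined_metric", "background mask needs at least 2 pixels")
  v <- var(bg)
  if (v == 0)
    nchr_stop("nchr_undefined_metric", "background variance is zero; SNR undefined")
  10 * log10(max(abs(img))^2 / v)
}

#' Contrast-to-noise ratio and full quality report
#'
#' Per region r, `CNR_r = (mu_r - mu_b) / sqrt(var_r + var_b)` with the
#' background mean/variance `mu_b`, `var_b`; the reported CNR is the
#' arithmetic mean over regions. Means and variances are unbiased sample
#' statistics over the ROI masks.
#'
#' @inheritParams snr
#' @return An object of class `quality_report`: list with `snr_db`, `cnr`,
#'   and `per_region_cnr`.
#' @export
cnr <- function(image, rois, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  stopifnot(inherits(rois, "roi_set"), all(dim(image) == dim(rois$background)))
  img <- metric_image(image, scale)
  bg <- img[rois$background]
  if (length(bg) < 2L)
    nchr_stop("nchr_undefined_metric", "background mask needs at least 2 pixels")
  mu_b <- mean(bg); v_b <- var(bg)
  per <- vapply(rois$regions, function(m) {
    px <- img[m]
    if (length(px) < 2L)
      nchr_stop("nchr_undefined_metric", "region mask needs at least 2 pixels")
    v_r <- var(px)
    if (v_r + v_b == 0)
      nchr_stop("nchr_undefined_metric", "zero combined variance; CNR undefined")
    (mean(px) - mu_b) / sqrt(v_r + v_b)
  }, 0)
  structure(list(
    snr_db = snr(image, rois, scale),
    cnr = mean(per),
    per_region_cnr = per
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("SNR: %.3f dB   CNR: %.4f (%d region%s)\n",
              x$snr_db, x$cnr, length(x$per_region_cnr),
              if (length(x$per_region_cnr) == 1) "" else "s"))
  invisible(x)
}
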
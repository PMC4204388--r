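#' Patch and search-neighborhood geometry
#'
#' @param patch_size Odd pixels per side of the comparison patch (default 9).
#' @param neighborhood_size Odd pixels per side of the search neighborhood
#'   (default 21); must be at least `patch_size`.
#' @return An object of class `patch_config`. Boundary handling is always
#'   symmetric-reflection padding.
#' @export
patch_config <- function(patch_size = 9L, neighborhood_size = 21L) {
  patch_size <- as.integer(patch_size)
  neighborhood_size <- as.integer(neighborhood_size)
  if (patch_size %% 2L == 0L || neighborhood_size %% 2L == 0L)
    nchr_stop("nchr_invalid_config", "patch and neighborhood sizes must be odd")
  if (patch_size < 3L || neighborhood_size < patch_size)
    nchr_stop("nchr_invalid_config",
              "need 3 <= patch_size <= neighborhood_size")
  structure(list(patch_size = patch_size,
                 neighborhood_size = neighborhood_size,
                 boundary = "symmetric"),
            class = "patch_config")
}

# Symmetric (half-sample) reflection of 1-based indices into [1, n].
reflect_index <- function(i, n) {
  p <- (i - 1L) %% (2L * n)        # R modulo is nonnegative here
  ifelse(p >= n, 2L * n - 1L - p, p) + 1L
}

# Patch extraction without a bounds check on the center: used internally for
# neighbor centers that fall outside the image near borders.
patch_at <- function(image, center, pr) {
  rows <- reflect_index(center[1] + (-pr:pr), nrow(image))
  cols <- reflect_index(center[2] + (-pr:pr), ncol(image))
  image[rows, cols, drop = FALSE]
}

#' Extract a patch centered at a pixel
#'
#' Returns the `patch_size` x `patch_size` window centered at `center`, with
#' symmetric-reflection padding wherever the window exits the image.
#'
#' @param image Numeric matrix.
#' @param center Integer vector `c(row, col)`, inside the image.
#' @param cfg A [patch_config()].
#' @return A `patch_size` x `patch_size` matrix.
#' @export
extract_patch <- function(image, center, cfg = patch_config()) {
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image))
    nchr_stop("nchr_index_error", "patch center (%d, %d) outside the image",
              center[1], center[2])
  patch_at(image, as.integer(center), cfg$patch_size %/% 2L)
}

#' Self-exclusion indicator
#'
#' 1 when the pixels differ, 0 when `x == i`: the indicator that removes the
#' self-pixel from every non-local weight.
#'
#' @param x,i Integer coordinate vectors `c(row, col)`.
#' @return 0 or 1.
#' @export
neighbor_indicator <- function(x, i) {
  as.integer(!all(x == i))
}

#' Positive-part James-Stein shrinkage factor
#'
#' `max(0, 1 - (n_size - 2) * sigma^2 / residual_sq_norm)`, the shrinkage
#' factor applied to every non-local weight in the modified mode. A zero
#' residual returns 0 (full shrinkage), and the raw factor is clipped at 0
#' (positive-part rule) so weights stay nonnegative.
#'
#' @param residual_sq_norm Squared norm of the residual vector (>= 0).
#' @param sigma Noise/continuation level (>= 0).
#' @param n_size Dimension count of the residual vector (>= 3).
#' @return Shrinkage factor in [0, 1].
#' @export
js_shrinkage_factor <- function(residual_sq_norm, sigma, n_size) {
  if (residual_sq_norm < 0)
    nchr_stop("nchr_domain_error", "residual_sq_norm must be nonnegative")
  if (n_size < 3)
    nchr_stop("nchr_domain_error", "n_size must be at least 3")
  if (residual_sq_norm == 0) return(0)
  max(0, 1 - (n_size - 2) * sigma^2 / residual_sq_norm)
}

js_count_size <- function(cfg, js_count) {
  if (js_count == "patch") cfg$patch_size^2 else cfg$neighborhood_size^2
}

#' Modified James-Stein non-local weight for one pixel pair
#'
#' `w(x, i, sigma) = alpha(x, i) * JS(x) * exp(-||P(x) - P(i)||^2 / (2 sigma^2))`
#' where the patches `P` are taken from the current estimate, and the
#' James-Stein factor shrinks by the squared norm of the residual patch
#' (noisy minus current estimate) at `x`. The factor's dimension count is the
#' patch pixel count by default (`js_count = "patch"`); the literal
#' neighborhood-count reading is available via `js_count = "neighborhood"`.
#'
#' @param current_estimate,noisy_image Numeric matrices of equal size.
#' @param x Center pixel `c(row, col)`, inside the image.
#' @param i Neighbor pixel `c(row, col)`; may fall outside the image near a
#'   border, in which case its patch is read through reflection.
#' @param sigma Positive bandwidth of the similarity kernel.
#' @param cfg A [patch_config()].
#' @param js_count Dimension count used in the shrinkage factor.
#' @return Weight in [0, 1].
#' @export
nl_weight <- function(current_estimate, x, i, sigma, noisy_image,
                      cfg = patch_config(),
                      js_count = c("patch", "neighborhood")) {
  js_count <- match.arg(js_count)
  if (sigma <= 0)
    nchr_stop("nchr_domain_error", "sigma must be positive")
  if (neighbor_indicator(x, i) == 0L) return(0)
  pr <- cfg$patch_size %/% 2L
  x <- as.integer(x); i <- as.integer(i)
  res <- patch_at(noisy_image, x, pr) - patch_at(current_estimate, x, pr)
  js <- js_shrinkage_factor(sum(res^2), sigma, js_count_size(cfg, js_count))
  if (js == 0) return(0)
  d2 <- sum((patch_at(current_estimate, x, pr) -
               patch_at(current_estimate, i, pr))^2)
  js * exp(-d2 / (2 * sigma^2))
}

#' Conventional non-local weight (no James-Stein factor)
#'
#' The baseline weight `alpha(x, i) * exp(-||P(x) - P(i)||^2 / (2 sigma^2))`
#' used by the conventional homotopic non-local regularization strategy. For
#' any input it bounds the modified weight from above.
#'
#' @inheritParams nl_weight
#' @return Weight in [0, 1].
#' @export
conventional_nl_weight <- function(current_estimate, x, i, sigma,
                                   cfg = patch_config()) {
  if (sigma <= 0)
    nchr_stop("nchr_domain_error", "sigma must be positive")
  if (neighbor_indicator(x, i) == 0L) return(0)
  pr <- cfg$patch_size %/% 2L
  x <- as.integer(x); i <- as.integer(i)
  d2 <- sum((patch_at(current_estimate, x, pr) -
               patch_at(current_estimate, i, pr))^2)
  exp(-d2 / (2 * sigma^2))
}

#' Compute the full weight field at one continuation level
#'
#' Evaluates [nl_weight()] (or [conventional_nl_weight()]) for every image
#' pixel and every neighborhood offset at once. Column
#' `j = (dc + nr) * neighborhood_size + (dr + nr) + 1` of the weight matrix
#' holds the weights for offset `(dr, dc)`, `nr` being the neighborhood
#' radius; rows are image pixels in column-major order.
#'
#' @inheritParams nl_weight
#' @param mode `"modified-js"` (default) or `"conventional"`.
#' @return An object of class `nchr_weight_field`: list with the weight
#'   matrix `w`, `sigma`, `cfg`, `mode` and the image `dim`.
#' @export
weight_field <- function(current_estimate, noisy_image, sigma,
                         cfg = patch_config(),
                         mode = c("modified-js", "conventional"),
                         js_count = c("patch", "neighborhood")) {
  mode <- match.arg(mode)
  js_count <- match.arg(js_count)
  if (sigma <= 0)
    nchr_stop("nchr_domain_error", "sigma must be positive")
  stopifnot(all(dim(current_estimate) == dim(noisy_image)))
  w <- cpp_weight_field(current_estimate, noisy_image, sigma,
                        cfg$patch_size, cfg$neighborhood_size,
                        mode == "modified-js", js_count == "patch")
  structure(list(w = w, sigma = sigma, cfg = cfg, mode = mode,
                 js_count = js_count, dim = dim(current_estimate)),
            class = "nchr_weight_field")
}

#' Non-local regularization penalty
#'
#' `rho(f, sigma) = sum_x sum_{i in N(x)} w(x, i, sigma) ||P(x) - P(i)||^2`,
#' with the patch differences taken from `image` and the weights frozen at
#' the values in `weights` (computed from the current estimate).
#'
#' @param image Numeric matrix.
#' @param weights A [weight_field()] computed on an image of the same size.
#' @return Nonnegative scalar.
#' @export
nl_penalty <- function(image, weights) {
  stopifnot(inherits(weights, "nchr_weight_field"),
            all(dim(image) == weights$dim))
  cpp_penalty(image, weights$w, weights$cfg$patch_size,
              weights$cfg$neighborhood_size)
}

#' Gradient of the non-local penalty under frozen weights
#'
#' The exact derivative of [nl_penalty()] with respect to every image pixel,
#' weights treated as constants — the search direction of the inner
#' steepest-descent loop.
#'
#' @inheritParams nl_penalty
#' @return Numeric matrix of the same size as `image`.
#' @export
nl_penalty_gradient <- function(image, weights) {
  stopifnot(inherits(weights, "nchr_weight_field"),
            all(dim(image) == weights$dim))
  cpp_penalty_gradient(image, weights$w, weights$cfg$patch_size,
                       weights$cfg$neighborhood_size)
}
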
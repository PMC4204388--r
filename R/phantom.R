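#' Specify a layered retina-like phantom
#'
#' Describes a noise-free reflectivity map emulating a retinal B-scan
#' cross-section: a dark background band at the top (vitreous), a stack of
#' horizontal tissue layers with gently curved boundaries, and optional
#' disc inclusions emulating vessel cross-sections. Boundary curvature is a
#' sinusoid with seed-drawn phases, so a spec plus its seed determines the
#' scene exactly.
#'
#' @param height,width Image size in pixels (rows are axial depth, columns
#'   are A-scan index).
#' @param layer_tops Strictly increasing base row index of each layer's upper
#'   boundary, in `(1, height]`.
#' @param layer_reflectivities One nonnegative reflectivity per layer. The
#'   background reflectivity must be strictly below the dimmest layer.
#' @param background_reflectivity Reflectivity of the band above the first
#'   layer (default 0, a signal-free region used for noise metrics).
#' @param wave_amplitude Peak boundary displacement in pixels (default 3).
#' @param wave_cycles Number of sinusoid cycles across the image width.
#' @param inclusions Optional list of `list(center = c(row, col), radius,
#'   reflectivity)` discs drawn on top of the layers.
#' @param roi_margin Erosion margin (pixels) between layer boundaries and the
#'   homogeneous ROI masks; defaults to the radius of the default 9x9 patch
#'   so metrics never straddle a boundary.
#' @param seed Integer seed controlling the boundary phases.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [default_phantom_spec()]
#' @export
phantom_spec <- function(height, width, layer_tops, layer_reflectivities,
                         background_reflectivity = 0,
                         wave_amplitude = 3, wave_cycles = 1.5,
                         inclusions = NULL, roi_margin = 4L, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < 8L || width < 8L)
    nchr_stop("nchr_invalid_spec", "phantom must be at least 8x8 pixels")
  L <- length(layer_tops)
  if (L < 1L || length(layer_reflectivities) != L)
    nchr_stop("nchr_invalid_spec",
              "need one reflectivity per layer (%d boundaries, %d values)",
              L, length(layer_reflectivities))
  if (any(diff(layer_tops) <= 0))
    nchr_stop("nchr_invalid_spec",
              "layer boundaries must be strictly increasing (zero-height layer)")
  if (layer_tops[1] <= 1 || layer_tops[L] > height)
    nchr_stop("nchr_invalid_spec", "layer boundaries must lie inside (1, height]")
  if (any(layer_reflectivities < 0) || background_reflectivity < 0)
    nchr_stop("nchr_invalid_spec", "reflectivities must be nonnegative")
  if (background_reflectivity >= min(layer_reflectivities))
    nchr_stop("nchr_invalid_spec",
              "background reflectivity must be strictly below every layer")
  if (wave_amplitude < 0)
    nchr_stop("nchr_invalid_spec", "wave_amplitude must be nonnegative")
  structure(list(
    height = height, width = width,
    layer_tops = as.numeric(layer_tops),
    layer_reflectivities = as.numeric(layer_reflectivities),
    background_reflectivity = background_reflectivity,
    wave_amplitude = wave_amplitude, wave_cycles = wave_cycles,
    inclusions = inclusions, roi_margin = as.integer(roi_margin),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Default 128x128 five-layer phantom
#'
#' Five layers with reflectivities spanning a 10:1 range over a zero-
#' reflectivity background band, boundaries perturbed by a sinusoid of
#' amplitude 3 px.
#'
#' @param seed Integer seed for the boundary phases.
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1L) {
  phantom_spec(
    height = 128L, width = 128L,
    layer_tops = c(25, 46, 67, 88, 109),
    layer_reflectivities = c(0.8, 0.3, 1.0, 0.1, 0.5),
    background_reflectivity = 0,
    wave_amplitude = 3, wave_cycles = 1.5,
    seed = seed
  )
}

#' Generate a phantom scene from a spec
#'
#' Renders the noise-free reflectivity map, the per-pixel layer labels, and
#' the ROI masks used by the quality metrics: one background mask inside the
#' zero-reflectivity top band and one homogeneous mask per layer interior,
#' eroded away from the boundaries by `roi_margin`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_scene`: a list with elements `clean`
#'   (numeric matrix), `labels` (integer matrix, 0 = background), `rois`
#'   (a [roi_set()]), and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    nchr_stop("nchr_invalid_spec", "spec must be a phantom_spec")
  H <- spec$height; W <- spec$width
  L <- length(spec$layer_tops)
  phases <- withr::with_seed(spec$seed, runif(L, 0, 2 * pi))
  xs <- (seq_len(W) - 1) / max(W - 1, 1)
  # per-column boundary rows, L x W
  B <- matrix(0L, L, W)
  for (j in seq_len(L)) {
    B[j, ] <- as.integer(round(
      spec$layer_tops[j] +
        spec$wave_amplitude * sin(2 * pi * spec$wave_cycles * xs + phases[j])
    ))
  }
  B <- pmin(pmax(B, 2L), H)
  if (any(apply(B, 2, function(b) any(diff(b) <= 0))))
    nchr_stop("nchr_invalid_spec",
              "curved boundaries overlap or invert; reduce wave_amplitude")

  labels <- matrix(0L, H, W)
  for (cidx in seq_len(W)) {
    b <- B[, cidx]
    for (j in seq_len(L)) {
      lo <- b[j]
      hi <- if (j < L) b[j + 1] - 1L else H
      labels[lo:hi, cidx] <- j
    }
  }
  refl <- c(spec$background_reflectivity, spec$layer_reflectivities)
  clean <- matrix(refl[labels + 1L], H, W)

  incl_mask <- matrix(FALSE, H, W)
  if (!is.null(spec$inclusions)) {
    rr <- row(clean); cc <- col(clean)
    for (inc in spec$inclusions) {
      d2 <- (rr - inc$center[1])^2 + (cc - inc$center[2])^2
      inside <- d2 <= inc$radius^2
      clean[inside] <- inc$reflectivity
      # exclude a dilated disc from the homogeneous-layer masks
      incl_mask <- incl_mask | (d2 <= (inc$radius + spec$roi_margin)^2)
    }
  }

  m <- spec$roi_margin
  bg <- matrix(FALSE, H, W)
  region <- vector("list", L)
  for (j in seq_len(L)) region[[j]] <- matrix(FALSE, H, W)
  for (cidx in seq_len(W)) {
    b <- B[, cidx]
    top <- b[1] - 1L - m
    if (top >= 1L) bg[1:top, cidx] <- TRUE
    for (j in seq_len(L)) {
      lo <- b[j] + m
      hi <- (if (j < L) b[j + 1] - 1L else H) - m
      if (hi >= lo) region[[j]][lo:hi, cidx] <- TRUE
    }
  }
  for (j in seq_len(L)) region[[j]] <- region[[j]] & !incl_mask
  sizes <- c(sum(bg), vapply(region, sum, 0))
  if (any(sizes < 50))
    nchr_stop("nchr_invalid_spec",
              "an ROI mask has fewer than 50 pixels; thicken the layers")

  structure(list(
    clean = clean, labels = labels,
    rois = roi_set(bg, region), spec = spec
  ), class = "phantom_scene")
}

#' Multiply an amplitude image by fully developed speckle
#'
#' Fully developed speckle is modeled as the magnitude of a unit-power
#' complex circular Gaussian field multiplying the amplitude, so the
#' expected speckled intensity (amplitude squared) at each pixel equals the
#' clean intensity.
#'
#' @param clean Nonnegative amplitude image (numeric matrix).
#' @param seed Integer seed; the same seed reproduces the speckle field.
#' @return Speckled amplitude image of the same size.
#' @export
apply_speckle <- function(clean, seed = 1L) {
  if (any(clean < 0))
    nchr_stop("nchr_domain_error", "speckle is multiplicative on amplitude; negative input pixel")
  n <- length(clean)
  z <- withr::with_seed(seed, {
    zr <- rnorm(n, 0, sqrt(0.5))
    zi <- rnorm(n, 0, sqrt(0.5))
    sqrt(zr^2 + zi^2)
  })
  clean * matrix(z, nrow(clean), ncol(clean))
}

#' Acquisition model for speed-scaled detector noise
#'
#' Detector noise is complex additive white Gaussian in k-space (where the
#' SD-OCT camera samples), with per-coefficient variance
#' `speed_factor * base_noise_std^2`: halving the exposure (doubling the
#' A-scan rate) doubles the noise variance.
#'
#' @param speed_factor Acquisition speed relative to the 47 kHz baseline
#'   (1 = 47 kHz, 4 = 188 kHz, 8 = 376 kHz); must be >= 1.
#' @param base_noise_std Complex noise standard deviation per k-space
#'   coefficient at `speed_factor = 1`.
#' @param speckle Apply fully developed speckle to the clean image first?
#' @param seed Integer seed for the speckle field (and, by default, offset
#'   by one for the noise draw).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(speed_factor = 1, base_noise_std = 0.03,
                              speckle = TRUE, seed = 1L) {
  if (speed_factor < 1)
    nchr_stop("nchr_invalid_model", "speed_factor must be >= 1")
  if (base_noise_std < 0)
    nchr_stop("nchr_invalid_model", "base_noise_std must be nonnegative")
  structure(list(
    speed_factor = speed_factor, base_noise_std = base_noise_std,
    speckle = isTRUE(speckle), seed = as.integer(seed)
  ), class = "acquisition_model")
}

#' Simulate a k-space acquisition of a phantom scene
#'
#' Forward model: optional speckle on the clean amplitude image, unitary
#' forward transform to k-space, then additive complex white Gaussian noise
#' with per-coefficient variance `speed_factor * base_noise_std^2`.
#'
#' @param scene A [generate_phantom()] scene.
#' @param acq An [acquisition_model()].
#' @param noise_seed Optional separate seed for the noise draw so the same
#'   speckle realization can be paired with independent noise realizations;
#'   defaults to `acq$seed + 1`.
#' @return A [kspace_measurement()] whose `meta` records the true complex
#'   noise standard deviation `sqrt(speed_factor) * base_noise_std`.
#' @export
simulate_acquisition <- function(scene, acq, noise_seed = NULL) {
  if (!inherits(scene, "phantom_scene"))
    nchr_stop("nchr_invalid_spec", "scene must be a phantom_scene")
  if (!inherits(acq, "acquisition_model"))
    nchr_stop("nchr_invalid_model", "acq must be an acquisition_model")
  img <- if (acq$speckle) apply_speckle(scene$clean, acq$seed) else scene$clean
  coeff <- forward_transform(img)
  noise_std <- sqrt(acq$speed_factor) * acq$base_noise_std
  if (noise_std > 0) {
    n <- length(coeff)
    sd_comp <- noise_std / sqrt(2)
    noise <- withr::with_seed(noise_seed %||% (acq$seed + 1L), {
      complex(real = rnorm(n, 0, sd_comp), imaginary = rnorm(n, 0, sd_comp))
    })
    coeff <- coeff + matrix(noise, nrow(coeff), ncol(coeff))
  }
  kspace_measurement(coeff, delta = NULL, meta = list(
    speed_factor = acq$speed_factor, base_noise_std = acq$base_noise_std,
    noise_std = noise_std, seed = acq$seed
  ))
}
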
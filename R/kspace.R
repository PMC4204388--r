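#' k-space measurement container
#'
#' Holds the complex coefficient array on the same lattice as the spatial
#' B-scan, plus the data-consistency tolerance `delta` once it has been set
#' (see [estimate_delta()]).
#'
#' @param coefficients Complex matrix.
#' @param delta Nonnegative tolerance, or `NULL` if not yet estimated.
#' @param meta Optional list of attributes (`speed_factor`, `noise_std`,
#'   `seed`, ...) carried through serialization.
#' @return An object of class `kspace_measurement`.
#' @export
kspace_measurement <- function(coefficients, delta = NULL, meta = list()) {
  if (!is.matrix(coefficients))
    nchr_stop("nchr_contract_error", "coefficients must be a matrix")
  if (!is.complex(coefficients)) storage.mode(coefficients) <- "complex"
  if (!is.null(delta) && (!is.finite(delta) || delta < 0))
    nchr_stop("nchr_contract_error", "delta must be a nonnegative number")
  structure(list(coefficients = coefficients, delta = delta, meta = meta),
            class = "kspace_measurement")
}

#' Unitary forward transform (spatial image to k-space)
#'
#' The unitary discrete Fourier transform of the whole B-scan (default), or
#' a per-A-scan 1-D transform along the axial (row) direction with
#' `mode = "axial"`. Unitarity makes the pair energy preserving, so Parseval
#' holds and the inverse is exact.
#'
#' @param image Real or complex matrix.
#' @param mode `"2d"` (default) or `"axial"`.
#' @return Complex coefficient matrix of the same size.
#' @export
forward_transform <- function(image, mode = c("2d", "axial")) {
  mode <- match.arg(mode)
  if (!all(is.finite(Re(image))) || !all(is.finite(Im(image))))
    nchr_stop("nchr_contract_error", "image contains non-finite values")
  if (mode == "2d") fft(image) / sqrt(length(image))
  else mvfft(image) / sqrt(nrow(image))
}

#' Unitary inverse transform (k-space to spatial image)
#'
#' Returns the real part of the inverse unitary transform; the magnitude of
#' the discarded imaginary residual is attached as attribute
#' `imag_residual`.
#'
#' @param coefficients Complex matrix.
#' @param mode `"2d"` (default) or `"axial"`.
#' @return Real matrix with attribute `imag_residual`.
#' @export
inverse_transform <- function(coefficients, mode = c("2d", "axial")) {
  mode <- match.arg(mode)
  if (!all(is.finite(Re(coefficients))) || !all(is.finite(Im(coefficients))))
    nchr_stop("nchr_contract_error", "coefficients contain non-finite values")
  z <- if (mode == "2d") fft(coefficients, inverse = TRUE) / sqrt(length(coefficients))
       else mvfft(coefficients, inverse = TRUE) / sqrt(nrow(coefficients))
  out <- Re(z)
  attr(out, "imag_residual") <- max(abs(Im(z)))
  out
}

#' Mask of high-frequency k-space coefficients
#'
#' Marks coefficients whose normalized frequency magnitude exceeds
#' `0.5 * (1 - fraction)` along *both* axes — a corner band that is
#' essentially signal-free for smooth layered scenes and can serve as the
#' noise-floor estimation region.
#'
#' @param dim Integer vector `c(rows, cols)`.
#' @param fraction Fraction of the [0, 0.5] frequency range (per axis)
#'   included in the band; default 0.25.
#' @return Logical matrix.
#' @export
highfreq_noise_mask <- function(dim, fraction = 0.25) {
  stopifnot(length(dim) == 2, fraction > 0, fraction < 1)
  f <- function(n) {
    i <- seq_len(n) - 1
    pmin(i, n - i) / n
  }
  thr <- 0.5 * (1 - fraction)
  outer(f(dim[1]) >= thr, f(dim[2]) >= thr, `&`)
}

#' Estimate the data-consistency tolerance delta from the noise floor
#'
#' `delta = kappa * noise_std`, where `noise_std` is the per-coefficient
#' complex noise standard deviation: either supplied directly (from
#' calibration frames or a known acquisition model) or estimated as the
#' root-mean-square magnitude of the coefficients inside a user-marked
#' signal-free band (see [highfreq_noise_mask()]).
#'
#' @param measurement A [kspace_measurement()].
#' @param noise_std Known noise standard deviation, if available.
#' @param kappa Multiplier converting the noise floor into the tolerance
#'   (default 3).
#' @param noise_mask Logical matrix marking a signal-free spectral band,
#'   used when `noise_std` is not supplied.
#' @return The tolerance (nonnegative scalar).
#' @export
estimate_delta <- function(measurement, noise_std = NULL, kappa = 3,
                           noise_mask = NULL) {
  stopifnot(inherits(measurement, "kspace_measurement"), kappa >= 0)
  if (is.null(noise_std)) {
    if (is.null(noise_mask))
      nchr_stop("nchr_cannot_estimate",
                "no noise_std given and no signal-free band marked")
    if (!all(dim(noise_mask) == dim(measurement$coefficients)))
      nchr_stop("nchr_contract_error", "noise_mask shape mismatch")
    px <- measurement$coefficients[noise_mask]
    if (length(px) < 2L)
      nchr_stop("nchr_cannot_estimate", "signal-free band is empty")
    noise_std <- sqrt(mean(Mod(px)^2))
  }
  if (noise_std < 0)
    nchr_stop("nchr_contract_error", "noise_std must be nonnegative")
  kappa * noise_std
}

#' Project reconstructed coefficients into the delta-ball of the data
#'
#' Per coefficient the deviation `d = est - F` is clamped radially:
#' `d <- d * min(1, delta / |d|)` (the complex generalization of the
#' three-branch scalar rule: pass if within delta, else pull back onto the
#' tolerance boundary). `mode = "separate"` instead clamps the real and
#' imaginary parts independently to `[-delta, delta]`. With `delta = 0` the
#' output equals the measurements exactly (hard data consistency).
#'
#' @param estimate_coeffs Complex matrix (the reconstructed spectrum).
#' @param measurement A [kspace_measurement()] with `delta` set.
#' @param mode `"radial"` (default, rotation invariant) or `"separate"`.
#' @return Complex matrix whose deviation magnitude from the measurements is
#'   everywhere `<= delta` (radial mode).
#' @export
project_to_tolerance <- function(estimate_coeffs, measurement,
                                 mode = c("radial", "separate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(measurement, "kspace_measurement"))
  F0 <- measurement$coefficients
  if (!all(dim(estimate_coeffs) == dim(F0)))
    nchr_stop("nchr_contract_error", "coefficient shape mismatch")
  delta <- measurement$delta
  if (is.null(delta) || !is.finite(delta) || delta < 0)
    nchr_stop("nchr_contract_error",
              "measurement delta is unset; run estimate_delta() first")
  if (delta == 0) return(F0)
  d <- estimate_coeffs - F0
  out <- estimate_coeffs
  if (mode == "radial") {
    # only touch coefficients outside the ball: in-tolerance ones pass
    # through bit-identically
    outside <- Mod(d) > delta
    out[outside] <- F0[outside] + d[outside] * (delta / Mod(d[outside]))
  } else {
    outside <- abs(Re(d)) > delta | abs(Im(d)) > delta
    out[outside] <- F0[outside] + complex(
      real = pmin(pmax(Re(d[outside]), -delta), delta),
      imaginary = pmin(pmax(Im(d[outside]), -delta), delta)
    )
  }
  out
}
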
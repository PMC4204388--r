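# Atomic write helper: write to a temp file in the target directory, then
# rename, so interrupted runs never leave truncated outputs.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    nchr_stop("nchr_io_error", "output directory does not exist: %s", dir)
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    nchr_stop("nchr_io_error", "could not move temporary file onto %s", path)
  invisible(path)
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) "tiff"
  else if (ext == "png") "png"
  else nchr_stop("nchr_unsupported_format",
                 "unsupported image extension '.%s' (use TIFF or PNG)", ext)
}

#' Read a grayscale B-scan image
#'
#' Accepts 8- or 16-bit grayscale TIFF or PNG; values are mapped to [0, 1]
#' floats. The original bit depth is recorded in the `bits` attribute, and a
#' `<path>.json` sidecar written by [write_oct_image()] (holding the min-max
#' scaling constants) is restored into the `scale_min` / `scale_max`
#' attributes when present.
#'
#' @param path File path.
#' @return Numeric matrix in [0, 1] with attributes `bits` and, when known,
#'   `scale_min` / `scale_max`.
#' @export
read_oct_image <- function(path) {
  if (!file.exists(path))
    nchr_stop("nchr_not_found", "no such file: %s", path)
  fmt <- image_format(path)
  if (fmt == "tiff") {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample") %||% 8L
  } else {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bits <- info$bit.depth %||% 8L
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L)
      nchr_stop("nchr_unsupported_format",
                "image has %d channels; only single-channel grayscale is supported",
                dim(img)[3])
    img <- img[, , 1]
  }
  if (!bits %in% c(8L, 16L))
    nchr_stop("nchr_unsupported_format",
              "unsupported bit depth %d (only 8 or 16)", bits)
  out <- matrix(as.numeric(img), nrow(img), ncol(img))
  attr(out, "bits") <- as.integer(bits)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "scale_min") <- meta$scale_min
    attr(out, "scale_max") <- meta$scale_max
  }
  out
}

#' Write a B-scan image as grayscale TIFF or PNG
#'
#' The image is min-max scaled into [0, 1] before quantization; the scaling
#' constants are stored in a `<path>.json` sidecar so the original intensity
#' range can be recovered. Writes are atomic.
#'
#' @param image Numeric matrix.
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @param bits Bit depth, 8 or 16 (default 16; PNG is written 8-bit by the
#'   underlying writer when `bits = 8`).
#' @return The path, invisibly.
#' @export
write_oct_image <- function(image, path, bits = 16L) {
  if (!bits %in% c(8L, 16L))
    nchr_stop("nchr_unsupported_format", "bits must be 8 or 16")
  fmt <- image_format(path)
  lo <- min(image); hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  atomic_write(path, function(tmp) {
    if (fmt == "tiff") tiff::writeTIFF(scaled, tmp, bits.per.sample = bits)
    else png::writePNG(scaled, tmp)
  })
  atomic_write(paste0(path, ".json"), function(tmp) {
    jsonlite::write_json(list(scale_min = lo, scale_max = hi, bits = bits),
                         tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Read / write a binary ROI mask (8-bit PNG, 0/255)
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `read_mask` returns a logical matrix; `write_mask` the path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  atomic_write(path, function(tmp) {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), tmp)
  })
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path))
    nchr_stop("nchr_not_found", "no such file: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img >= 0.5
}

#' Write a k-space measurement container
#'
#' JSON container with datasets `kspace_real` and `kspace_imag` (row-major
#' nested arrays) plus the attributes `delta`, `speed_factor`,
#' `base_noise_std`, `noise_std` and `seed` when known. Optionally bundles
#' the scene's clean image and ROI masks (`clean`, `mask_background`,
#' `mask_roi_<r>`). Writes are atomic.
#'
#' @param measurement A [kspace_measurement()].
#' @param path Output path (`.json`).
#' @param scene Optional [generate_phantom()] scene to bundle.
#' @return The path, invisibly.
#' @export
write_kspace <- function(measurement, path, scene = NULL) {
  stopifnot(inherits(measurement, "kspace_measurement"))
  obj <- list(
    kspace_real = Re(measurement$coefficients),
    kspace_imag = Im(measurement$coefficients)
  )
  attrs <- measurement$meta
  attrs$delta <- measurement$delta
  obj$attributes <- attrs[!vapply(attrs, is.null, TRUE)]
  if (!is.null(scene)) {
    obj$clean <- scene$clean
    obj$mask_background <- scene$rois$background * 1
    for (r in seq_along(scene$rois$regions))
      obj[[paste0("mask_roi_", r)]] <- scene$rois$regions[[r]] * 1
  }
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  })
  invisible(path)
}

#' Read a k-space measurement container
#'
#' @param path Path written by [write_kspace()].
#' @return A [kspace_measurement()]; `delta` is `NULL` when the container
#'   carries no delta attribute (estimate it before reconstructing).
#' @export
read_kspace <- function(path) {
  if (!file.exists(path))
    nchr_stop("nchr_not_found", "no such file: %s", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    nchr_stop("nchr_malformed_container",
                              "cannot parse container: %s", conditionMessage(e)))
  for (k in c("kspace_real", "kspace_imag"))
    if (is.null(obj[[k]]) || !is.matrix(obj[[k]]))
      nchr_stop("nchr_malformed_container", "container missing dataset '%s'", k)
  if (!all(dim(obj$kspace_real) == dim(obj$kspace_imag)))
    nchr_stop("nchr_malformed_container",
              "kspace_real/kspace_imag shape mismatch")
  coeff <- matrix(complex(real = obj$kspace_real, imaginary = obj$kspace_imag),
                  nrow(obj$kspace_real), ncol(obj$kspace_real))
  attrs <- obj$attributes %||% list()
  kspace_measurement(coeff, delta = attrs$delta,
                     meta = attrs[setdiff(names(attrs), "delta")])
}

#' Write a quality report or trace as JSON
#'
#' @param report A list or `quality_report`.
#' @param path Output `.json` path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}
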
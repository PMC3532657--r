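#' Raw camera frame
#'
#' Integer (or, for noise-free phantoms, real-valued) pixel counts together
#' with the exposure time needed to convert them to emission rates.
#'
#' @param pixels numeric matrix of non-negative counts.
#' @param exposure_time exposure time in ms (> 0).
#' @param bit_depth ADC bit depth.
#' @param metadata free-form acquisition record (named list); `pixel_pitch`
#'   (um/pixel) and `dark_offset` are honored downstream when present.
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, exposure_time, bit_depth = 16L, metadata = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) stopf("pixels must be a numeric matrix")
  if (any(pixels < 0)) stopf("pixel counts must be non-negative")
  if (is.null(exposure_time) || !is_count(exposure_time) || exposure_time <= 0) {
    stopf("exposure_time must be a positive duration in ms")
  }
  if (any(pixels > 2^bit_depth - 1 + 0.5)) {
    stopf("pixel counts exceed the %d-bit ADC ceiling", bit_depth)
  }
  structure(list(pixels = pixels, exposure_time = exposure_time,
                 bit_depth = as.integer(bit_depth), metadata = metadata),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("raw_image: %d x %d px, %g ms, %d-bit, counts in [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$exposure_time, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Exposure-normalized emission-rate map
#'
#' The time-independent intensity: background-subtracted counts divided by
#' exposure time, in counts/s/pixel.
#'
#' @param rates numeric matrix, counts/s.
#' @param provenance named list recording at least the background method used;
#'   `pixel_pitch` is carried here for area conversions.
#' @return An object of class `emission_rate_image`.
#' @export
emission_rate_image <- function(rates, provenance = list()) {
  if (!is.matrix(rates) || !is.numeric(rates)) stopf("rates must be a numeric matrix")
  if (any(!is.finite(rates))) stopf("rates must be finite")
  if (any(rates < 0)) stopf("rates must be non-negative (floored at 0)")
  structure(list(rates = rates, provenance = provenance),
            class = "emission_rate_image")
}

#' @export
print.emission_rate_image <- function(x, ...) {
  cat(sprintf("emission_rate_image: %d x %d px, rates in [%.3g, %.3g] counts/s (background: %s)\n",
              nrow(x$rates), ncol(x$rates), min(x$rates), max(x$rates),
              x$provenance$background_method %||% "unknown"))
  invisible(x)
}

# accept either an emission_rate_image or a bare matrix of rates
rate_matrix <- function(img) {
  if (inherits(img, "emission_rate_image")) img$rates
  else if (is.matrix(img)) img
  else stopf("expected an emission_rate_image or a rate matrix")
}

img_pitch <- function(img, default = NA_real_) {
  if (inherits(img, "emission_rate_image")) img$provenance$pixel_pitch %||% default
  else if (inherits(img, "raw_image")) img$metadata$pixel_pitch %||% default
  else default
}
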
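#' Acquisition geometry and camera model
#'
#' Describes the wide-field imaging head: pixel pitch at 1:1 magnification,
#' frame shape, exposure time, and the CCD noise/offset parameters used by the
#' phantom generators. The defaults place about 1385 x 1015 pixels across a
#' 9.0 x 6.6 mm field of view at 6.5 um/pixel.
#'
#' @param pixel_pitch pixel pitch in um/pixel at 1:1 magnification.
#' @param frame_shape integer vector `c(rows, cols)`.
#' @param exposure_time exposure time in ms.
#' @param bit_depth ADC bit depth; counts are clipped to `2^bit_depth - 1`.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param dark_offset constant dark/bias offset in counts.
#' @param full_well saturation ceiling in counts.
#' @return An object of class `acquisition_spec`.
#' @examples
#' spec <- acquisition_spec(frame_shape = c(120, 160), exposure_time = 50)
#' field_of_view(spec) # mm
#' @export
acquisition_spec <- function(pixel_pitch = 6.5,
                             frame_shape = c(1015L, 1385L),
                             exposure_time = 100,
                             bit_depth = 16L,
                             read_noise_sd = 5,
                             dark_offset = 100,
                             full_well = 60000) {
  if (!is_count(pixel_pitch) || pixel_pitch <= 0) stopf("pixel_pitch must be > 0")
  if (!is_count(exposure_time) || exposure_time <= 0) stopf("exposure_time must be > 0 ms")
  if (!is_count(dark_offset)) stopf("dark_offset must be >= 0")
  if (length(frame_shape) != 2 || any(frame_shape < 1)) {
    stopf("frame_shape must be c(rows, cols) with positive entries")
  }
  if (!is_count(bit_depth) || bit_depth < 8 || bit_depth > 32) {
    stopf("bit_depth must lie in [8, 32]")
  }
  structure(list(
    pixel_pitch = pixel_pitch,
    frame_shape = as.integer(frame_shape),
    exposure_time = exposure_time,
    bit_depth = as.integer(bit_depth),
    read_noise_sd = read_noise_sd,
    dark_offset = dark_offset,
    full_well = full_well
  ), class = "acquisition_spec")
}

#' Field of view implied by an acquisition spec
#' @param spec an [acquisition_spec()].
#' @return numeric `c(width_mm, height_mm)` (cols x pitch, rows x pitch).
#' @export
field_of_view <- function(spec) {
  stopifnot(inherits(spec, "acquisition_spec"))
  c(width_mm = spec$frame_shape[2] * spec$pixel_pitch / 1000,
    height_mm = spec$frame_shape[1] * spec$pixel_pitch / 1000)
}

#' @export
print.acquisition_spec <- function(x, ...) {
  fov <- field_of_view(x)
  cat(sprintf(
    "acquisition_spec: %d x %d px @ %.2f um/px (%.1f x %.1f mm), %g ms, %d-bit\n",
    x$frame_shape[1], x$frame_shape[2], x$pixel_pitch, fov[1], fov[2],
    x$exposure_time, x$bit_depth))
  invisible(x)
}

# max representable count after ADC clipping
adc_ceiling <- function(spec) min(2^spec$bit_depth - 1, spec$full_well)

#' Simulate camera counts from an emission-rate map
#'
#' Applies the CCD forward model: `counts = Poisson(rate * t) + N(0, read) +
#' dark_offset`, rounded and clipped to the ADC range. With `noise = "off"`
#' the counts are the exact (real-valued) expectation `rate * t + dark_offset`
#' so that exposure normalization round-trips losslessly.
#'
#' @param rates matrix of emission rates in counts/s/pixel.
#' @param spec an [acquisition_spec()]; `exposure_time` may be overridden.
#' @param exposure_time ms; defaults to `spec$exposure_time`.
#' @param noise `"on"` or `"off"`.
#' @return A [raw_image()] carrying the spec fields in its metadata.
#' @keywords internal
expose_frame <- function(rates, spec, exposure_time = spec$exposure_time,
                         noise = c("on", "off")) {
  noise <- match.arg(noise)
  t_s <- exposure_time / 1000
  lambda <- rates * t_s
  if (noise == "off") {
    counts <- lambda + spec$dark_offset
  } else {
    n <- length(lambda)
    counts <- stats::rpois(n, lambda) +
      stats::rnorm(n, 0, spec$read_noise_sd) + spec$dark_offset
    counts <- round(pmin(pmax(counts, 0), adc_ceiling(spec)))
    dim(counts) <- dim(lambda)
  }
  raw_image(counts, exposure_time, bit_depth = spec$bit_depth,
            metadata = list(pixel_pitch = spec$pixel_pitch,
                            dark_offset = spec$dark_offset,
                            read_noise_sd = spec$read_noise_sd,
                            full_well = spec$full_well,
                            noise = noise))
}
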
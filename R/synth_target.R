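#' Synthesize a bar-pattern resolution target
#'
#' Renders square-wave bar groups (three bars per group, the USAF-1951
#' convention) at the requested spatial frequencies, optically blurred by a
#' Gaussian of `blur_sigma` micrometres, and exposes the scene through the
#' camera model. The blurred profile is evaluated in closed form at pixel
#' centres; bar and gap centres are aligned to pixel centres so measured
#' extrema sample the continuum extrema.
#'
#' The bar pattern oscillates between `bright_rate/2 * (1 - contrast)` and
#' `bright_rate/2 * (1 + contrast)`, so an unblurred target on a zero
#' background has square-wave contrast exactly `contrast`.
#'
#' @param spec an [acquisition_spec()].
#' @param frequencies spatial frequencies in line cycles/mm.
#' @param blur_sigma Gaussian blur sigma in um (0 = none).
#' @param contrast square-wave contrast of the rendered pattern, in (0, 1].
#' @param bright_rate peak-to-peak emission amplitude in counts/s.
#' @param background_rate pedestal emission rate outside the groups.
#' @param orientation `"vertical"` bars (modulation along columns) or
#'   `"horizontal"` (modulation along rows).
#' @param noise `"off"` (exact expectation counts) or `"on"` (shot + read).
#' @param seed integer seed for the noise draw.
#' @return list with `image` (a [raw_image()]), `rates` (the noiseless
#'   emission-rate matrix) and `groups`, a data.frame of annotations with one
#'   row per group: `frequency`, `orientation`, bounding box `row0,row1,
#'   col0,col1` (1-based, inclusive) and `x0_um`, the position of the left
#'   edge of the measurement box along the modulation axis. Each box spans
#'   three full line cycles: half a period of margin, three bars, and the two
#'   gaps between them.
#' @export
make_bar_target <- function(spec, frequencies, blur_sigma = 0, contrast = 1,
                            bright_rate = 1000, background_rate = 0,
                            orientation = c("vertical", "horizontal"),
                            noise = c("off", "on"), seed = NULL) {
  orientation <- match.arg(orientation)
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "acquisition_spec"))
  if (contrast <= 0 || contrast > 1) stopf("contrast must lie in (0, 1]")
  if (blur_sigma < 0) stopf("blur_sigma must be >= 0")
  p <- spec$pixel_pitch
  f_nyq <- 1000 / (2 * p)
  bad <- frequencies[1000 / frequencies < 2 * p]
  if (length(bad) > 0) {
    stopf("frequencies %s cycles/mm exceed the Nyquist limit %.1f cycles/mm at %.2f um/pixel",
          paste(signif(bad, 4), collapse = ", "), f_nyq, p)
  }
  shape <- spec$frame_shape
  if (orientation == "horizontal") shape <- rev(shape)
  nr <- shape[1]; nc <- shape[2]

  m <- bright_rate / 2
  rates <- matrix(background_rate, nr, nc)
  xs <- (seq_len(nc) - 0.5) * p
  groups <- NULL
  row_cursor <- 5L
  for (f in frequencies) {
    period <- 1000 / f        # um
    w <- period / 2           # bar width, um
    len_px <- max(8L, ceiling(6 * w / p))         # bar length along the bars
    if (row_cursor + len_px + 4L > nr) {
      stopf("frame too small to stack %d groups at this pitch", length(frequencies))
    }
    # first bar centre on a pixel centre, with a half-period of left margin
    j0 <- max(ceiling(w / p) + 2L, 3L)
    centers <- (j0 - 0.5) * p + (0:2) * period
    x_hi <- centers[3] + w
    if (x_hi + p > nc * p) stopf("frame too narrow for frequency %.3g cycles/mm", f)
    prof <- blurred_bar_profile(xs, centers, w, blur_sigma)
    band <- row_cursor:(row_cursor + len_px - 1L)
    rates[band, ] <- rep(m * (1 - contrast) + 2 * m * contrast * prof,
                         each = length(band)) + background_rate
    x_lo <- centers[1] - w
    col0 <- ceiling(x_lo / p + 0.5)
    col1 <- floor(x_hi / p + 0.5)
    groups <- rbind(groups, data.frame(
      frequency = f, orientation = orientation,
      row0 = row_cursor, row1 = row_cursor + len_px - 1L,
      col0 = col0, col1 = col1, x0_um = x_lo))
    row_cursor <- row_cursor + len_px + 4L
  }
  if (orientation == "horizontal") {
    rates <- t(rates)
    groups <- data.frame(frequency = groups$frequency,
                         orientation = groups$orientation,
                         row0 = groups$col0, row1 = groups$col1,
                         col0 = groups$row0, col1 = groups$row1,
                         x0_um = groups$x0_um)
  }
  img <- with_rng(seed, expose_frame(rates, spec, noise = noise))
  img$metadata$seed <- seed
  list(image = img, rates = rates, groups = groups)
}

# closed-form Gaussian-blurred 3-bar square wave: sum of blurred boxes,
# amplitude in [0, 1]
blurred_bar_profile <- function(x, centers, half_period, sigma) {
  prof <- numeric(length(x))
  for (c0 in centers) {
    prof <- prof + if (sigma > 0) {
      stats::pnorm((x - c0 + half_period / 2) / sigma) -
        stats::pnorm((x - c0 - half_period / 2) / sigma)
    } else {
      as.numeric(abs(x - c0) < half_period / 2 * (1 - 1e-12))
    }
  }
  pmin(prof, 1)
}
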
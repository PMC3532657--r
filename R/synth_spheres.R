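# stamp a uniform-rate disc into a rate matrix (pixel-centre inclusion),
# touching only its bounding box
stamp_disc <- function(rates, center_um, diameter_um, rate, pixel_pitch,
                       field = NULL) {
  nr <- nrow(rates); nc <- ncol(rates)
  r_um <- diameter_um / 2
  r0 <- max(1L, floor((center_um[1] - r_um) / pixel_pitch))
  r1 <- min(nr, ceiling((center_um[1] + r_um) / pixel_pitch) + 1L)
  c0 <- max(1L, floor((center_um[2] - r_um) / pixel_pitch))
  c1 <- min(nc, ceiling((center_um[2] + r_um) / pixel_pitch) + 1L)
  yc <- (r0:r1 - 0.5) * pixel_pitch
  xc <- (c0:c1 - 0.5) * pixel_pitch
  inside <- outer((yc - center_um[1])^2, (xc - center_um[2])^2, "+") <= r_um^2
  if (!any(inside)) {
    # sub-pitch disc between pixel centres: claim the pixel holding the centre
    inside[min(max(ceiling(center_um[1] / pixel_pitch), r0), r1) - r0 + 1L,
           min(max(ceiling(center_um[2] / pixel_pitch), c0), c1) - c0 + 1L] <- TRUE
  }
  block <- rates[r0:r1, c0:c1, drop = FALSE]
  val <- if (is.null(field)) rate else rate * field[r0:r1, c0:c1, drop = FALSE][inside]
  block[inside] <- val
  rates[r0:r1, c0:c1] <- block
  rates
}

#' Synthesize a microsphere calibration series
#'
#' Emulates imaging fluorescent microspheres of graded nominal brightness in a
#' flow channel: for every (nominal fraction, exposure time) pair one frame is
#' rendered with the same non-overlapping sphere placements, so intensity
#' ratios and exposure ratios are exact by construction. Nominal fractions are
#' relative to the brightest sphere (the instrument was characterized over
#' 0.4% to 100% and 1-250 ms).
#'
#' @param spec an [acquisition_spec()].
#' @param nominal_fractions relative emission levels in (0, 1].
#' @param exposure_times exposure times in ms, all > 0.
#' @param sphere_diameter sphere diameter in um (default 6).
#' @param n_spheres spheres per frame (>= 15).
#' @param brightest_rate emission rate of a fraction-1 sphere, counts/s;
#'   clamped so no sphere can exceed `full_well` at the longest exposure.
#' @param noise `"on"` or `"off"`.
#' @param seed integer seed (placements and noise).
#' @return list with `frames` (nested list `frames[[i]][[j]]` of
#'   [raw_image()]s for fraction i, exposure j), `fractions`, `exposures`, and
#'   `truth`, a data.frame of per-sphere centroids (um) and true emission
#'   rates (counts/s).
#' @export
make_microsphere_series <- function(spec, nominal_fractions, exposure_times,
                                    sphere_diameter = 6, n_spheres = 20L,
                                    brightest_rate = 20000,
                                    noise = c("on", "off"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "acquisition_spec"))
  if (any(nominal_fractions <= 0 | nominal_fractions > 1)) {
    stopf("nominal_fractions must lie in (0, 1]")
  }
  if (any(exposure_times <= 0)) stopf("exposure_times must be > 0 ms")
  if (n_spheres < 15L) stopf("need >= 15 spheres per frame")
  p <- spec$pixel_pitch
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  # saturation guard: truth rates may never exceed full_well / exposure
  rate_cap <- spec$full_well / (max(exposure_times) / 1000)
  with_rng(seed, {
    margin <- sphere_diameter + 2 * p
    min_sep <- 2 * sphere_diameter + 2 * p
    centers <- matrix(NA_real_, n_spheres, 2)
    placed <- 0L; tries <- 0L; max_tries <- 2000L * n_spheres
    while (placed < n_spheres) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stopf(paste("cannot place %d non-overlapping %g-um spheres in a %.0f x %.0f um frame",
                    "(density limit: ~%.0f at %.0f um separation)"),
              n_spheres, sphere_diameter, nr * p, nc * p,
              floor(nr * p * nc * p / (pi * min_sep^2)), min_sep)
      }
      cand <- c(stats::runif(1, margin, nr * p - margin),
                stats::runif(1, margin, nc * p - margin))
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
              (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < min_sep^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    truth <- NULL
    frames <- vector("list", length(nominal_fractions))
    for (i in seq_along(nominal_fractions)) {
      fr <- nominal_fractions[i]
      rate <- min(fr * brightest_rate, fr * rate_cap)
      truth <- rbind(truth, data.frame(
        fraction = fr, sphere_id = seq_len(n_spheres),
        center_row_um = centers[, 1], center_col_um = centers[, 2],
        diameter_um = sphere_diameter, rate = rate))
      base <- matrix(0, nr, nc)
      for (s in seq_len(n_spheres)) {
        base <- stamp_disc(base, centers[s, ], sphere_diameter, rate, p)
      }
      frames[[i]] <- lapply(exposure_times, function(e) {
        expose_frame(base, spec, exposure_time = e, noise = noise)
      })
    }
    list(frames = frames, fractions = nominal_fractions,
         exposures = exposure_times, truth = truth, spec = spec)
  })
}
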
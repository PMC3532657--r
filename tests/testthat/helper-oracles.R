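# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the CTF oracle is a brute-force 1-D numerical
# convolution on a fine grid; the Kaplan-Meier oracle re-derives risk sets by
# full scans; disc rasterization is re-enumerated over the pixel lattice.

# square-wave contrast of a Gaussian-blurred 3-bar pattern, by direct 1-D
# numerical convolution at dx = 0.05 um; same extremum summary as the
# measurement definition (per-bar maxima, per-gap minima)
ctf_conv_oracle <- function(freq_cycles_mm, sigma_um, contrast = 1,
                            bright = 1000, dx = 0.05) {
  period <- 1000 / freq_cycles_mm
  w <- period / 2
  half <- 6 * max(sigma_um, w)
  x <- seq(-half, 5 * w + half, by = dx)
  sq <- as.numeric((x >= 0 & x < w) | (x >= 2 * w & x < 3 * w) |
                     (x >= 4 * w & x < 5 * w))
  if (sigma_um > 0) {
    kx <- seq(-6 * sigma_um, 6 * sigma_um, by = dx)
    k <- stats::dnorm(kx, 0, sigma_um) * dx
    sm <- stats::convolve(sq, rev(k), type = "open")
    off <- (length(k) - 1) / 2
    sm <- sm[(off + 1):(off + length(sq))]
  } else sm <- sq
  m <- bright / 2
  prof <- m * (1 - contrast) + 2 * m * contrast * pmin(sm, 1)
  win <- function(c0) prof[x >= c0 - w / 2 & x <= c0 + w / 2]
  i_max <- mean(vapply(c(0.5, 2.5, 4.5) * w, function(c0) max(win(c0)), 1))
  i_min <- mean(vapply(c(1.5, 3.5) * w, function(c0) min(win(c0)), 1))
  (i_max - i_min) / (i_max + i_min)
}

# brute-force product-limit estimate: risk sets recomputed by scanning the
# records at every distinct event time
km_brute_oracle <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  gsum <- 0
  out <- data.frame(time = et, survival = NA_real_, variance = NA_real_)
  for (i in seq_along(et)) {
    n <- 0L; d <- 0L
    for (j in seq_along(time)) {
      if (time[j] >= et[i]) n <- n + 1L
      if (time[j] == et[i] && event[j] == 1) d <- d + 1L
    }
    s <- s * (n - d) / n
    gsum <- if (n > d) gsum + d / (n * (n - d)) else Inf
    out$survival[i] <- s
    out$variance[i] <- if (is.finite(gsum)) s^2 * gsum else 0
  }
  out
}

# count of lattice pixel centres inside a disc — rasterization oracle
disc_pixel_count_oracle <- function(center_um, diameter_um, pitch, n_grid = 400) {
  cnt <- 0L
  for (r in seq_len(n_grid)) {
    for (cc in seq_len(n_grid)) {
      dy <- (r - 0.5) * pitch - center_um[1]
      dxx <- (cc - 0.5) * pitch - center_um[2]
      if (dy * dy + dxx * dxx <= (diameter_um / 2)^2) cnt <- cnt + 1L
    }
  }
  cnt
}

# 1-2 residual clusters >= 16 um at tumor-level emission, random positions
# inside the central region of the default 120 x 160 @ 6.5 um frame
draw_residual_clusters <- function(seed, tumor_rate = 2400) {
  set.seed(seed)
  ncl <- sample(1:2, 1)
  data.frame(diameter_um = stats::runif(ncl, 16, 60),
             rate = tumor_rate,
             center_row_um = stats::runif(ncl, 160, 620),
             center_col_um = stats::runif(ncl, 160, 880))
}

small_spec <- function(...) {
  acquisition_spec(frame_shape = c(120L, 160L), exposure_time = 100, ...)
}

# raw frame of given uniform rates at an arbitrary exposure (noise off)
reexpose <- function(rates, spec, exposure_ms) {
  residuoscope:::expose_frame(rates, spec, exposure_time = exposure_ms,
                              noise = "off")
}
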
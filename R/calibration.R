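#' Normalize a raw frame by exposure time
#'
#' Converts counts to the time-independent emission rate in counts/s:
#' `(counts - background) / exposure_seconds`, floored at zero. The background
#' estimate defaults to the camera's dark offset when the image metadata
#' carries one, falling back to the 1st percentile of the frame; it can be
#' forced to a number, a percentile, or disabled.
#'
#' @param img a [raw_image()].
#' @param background `"auto"` (metadata dark offset, else 1st percentile),
#'   `"percentile"` (1st percentile), `"none"`, or a numeric scalar in counts.
#' @param saturation_fraction pixels at or above this fraction of full scale
#'   are flagged as saturated (default 0.98).
#' @return An [emission_rate_image()]; provenance records the background
#'   method and value, the exposure time, the saturated-pixel fraction (with a
#'   warning note when it exceeds 1%), and the pixel pitch when known.
#' @export
normalize_by_exposure <- function(img, background = "auto",
                                  saturation_fraction = 0.98) {
  if (!inherits(img, "raw_image")) stopf("img must be a raw_image")
  if (is.null(img$exposure_time) || img$exposure_time <= 0) {
    stopf("exposure_time missing or zero: cannot normalize")
  }
  counts <- img$pixels
  if (is.numeric(background)) {
    bg <- background; method <- "fixed"
  } else {
    method <- match.arg(background, c("auto", "percentile", "none"))
    if (method == "auto" && !is.null(img$metadata$dark_offset)) {
      bg <- img$metadata$dark_offset; method <- "dark_offset"
    } else if (method == "none") {
      bg <- 0
    } else {
      bg <- stats::quantile(counts, 0.01, names = FALSE); method <- "percentile1"
    }
  }
  full_scale <- min(2^img$bit_depth - 1, img$metadata$full_well %||% Inf)
  sat_frac <- mean(counts >= saturation_fraction * full_scale)
  t_s <- img$exposure_time / 1000
  rates <- pmax(counts - bg, 0) / t_s
  prov <- list(source_id = img$metadata$source_id %||% NA_character_,
               background_method = method, background_value = bg,
               exposure_time_ms = img$exposure_time,
               saturated_fraction = sat_frac,
               pixel_pitch = img$metadata$pixel_pitch)
  if (sat_frac > 0.01) {
    prov$warning <- sprintf("%.1f%% of pixels saturated", 100 * sat_frac)
    warning(prov$warning, call. = FALSE)
  }
  emission_rate_image(rates, prov)
}

new_linearity_fit <- function(fit, n) {
  # noise-off series fit exactly; silence summary.lm's perfect-fit warning
  s <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 residual_sd = s$sigma,
                 n_points = n), class = "linearity_fit")
}

#' @export
print.linearity_fit <- function(x, ...) {
  cat(sprintf("linearity_fit: slope %.6g, intercept %.6g, r^2 %.6f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit the device's exposure-time linearity
#'
#' Least-squares line of mean sphere counts against exposure time; on an
#' ideal detector the intercept is the dark offset and r-squared is 1.
#'
#' @param measurements data.frame with columns `exposure_ms` and
#'   `mean_counts` (one row per exposure, averaged over spheres).
#' @return A `linearity_fit` with slope, intercept, r_squared, residual_sd
#'   and n_points.
#' @export
fit_exposure_linearity <- function(measurements) {
  x <- measurements$exposure_ms; y <- measurements$mean_counts
  if (is.null(x) || is.null(y)) stopf("need columns exposure_ms and mean_counts")
  if (length(unique(x)) < 3) stopf("need >= 3 distinct exposure times")
  new_linearity_fit(stats::lm(y ~ x), length(x))
}

#' Fit the device's intensity linearity
#'
#' Least-squares line of mean emission rate against nominal relative
#' fluorescence (the instrument was characterized over a 250-fold, 0.4% to
#' 100% range).
#'
#' @param measurements data.frame with columns `fraction` and `mean_rate`.
#' @return A `linearity_fit`; the slope estimates the brightest sphere's
#'   emission rate.
#' @export
fit_intensity_linearity <- function(measurements) {
  x <- measurements$fraction; y <- measurements$mean_rate
  if (is.null(x) || is.null(y)) stopf("need columns fraction and mean_rate")
  if (length(unique(x)) < 3) stopf("need >= 3 distinct nominal fractions")
  new_linearity_fit(stats::lm(y ~ x), length(x))
}

# mean intensity of one sphere: pixels within (radius + margin_px) of the
# centroid. Margin defaults to 0: with the generator's flat-top spheres a
# positive margin mixes in background pixels and biases the disc mean low by
# (r / (r + margin))^2, which would break intensity-slope recovery; a margin
# of 1 px is available for blurred or real data.
sphere_mean <- function(mat, center_um, diameter_um, pixel_pitch,
                        margin_px = 0) {
  m <- disc_mask(dim(mat), center_um,
                 diameter_um + 2 * margin_px * pixel_pitch, pixel_pitch)
  mean(mat[m])
}

#' Measure a microsphere series for the linearity fits
#'
#' For every (fraction, exposure) frame, averages each sphere's intensity
#' over a fixed-radius disc (sphere radius + 1 pixel) about its centroid,
#' then averages over spheres. Centroids come from the generator's truth
#' table by default, or from [detect_spheres()].
#'
#' @param series output of [make_microsphere_series()].
#' @param detect if TRUE, re-detect centroids from each frame instead of
#'   using the truth table.
#' @return data.frame with one row per (fraction, exposure): `fraction`,
#'   `exposure_ms`, `mean_counts` (raw), `mean_rate` (exposure-normalized,
#'   dark-offset subtracted).
#' @export
measure_sphere_series <- function(series, detect = FALSE) {
  out <- NULL
  for (i in seq_along(series$fractions)) {
    fr <- series$fractions[i]
    tt <- series$truth[series$truth$fraction == fr, ]
    for (j in seq_along(series$exposures)) {
      img <- series$frames[[i]][[j]]
      centers <- if (detect) {
        detect_spheres(normalize_by_exposure(img), tt$diameter_um[1], nrow(tt))
      } else {
        data.frame(center_row_um = tt$center_row_um,
                   center_col_um = tt$center_col_um)
      }
      rimg <- normalize_by_exposure(img)
      mc <- mr <- numeric(nrow(centers))
      for (s in seq_len(nrow(centers))) {
        ctr <- c(centers$center_row_um[s], centers$center_col_um[s])
        mc[s] <- sphere_mean(img$pixels, ctr, tt$diameter_um[1],
                             img$metadata$pixel_pitch %||% series$spec$pixel_pitch)
        mr[s] <- sphere_mean(rimg$rates, ctr, tt$diameter_um[1],
                             img$metadata$pixel_pitch %||% series$spec$pixel_pitch)
      }
      out <- rbind(out, data.frame(fraction = fr,
                                   exposure_ms = series$exposures[j],
                                   mean_counts = mean(mc), mean_rate = mean(mr)))
    }
  }
  out
}

#' Detect bright spheres by local-maximum search
#'
#' Median-filters the rate image, thresholds it (Otsu), and greedily picks
#' the `n` brightest local maxima at least one sphere diameter apart.
#'
#' @param img an [emission_rate_image()].
#' @param diameter_um expected sphere diameter in um.
#' @param n number of spheres to return.
#' @return data.frame of centroids `center_row_um`, `center_col_um`.
#' @export
detect_spheres <- function(img, diameter_um, n) {
  p <- img$provenance$pixel_pitch
  if (is.null(p) || is.na(p)) stopf("pixel pitch unknown: cannot detect spheres")
  sm <- median_filter3(rate_matrix(img))
  thr <- otsu_threshold(sm)
  lab <- label_components(sm > thr, 8L)
  sizes <- attr(lab, "sizes")
  if (length(sizes) < n) stopf("found only %d candidate spheres, expected %d",
                               length(sizes), n)
  # centroid and peak brightness per component; keep the n brightest
  stats_df <- do.call(rbind, lapply(seq_along(sizes), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    data.frame(row = mean(idx[, 1]), col = mean(idx[, 2]),
               peak = max(sm[lab == k]))
  }))
  stats_df <- stats_df[order(-stats_df$peak), ][seq_len(n), ]
  data.frame(center_row_um = (stats_df$row - 0.5) * p,
             center_col_um = (stats_df$col - 0.5) * p)
}
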
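#' Measure bar-group contrast
#'
#' Averages the image along the bar direction inside the annotated box to
#' obtain a 1-D profile perpendicular to the bars, then takes `i_max` as the
#' mean of the per-cycle maxima (one window of one bar width centred on each
#' of the three bar positions) and `i_min` as the mean of the per-cycle minima
#' in the two gaps between consecutive bright bars. Windows are located from
#' the annotated frequency and the box's left edge (`x0_um`), following the
#' annotation convention of [make_bar_target()]: each box spans three full
#' line cycles.
#'
#' @param img an [emission_rate_image()] (or a rate matrix, in which case
#'   `pixel_pitch` must be supplied).
#' @param group one-row data.frame from a [make_bar_target()] annotation
#'   (`frequency`, `orientation`, `row0,row1,col0,col1`, `x0_um`).
#' @param pixel_pitch um/pixel; defaults to the image provenance.
#' @return An object of class `bar_group_measurement` with fields
#'   `frequency`, `i_max`, `i_min`.
#' @export
measure_bar_contrast <- function(img, group, pixel_pitch = NULL) {
  rates <- rate_matrix(img)
  p <- pixel_pitch %||% img_pitch(img)
  if (is.null(p) || is.na(p)) stopf("pixel pitch unknown: supply pixel_pitch")
  if (group$row0 < 1 || group$col0 < 1 ||
      group$row1 > nrow(rates) || group$col1 > ncol(rates)) {
    stopf("annotation box lies outside the frame")
  }
  box <- rates[group$row0:group$row1, group$col0:group$col1, drop = FALSE]
  if (identical(group$orientation, "horizontal")) box <- t(box)
  prof <- colMeans(box)  # profile perpendicular to the bars
  period_px <- (1000 / group$frequency) / p
  if (length(prof) < 2 * period_px) {
    stopf("annotation box spans %.1f cycles; need >= 2 full line cycles",
          length(prof) / period_px)
  }
  w <- (1000 / group$frequency) / 2  # bar width, um
  # absolute um positions of pixel centres along the modulation axis
  first <- if (identical(group$orientation, "horizontal")) group$row0 else group$col0
  x <- (first - 1 + seq_along(prof) - 0.5) * p
  win <- function(center) {
    sel <- x >= center - w / 2 & x <= center + w / 2
    if (!any(sel)) stopf("measurement window empty: box too small for one cycle")
    prof[sel]
  }
  bar_centers <- group$x0_um + c(1, 3, 5) * w
  gap_centers <- group$x0_um + c(2, 4) * w
  i_max <- mean(vapply(bar_centers, function(c0) max(win(c0)), numeric(1)))
  i_min <- mean(vapply(gap_centers, function(c0) min(win(c0)), numeric(1)))
  if (i_max < i_min) {
    # deep-blur limit: sampling can invert a vanishing modulation; report
    # zero contrast rather than an invalid measurement
    i_max <- i_min <- (i_max + i_min) / 2
  }
  structure(list(frequency = group$frequency, i_max = i_max, i_min = i_min),
            class = "bar_group_measurement")
}

#' Contrast-transfer-function modulus
#'
#' `CTF(f) = (i_max - i_min) / (i_max + i_min)` for the square-wave bar group
#' at spatial frequency `f`.
#'
#' @param m a `bar_group_measurement` (or any list with `i_max`, `i_min`).
#' @return contrast modulus in `[0, 1]`.
#' @export
ctf_modulus <- function(m) {
  if (m$i_max < m$i_min) stopf("i_max < i_min: invalid measurement")
  if (m$i_max + m$i_min <= 0) stopf("i_max = i_min = 0: contrast undefined")
  (m$i_max - m$i_min) / (m$i_max + m$i_min)
}

#' Measure a full CTF curve from an annotated target image
#'
#' @param img an [emission_rate_image()] of a bar target.
#' @param groups annotation data.frame from [make_bar_target()].
#' @param cutoff CTF level defining the resolution limit (default 0.1).
#' @param pixel_pitch um/pixel override.
#' @return An object of class `ctf_curve`: `points` (data.frame `frequency`,
#'   `ctf`, sorted by frequency), `axis`, `cutoff`, and `resolution_limit`
#'   (cycles/mm; NA when the curve never crosses the cutoff).
#' @export
measure_ctf_curve <- function(img, groups, cutoff = 0.1, pixel_pitch = NULL) {
  pts <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    m <- measure_bar_contrast(img, groups[i, ], pixel_pitch)
    data.frame(frequency = m$frequency, ctf = ctf_modulus(m))
  }))
  pts <- pts[order(pts$frequency), ]
  lim <- tryCatch(resolution_limit(pts, cutoff), error = function(e) NA_real_)
  structure(list(points = pts,
                 axis = unique(groups$orientation)[1],
                 cutoff = cutoff, resolution_limit = lim),
            class = "ctf_curve")
}

#' @export
print.ctf_curve <- function(x, ...) {
  cat(sprintf("ctf_curve (%s bars): %d groups, limit %.4g cycles/mm at CTF = %.2g\n",
              x$axis, nrow(x$points), x$resolution_limit, x$cutoff))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Resolution-limit frequency from a CTF curve
#'
#' Linear interpolation of the first downward crossing of `ctf = cutoff`
#' along increasing frequency.
#'
#' @param points data.frame with columns `frequency`, `ctf`.
#' @param cutoff contrast level in (0, 1).
#' @return frequency in cycles/mm.
#' @export
resolution_limit <- function(points, cutoff = 0.1) {
  pts <- points[order(points$frequency), ]
  if (nrow(pts) < 2) stopf("need >= 2 points straddling the cutoff")
  for (i in seq_len(nrow(pts) - 1)) {
    if (pts$ctf[i] >= cutoff && pts$ctf[i + 1] < cutoff) {
      return(pts$frequency[i] + (pts$ctf[i] - cutoff) /
               (pts$ctf[i] - pts$ctf[i + 1]) *
               (pts$frequency[i + 1] - pts$frequency[i]))
    }
  }
  stopf("CTF never crosses %.3g over %.4g-%.4g cycles/mm (range %.3g-%.3g)",
        cutoff, min(pts$frequency), max(pts$frequency),
        min(pts$ctf), max(pts$ctf))
}

#' Convert a spatial frequency to spatial resolution
#'
#' One full line cycle: `1000 / f` um, the convention under which the
#' instrument's 62.8 and 63.0 cycles/mm limits correspond to approximately
#' 16 um in both axes.
#'
#' @param f spatial frequency in cycles/mm (> 0).
#' @return resolution in um.
#' @export
frequency_to_resolution <- function(f) {
  if (any(f <= 0)) stopf("frequency must be > 0")
  1000 / f
}

#' @rdname frequency_to_resolution
#' @param res_um resolution in um.
#' @export
resolution_to_frequency <- function(res_um) {
  if (any(res_um <= 0)) stopf("resolution must be > 0")
  1000 / res_um
}
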
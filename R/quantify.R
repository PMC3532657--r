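#' Region-of-interest mask
#'
#' @param mask logical matrix (>= 1 positive pixel).
#' @param label one of `"tumor"`, `"muscle"`, `"bed"`, `"custom"`.
#' @param origin how the mask was obtained: `"manual"`, `"otsu"`, `"file"`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, label = c("custom", "tumor", "muscle", "bed"),
                        origin = c("manual", "otsu", "file")) {
  label <- match.arg(label)
  origin <- match.arg(origin)
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stopf("region mask has no positive pixels")
  structure(list(mask = mask, label = label, origin = origin),
            class = "region_mask")
}

roi_mask <- function(roi, img = NULL) {
  m <- if (inherits(roi, "region_mask")) roi$mask else if (is.matrix(roi)) roi != 0
       else stopf("roi must be a region_mask or a binary matrix")
  if (!any(m)) stopf("empty ROI")
  if (!is.null(img) && !identical(dim(m), dim(rate_matrix(img)))) {
    stopf("ROI shape %s does not match image shape %s",
          paste(dim(m), collapse = "x"),
          paste(dim(rate_matrix(img)), collapse = "x"))
  }
  m
}

#' Mean emission rate over a region
#'
#' @param img an [emission_rate_image()].
#' @param roi a [region_mask()] or binary matrix of the same shape.
#' @return mean rate in counts/s.
#' @export
mean_region_rate <- function(img, roi) {
  mean(rate_matrix(img)[roi_mask(roi, img)])
}

#' Tumor-to-muscle signal ratio
#'
#' Ratio of the mean normalized intensity over the tumor region to that over
#' the muscle region — the contrast figure of merit per probe (about 12 for
#' Prosense 680, 22.7 for VM249 in the instrument's characterization).
#'
#' @param tumor_img,muscle_img [emission_rate_image()]s.
#' @param tumor_roi,muscle_roi [region_mask()]s or binary matrices.
#' @return dimensionless ratio.
#' @export
tumor_to_muscle_ratio <- function(tumor_img, tumor_roi, muscle_img, muscle_roi) {
  mt <- mean_region_rate(tumor_img, tumor_roi)
  mm <- mean_region_rate(muscle_img, muscle_roi)
  if (mm <= 0) stopf("muscle signal is zero: ratio undefined")
  mt / mm
}

#' Segment the tumor from a dark background
#'
#' Global two-class (Otsu) threshold on the emission rates; the largest
#' 8-connected foreground component is retained.
#'
#' @param img an [emission_rate_image()].
#' @return A [region_mask()] with label `"tumor"`, origin `"otsu"`.
#' @export
segment_tumor <- function(img) {
  rates <- rate_matrix(img)
  thr <- otsu_threshold(rates)  # errors on constant images
  lab <- label_components(rates > thr, 8L)
  sizes <- attr(lab, "sizes")
  if (length(sizes) == 0) stopf("no foreground found above the Otsu threshold")
  region_mask(lab == which.max(sizes), label = "tumor", origin = "otsu")
}

#' Calibrate the per-subject residual-fluorescence threshold
#'
#' The classification threshold is a fraction (default 0.8) of the minimum
#' fluorescence emission rate of the excised tumor: every subsequent bed
#' image from the same subject is called positive or negative against it. The
#' minimum statistic defaults to the literal minimum over the tumor ROI after
#' 3x3 median filtering (which rejects isolated dead/hot pixels); a
#' percentile alternative is exposed.
#'
#' @param tumor_img an [emission_rate_image()] of the excised tumor.
#' @param tumor_roi [region_mask()] or binary matrix.
#' @param fraction threshold fraction in (0, 1]; default 0.8.
#' @param min_statistic `"literal-min"` or `"percentile"`.
#' @param percentile percentile (in percent) used when
#'   `min_statistic = "percentile"`.
#' @param median_filter apply the 3x3 median prefilter (default TRUE).
#' @param subject_id identifier recorded in the model.
#' @return An object of class `threshold_model`: `threshold_rate`
#'   (`fraction * tumor_min_rate`), `fraction`, `tumor_min_rate`,
#'   `min_statistic`, `subject_id`.
#' @export
calibrate_threshold <- function(tumor_img, tumor_roi, fraction = 0.8,
                                min_statistic = c("literal-min", "percentile"),
                                percentile = 1, median_filter = TRUE,
                                subject_id = NA_character_) {
  min_statistic <- match.arg(min_statistic)
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  m <- roi_mask(tumor_roi, tumor_img)
  rates <- rate_matrix(tumor_img)
  if (median_filter) rates <- median_filter3(rates)
  vals <- rates[m]
  tumor_min <- if (min_statistic == "literal-min") min(vals)
               else stats::quantile(vals, percentile / 100, names = FALSE)
  structure(list(threshold_rate = fraction * tumor_min,
                 fraction = fraction,
                 tumor_min_rate = tumor_min,
                 min_statistic = if (min_statistic == "percentile")
                   sprintf("percentile(%g)", percentile) else min_statistic,
                 median_filter = median_filter,
                 frame_shape = dim(rate_matrix(tumor_img)),
                 subject_id = subject_id),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model [%s]: %.4g counts/s = %.2f x tumor min %.4g (%s)\n",
              x$subject_id, x$threshold_rate, x$fraction, x$tumor_min_rate,
              x$min_statistic))
  invisible(x)
}

#' Classify a tumor bed for residual fluorescence
#'
#' Pixels at or above the subject's threshold rate form the supra-threshold
#' mask; the bed is called positive when some 8-connected component reaches
#' `min_cluster_px` pixels. Because both the threshold and the bed image are
#' emission rates, the call is invariant to the exposure time of the raw bed
#' frame.
#'
#' @param bed_img an [emission_rate_image()] of the tumor bed.
#' @param model a `threshold_model` from [calibrate_threshold()].
#' @param min_cluster_px minimum connected supra-threshold extent for a
#'   positive call (default 4 px, about 13 um across at 6.5 um pitch).
#' @return An object of class `bed_classification`: `status`
#'   (`"positive"`/`"negative"`), `supra_threshold_mask`, `supra_area_um2`
#'   (NA when the pixel pitch is unknown), `max_bed_rate`, `threshold_rate`,
#'   `min_cluster_px`, `components` (sizes of qualifying components).
#' @export
classify_bed <- function(bed_img, model, min_cluster_px = 4L) {
  stopifnot(inherits(model, "threshold_model"))
  rates <- rate_matrix(bed_img)
  if (!is.null(model$frame_shape) && !identical(dim(rates), model$frame_shape)) {
    stopf("bed frame %s does not match the calibration geometry %s",
          paste(dim(rates), collapse = "x"),
          paste(model$frame_shape, collapse = "x"))
  }
  supra <- rates >= model$threshold_rate
  lab <- label_components(supra, 8L)
  sizes <- attr(lab, "sizes")
  qualifying <- sizes[sizes >= min_cluster_px]
  p <- img_pitch(bed_img)
  structure(list(
    status = if (length(qualifying) > 0) "positive" else "negative",
    supra_threshold_mask = supra,
    supra_area_um2 = if (is.na(p)) NA_real_ else sum(supra) * p^2,
    max_bed_rate = max(rates),
    threshold_rate = model$threshold_rate,
    min_cluster_px = as.integer(min_cluster_px),
    components = sizes), class = "bed_classification")
}

#' @export
print.bed_classification <- function(x, ...) {
  cat(sprintf("bed_classification: %s (max rate %.4g vs threshold %.4g; %d supra px)\n",
              x$status, x$max_bed_rate, x$threshold_rate,
              sum(x$supra_threshold_mask)))
  invisible(x)
}

#' Publication display transfer
#'
#' Maps emission rates linearly so the tumor image's own minimum and maximum
#' go to 0 and 255, clips outside that range, and applies the identical map
#' to every other image from the same subject. Rounding is round-half-to-even
#' (base R `round`). Not idempotent: the output is on a display scale, not an
#' emission-rate scale.
#'
#' @param tumor_img an [emission_rate_image()] defining the histogram window.
#' @param images named list of [emission_rate_image()]s (or rate matrices) to
#'   transfer; defaults to just the tumor image.
#' @param tumor_roi optional ROI restricting the histogram window.
#' @return named list of 8-bit integer matrices.
#' @export
display_transfer <- function(tumor_img, images = list(tumor = tumor_img),
                             tumor_roi = NULL) {
  rates <- rate_matrix(tumor_img)
  vals <- if (is.null(tumor_roi)) rates else rates[roi_mask(tumor_roi, tumor_img)]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) stopf("tumor histogram is degenerate (min = max): no display window")
  lapply(images, function(im) {
    r <- rate_matrix(im)
    out <- round(pmin(pmax((r - lo) / (hi - lo), 0), 1) * 255)
    storage.mode(out) <- "integer"
    out
  })
}
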
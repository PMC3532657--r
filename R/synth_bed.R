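#' Phantom scene ground truth
#'
#' Records what a synthetic tumor-bed scene actually contains: the background
#' (muscle) emission rate, the stamped objects, and a binary truth mask
#' marking tumor-cell-containing pixels — the phantom stand-in for reporter
#' histology of the bed.
#'
#' @param background_rate muscle-level emission rate, counts/s/pixel.
#' @param objects data.frame of stamped objects (centroids in um, diameters in
#'   um, rates in counts/s).
#' @param truth_mask logical matrix aligned to the frame.
#' @param tumor_mask logical matrix marking the excised-tumor footprint in
#'   the tumor frame.
#' @param spec the [acquisition_spec()] used.
#' @param hidden_layers list of data.frames of clusters lying below the bed
#'   surface, revealed (optionally) by resection steps.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(background_rate, objects, truth_mask, tumor_mask,
                          spec, hidden_layers = list()) {
  if (!is.null(objects) && nrow(objects) > 0) {
    if (any(objects$diameter_um <= 0)) stopf("object diameters must be > 0")
  }
  structure(list(background_rate = background_rate, objects = objects,
                 truth_mask = truth_mask, tumor_mask = tumor_mask,
                 spec = spec, hidden_layers = hidden_layers),
            class = "phantom_scene")
}

# per-pixel multiplicative lognormal heterogeneity with unit mean and the
# requested coefficient of variation
lognormal_field <- function(nr, nc, cv) {
  if (cv <= 0) return(matrix(1, nr, nc))
  sdlog <- sqrt(log(1 + cv^2))
  matrix(stats::rlnorm(nr * nc, meanlog = -sdlog^2 / 2, sdlog = sdlog), nr, nc)
}

normalize_clusters <- function(residual_clusters) {
  if (is.null(residual_clusters) || (is.data.frame(residual_clusters) &&
                                     nrow(residual_clusters) == 0) ||
      (is.list(residual_clusters) && length(residual_clusters) == 0)) {
    return(data.frame(diameter_um = numeric(0), rate = numeric(0),
                      center_row_um = numeric(0), center_col_um = numeric(0)))
  }
  if (!is.data.frame(residual_clusters)) {
    residual_clusters <- do.call(rbind, lapply(residual_clusters, function(cl) {
      as.data.frame(as.list(cl))
    }))
  }
  if (is.null(residual_clusters$center_row_um)) residual_clusters$center_row_um <- NA_real_
  if (is.null(residual_clusters$center_col_um)) residual_clusters$center_col_um <- NA_real_
  residual_clusters
}

#' Synthesize a matched tumor / muscle / tumor-bed image triple
#'
#' Emulates the intraoperative workflow: the excised tumor is imaged first,
#' then normal muscle, then the tumor bed, which contains zero or more
#' microscopic residual clusters at tumor-level emission on a muscle-level
#' background. Ground truth (cluster pixels) is returned as a
#' [phantom_scene()].
#'
#' @param spec an [acquisition_spec()].
#' @param tumor_rate mean tumor emission rate, counts/s (must exceed
#'   `muscle_rate`).
#' @param muscle_rate mean muscle emission rate, counts/s (> 0).
#' @param residual_clusters data.frame (or list of named vectors) with columns
#'   `diameter_um`, `rate` and optional `center_row_um`, `center_col_um`;
#'   missing centres are drawn uniformly over the central 60% of the frame.
#' @param heterogeneity_cv coefficient of variation of the multiplicative
#'   lognormal tissue texture (0 disables it).
#' @param dark_rate stage background around the excised tumor, counts/s.
#' @param hidden_layers list of cluster data.frames buried below the surface
#'   (used by the guided-resection simulator).
#' @param noise `"on"` or `"off"`.
#' @param seed integer seed.
#' @return list with [raw_image()]s `tumor`, `muscle`, `bed`, the noiseless
#'   rate matrices `tumor_rates`, `muscle_rates`, `bed_rates`, and `scene`, a
#'   [phantom_scene()].
#' @export
make_tumor_bed_pair <- function(spec, tumor_rate = 2400, muscle_rate = 200,
                                residual_clusters = NULL,
                                heterogeneity_cv = 0.2, dark_rate = 10,
                                hidden_layers = list(),
                                noise = c("on", "off"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "acquisition_spec"))
  if (!(tumor_rate > muscle_rate && muscle_rate > 0)) {
    stopf("need tumor_rate > muscle_rate > 0")
  }
  clusters <- normalize_clusters(residual_clusters)
  p <- spec$pixel_pitch
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  h_um <- nr * p; w_um <- nc * p
  with_rng(seed, {
    # excised tumor: ellipse filling ~3/4 of the frame on a dark stage
    yc <- (seq_len(nr) - 0.5) * p; xc <- (seq_len(nc) - 0.5) * p
    tumor_mask <- outer(((yc - h_um / 2) / (0.38 * h_um))^2,
                        ((xc - w_um / 2) / (0.38 * w_um))^2, "+") <= 1
    tumor_rates <- matrix(dark_rate, nr, nc)
    tumor_rates[tumor_mask] <-
      tumor_rate * lognormal_field(nr, nc, heterogeneity_cv)[tumor_mask]
    muscle_rates <- muscle_rate * lognormal_field(nr, nc, heterogeneity_cv)

    bed_rates <- muscle_rate * lognormal_field(nr, nc, heterogeneity_cv)
    truth_mask <- matrix(FALSE, nr, nc)
    if (nrow(clusters) > 0) {
      for (k in seq_len(nrow(clusters))) {
        if (is.na(clusters$center_row_um[k])) {
          clusters$center_row_um[k] <- stats::runif(1, 0.2 * h_um, 0.8 * h_um)
          clusters$center_col_um[k] <- stats::runif(1, 0.2 * w_um, 0.8 * w_um)
        }
        ctr <- c(clusters$center_row_um[k], clusters$center_col_um[k])
        r_um <- clusters$diameter_um[k] / 2
        if (ctr[1] - r_um < 0 || ctr[1] + r_um > h_um ||
            ctr[2] - r_um < 0 || ctr[2] + r_um > w_um) {
          stopf("residual cluster %d (%.0f um at %.0f, %.0f um) extends outside the %.0f x %.0f um frame",
                k, clusters$diameter_um[k], ctr[1], ctr[2], h_um, w_um)
        }
        bed_rates <- stamp_disc(bed_rates, ctr, clusters$diameter_um[k],
                                clusters$rate[k], p)
        truth_mask <- truth_mask | disc_mask(c(nr, nc), ctr,
                                             clusters$diameter_um[k], p)
      }
    }
    scene <- phantom_scene(muscle_rate, clusters, truth_mask, tumor_mask,
                           spec, hidden_layers)
    list(tumor = expose_frame(tumor_rates, spec, noise = noise),
         muscle = expose_frame(muscle_rates, spec, noise = noise),
         bed = expose_frame(bed_rates, spec, noise = noise),
         tumor_rates = tumor_rates, muscle_rates = muscle_rates,
         bed_rates = bed_rates, scene = scene)
  })
}
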
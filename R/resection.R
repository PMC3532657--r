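#' Simulate the resect-until-clear loop on a phantom bed
#'
#' Repeats the intraoperative routine: classify the bed against the
#' subject's threshold; while positive, remove the supra-threshold
#' components dilated by a margin (tissue there reverts to the muscle-level
#' background and its truth pixels are cleared), optionally revealing a
#' pre-placed deeper cluster layer (a per-step Bernoulli — a simulation
#' construct emulating serially positive beds, not a biological claim), and
#' re-image. The loop stops at the first negative classification or after
#' `max_steps` removals, in which case the persisting positivity is flagged
#' rather than raised as an error.
#'
#' @param scene a [phantom_scene()] (carries truth, background rate, hidden
#'   layers).
#' @param bed_img an [emission_rate_image()] of the initial bed.
#' @param model a `threshold_model` from [calibrate_threshold()].
#' @param margin_px dilation radius removed beyond each supra-threshold
#'   component (default 2 px).
#' @param reveal_prob per-step probability that the next hidden layer is
#'   exposed by the cut (default 0).
#' @param max_steps maximum number of removals (>= 1).
#' @param min_cluster_px forwarded to [classify_bed()].
#' @param seed integer seed for the reveal draws.
#' @return An object of class `resection_trace`: `steps` (list of
#'   `resection_step`s with `index`, `removed_mask`, `post_resection_bed`,
#'   `classification`), `final_classification`, `cleared` (logical),
#'   `n_removals`, `final_truth_mask`.
#' @export
run_guided_resection <- function(scene, bed_img, model, margin_px = 2L,
                                 reveal_prob = 0, max_steps = 4L,
                                 min_cluster_px = 4L, seed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (max_steps < 1) stopf("max_steps must be >= 1")
  with_rng(seed, {
    bed <- rate_matrix(bed_img)
    prov <- if (inherits(bed_img, "emission_rate_image")) bed_img$provenance else list()
    truth <- scene$truth_mask
    layers <- scene$hidden_layers
    p <- scene$spec$pixel_pitch
    steps <- list()
    cls <- classify_bed(emission_rate_image(bed, prov), model, min_cluster_px)
    i <- 0L
    while (cls$status == "positive" && i < max_steps) {
      i <- i + 1L
      removed <- dilate_mask(cls$supra_threshold_mask, margin_px)
      bed[removed] <- scene$background_rate
      truth[removed] <- FALSE
      if (length(layers) > 0 && stats::runif(1) < reveal_prob) {
        layer <- layers[[1]]
        layers <- layers[-1]
        for (k in seq_len(nrow(layer))) {
          ctr <- c(layer$center_row_um[k], layer$center_col_um[k])
          bed <- stamp_disc(bed, ctr, layer$diameter_um[k], layer$rate[k], p)
          truth <- truth | disc_mask(dim(bed), ctr, layer$diameter_um[k], p)
        }
      }
      post <- emission_rate_image(bed, prov)
      cls <- classify_bed(post, model, min_cluster_px)
      steps[[i]] <- structure(list(index = i, removed_mask = removed,
                                   post_resection_bed = post,
                                   classification = cls),
                              class = "resection_step")
    }
    structure(list(steps = steps, final_classification = cls,
                   cleared = cls$status == "negative",
                   n_removals = i, final_truth_mask = truth),
              class = "resection_trace")
  })
}

#' @export
print.resection_trace <- function(x, ...) {
  cat(sprintf("resection_trace: %d removal(s), final %s%s\n", x$n_removals,
              x$final_classification$status,
              if (!x$cleared) " [still positive at max_steps]" else ""))
  invisible(x)
}

#' Score classifier calls against ground truth
#'
#' @param classifications character vector (`"positive"`/`"negative"`),
#'   logical vector, or list of `bed_classification`s.
#' @param truths logical vector: does the bed truly contain tumor pixels?
#' @return list with the confusion counts `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity` = TP/(TP+FN), `specificity` = TN/(TN+FP), and exact
#'   (Clopper-Pearson) binomial 95% CIs `sensitivity_ci`, `specificity_ci`.
#' @export
score_detection <- function(classifications, truths) {
  if (is.list(classifications)) {
    classifications <- vapply(classifications, function(x) x$status, character(1))
  }
  pred <- if (is.character(classifications)) classifications == "positive"
          else as.logical(classifications)
  truths <- as.logical(truths)
  if (length(pred) == 0) stopf("empty input")
  if (length(pred) != length(truths)) stopf("classifications and truths differ in length")
  tp <- sum(pred & truths); fn <- sum(!pred & truths)
  tn <- sum(!pred & !truths); fp <- sum(pred & !truths)
  ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    unname(stats::binom.test(x, n)$conf.int)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sensitivity_ci = ci(tp, tp + fn),
       specificity_ci = ci(tn, tn + fp))
}
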
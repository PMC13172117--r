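#' Multi-scale sliding-window GP4Crib+ probability map
#'
#' The whole-prostate inference engine: square in-plane windows of several
#' sizes slide voxel-by-voxel over every slice; each valid window's
#' 90th-percentile ADC feeds the logistic model, and per-voxel probabilities
#' are consolidated by maximum projection, so the most suspicious signal at
#' each voxel is retained.
#'
#' A window is valid when it lies fully inside the slice and at least
#' `min_mask_fraction` of its voxels are in the prostate mask; its feature
#' uses the in-mask voxels only. Aggregation `"cover"` assigns each in-mask
#' voxel the maximum probability over all valid windows (of any size)
#' containing it; `"center"` uses only the (at most one per size) valid
#' windows centred on the voxel. A voxel is defined iff at least one valid
#' window contributes. Covering windows are a superset of centred ones, so
#' cover-aggregated values dominate center-aggregated values voxel-wise.
#'
#' @param adc An [adc_volume()].
#' @param mask A [prostate_mask()] aligned to `adc`; normally already eroded
#'   (see [erode_mask()]), or set `erode = TRUE`.
#' @param model A [crib_model()].
#' @param window_sizes Odd in-plane window widths in voxels, all >= 3;
#'   default `c(5, 7, 9, 11, 13)`. See [windows_from_mm()] to derive sizes
#'   from a physical extent.
#' @param aggregation `"cover"` (default) or `"center"`.
#' @param min_mask_fraction Minimum in-mask fraction for a window to be
#'   valid; default 0.5.
#' @param erode Apply [erode_mask()] to the mask first? Default `FALSE`.
#' @return Object of class `prob_map`: `prob` (3-D array, `NA` where
#'   undefined), `valid` (logical array; always a subset of the mask),
#'   `spacing`, and provenance fields `window_sizes`, `aggregation`,
#'   `model`.
#' @export
sliding_window_map <- function(adc, mask, model,
                               window_sizes = c(5L, 7L, 9L, 11L, 13L),
                               aggregation = c("cover", "center"),
                               min_mask_fraction = 0.5, erode = FALSE) {
  stopifnot(inherits(adc, "adc_volume"), inherits(mask, "prostate_mask"),
            inherits(model, "crib_model"))
  aggregation <- match.arg(aggregation)
  check_aligned(adc, mask)
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (any(window_sizes < 3L) || any(window_sizes %% 2L == 0L)) {
    stop("sliding_window_map: window sizes must be odd and >= 3")
  }
  if (min_mask_fraction <= 0 || min_mask_fraction > 1) {
    stop("sliding_window_map: `min_mask_fraction` must lie in (0, 1]")
  }
  if (erode) mask <- erode_mask(mask)
  if (!any(mask$data)) stop("sliding_window_map: empty mask")

  std <- model$standardize %||% list(mean = 0, sd = 1)
  res <- cpp_sliding_window_map(
    as.numeric(adc$data), as.logical(mask$data), dim(adc$data),
    window_sizes, min_mask_fraction, model$intercept, model$slope,
    std$mean, std$sd, aggregation == "cover")
  prob <- array(res$prob, dim = dim(adc$data))
  valid <- array(res$valid, dim = dim(adc$data))
  if (!any(valid)) {
    warning("sliding_window_map: no valid windows; the mask is thinner than ",
            "the smallest window at this `min_mask_fraction`")
  }
  structure(list(prob = prob, valid = valid, spacing = adc$spacing,
                 window_sizes = window_sizes, aggregation = aggregation,
                 model = model),
            class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$prob)
  cat(sprintf("<prob_map> %d x %d x %d, %d defined voxels, windows {%s}, %s aggregation\n",
              d[1], d[2], d[3], sum(x$valid),
              paste(x$window_sizes, collapse = ", "), x$aggregation))
  if (any(x$valid)) {
    cat(sprintf("  defined probabilities in [%.3f, %.3f]\n",
                min(x$prob[x$valid]), max(x$prob[x$valid])))
  }
  invisible(x)
}

#' Window sizes from a physical extent
#'
#' Maps target window extents in mm to the nearest odd voxel counts for a
#' given in-plane resolution, so windows measure a fixed physical
#' neighbourhood across patients scanned at different resolutions.
#'
#' @param extent_mm Target window widths in mm.
#' @param spacing_mm In-plane voxel size in mm (scalar).
#' @return Odd integer window sizes (minimum 3), duplicates removed.
#' @export
windows_from_mm <- function(extent_mm, spacing_mm) {
  stopifnot(spacing_mm > 0, all(extent_mm > 0))
  w <- round(extent_mm / spacing_mm)
  w <- as.integer(ifelse(w %% 2 == 0, w + 1, w))
  sort(unique(pmax(w, 3L)))
}

#' Patient-level score: the map maximum
#'
#' The continuous patient score is the maximum probability over all defined
#' voxels of the patient's map — the model's highest confidence of
#' cribriform presence anywhere in the prostate.
#'
#' @param pmap A `prob_map`.
#' @return A single probability.
#' @export
patient_score <- function(pmap) {
  stopifnot(inherits(pmap, "prob_map"))
  if (!any(pmap$valid)) stop("patient_score: map has no defined voxels")
  max(pmap$prob[pmap$valid])
}

#' Binary patient classification at a probability threshold
#'
#' Positive iff the score strictly exceeds the threshold.
#'
#' @param score Patient score(s) in `[0, 1]`.
#' @param threshold Probability threshold in `[0, 1]`.
#' @return Logical: `TRUE` = predicted cribriform-positive.
#' @export
classify_patient <- function(score, threshold) {
  if (threshold < 0 || threshold > 1) {
    stop("classify_patient: `threshold` must lie in [0, 1]")
  }
  score > threshold
}

#' Score a cohort of phantoms
#'
#' Full patient-level pipeline over a list of phantoms: slice-restricted
#' mask erosion, multi-scale sliding-window map, maximum patient score.
#'
#' @param phantoms List of `phantom` objects (or a `synthetic_cohort`).
#' @param model A [crib_model()]; default [default_crib_model()].
#' @param erode Erode each mask first (default `TRUE`, matching the
#'   deployed pipeline).
#' @param ... Passed on to [sliding_window_map()].
#' @return Data frame with `patient_id` and `score`.
#' @export
score_cohort <- function(phantoms, model = default_crib_model(),
                         erode = TRUE, ...) {
  if (inherits(phantoms, "synthetic_cohort")) phantoms <- phantoms$phantoms
  rows <- lapply(phantoms, function(p) {
    pmap <- sliding_window_map(p$adc, p$mask, model, erode = erode, ...)
    data.frame(patient_id = p$record$patient_id, score = patient_score(pmap),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
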
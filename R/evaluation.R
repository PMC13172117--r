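#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as one half, over all
#' positive-negative pairs. Implemented via midranks, so it is exact under
#' ties and invariant to strictly monotone score transforms.
#'
#' @param scores Numeric patient-level scores.
#' @param labels Logical (or 0/1) patient-level ground truth; `TRUE` =
#'   positive.
#' @return AUROC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  if (all(labels) || !any(labels)) {
    stop("roc_auc: both classes must be present")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: thresholds sweep the distinct score values
#' in descending order (ties grouped), and the area accumulates as
#' `sum over i of (R_i - R_{i-1}) * P_i` with recall `R` and precision `P`
#' at each threshold. No interpolation between points.
#'
#' @inheritParams roc_auc
#' @return AUPRC in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels)
  if (!any(labels)) stop("pr_auc: at least one positive required")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # group tied scores: evaluate at the last index of each tie block
  last_of_block <- c(s[-length(s)] != s[-1], TRUE)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(!y)[last_of_block]
  n_pos <- sum(labels)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

check_scores_labels <- function(scores, labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("labels must be logical or 0/1")
    labels <- labels == 1
  }
  stopifnot(is.logical(labels), length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels
}

#' Percentile-bootstrap confidence interval for a patient-level metric
#'
#' Resamples patients with replacement `n_boot` times and recomputes the
#' metric on each resample. Resamples on which the metric is undefined
#' (single class for AUROC, no positives for AUPRC) are skipped and counted;
#' more than 50% degenerate resamples aborts with an error, as the sample is
#' too small or imbalanced to bootstrap. Returns the 2.5th and 97.5th
#' percentiles of the retained replicates.
#'
#' @inheritParams roc_auc
#' @param metric `"auroc"`, `"auprc"`, or a function `(scores, labels) ->`
#'   number.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the interval is reproducible from it.
#' @return Named numeric `c(low, high)` with attribute `n_degenerate`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auroc", n_boot = 1000,
                         seed = NULL) {
  labels <- check_scores_labels(scores, labels)
  fn <- if (is.function(metric)) metric else
    switch(metric, auroc = roc_auc, auprc = pr_auc,
           stop("bootstrap_ci: unknown metric ", metric))
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  vals <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vals[i] <- tryCatch(fn(scores[idx], labels[idx]),
                        error = function(e) NA_real_)
  }
  n_deg <- sum(is.na(vals))
  if (n_deg > n_boot / 2) {
    stop("bootstrap_ci: ", n_deg, "/", n_boot, " degenerate resamples; ",
         "sample too small or imbalanced for a bootstrap interval")
  }
  ci <- stats::quantile(vals[!is.na(vals)], c(0.025, 0.975), names = FALSE)
  structure(c(low = ci[1], high = ci[2]), n_degenerate = n_deg)
}

#' Patient-level diagnostic evaluation
#'
#' AUROC and AUPRC with 95% percentile-bootstrap confidence intervals
#' (patient-level resampling, 1000 resamples by default) and the positive
#' prevalence.
#'
#' @inheritParams bootstrap_ci
#' @return List of class `eval_result` with fields `auroc`, `auprc`,
#'   `prevalence`, `auroc_ci`, `auprc_ci`, `n`, `n_boot`, `seed`.
#' @export
evaluate_scores <- function(scores, labels, n_boot = 1000, seed = NULL) {
  labels <- check_scores_labels(scores, labels)
  prev <- mean(labels)
  if (prev <= 0 || prev >= 1) stop("evaluate_scores: both classes required")
  structure(list(auroc = roc_auc(scores, labels),
                 auprc = pr_auc(scores, labels),
                 prevalence = prev,
                 auroc_ci = bootstrap_ci(scores, labels, "auroc", n_boot, seed),
                 auprc_ci = bootstrap_ci(scores, labels, "auprc", n_boot, seed),
                 n = length(scores), n_boot = n_boot, seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n = %d, prevalence = %.2f\n", x$n, x$prevalence))
  cat(sprintf("  AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2]))
  cat(sprintf("  AUPRC %.3f (95%% CI %.3f-%.3f)\n",
              x$auprc, x$auprc_ci[1], x$auprc_ci[2]))
  invisible(x)
}
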
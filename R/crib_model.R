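#' Single-feature logistic model for cribriform growth
#'
#' The deployed classifier is a logistic regression on one radiomic feature:
#' the 90th percentile of ADC within a region or window (`adc_p90`,
#' 10^-6 mm^2/s). Low ADC reflects the dense cellular architecture of
#' cribriform Gleason-pattern-4 tissue, so a fitted slope is negative: the
#' predicted probability of GP4Crib+ falls as the p90 ADC rises.
#'
#' @param intercept Intercept (beta0) on the logit scale.
#' @param slope Slope (beta1) per 10^-6 mm^2/s of (optionally standardized)
#'   p90 ADC.
#' @param standardize `NULL`, or `list(mean =, sd =)` applied to the feature
#'   before the linear term.
#' @return An object of class `crib_model`.
#' @export
crib_model <- function(intercept, slope, standardize = NULL) {
  if (!is.finite(intercept) || !is.finite(slope)) {
    stop("crib_model: coefficients must be finite")
  }
  if (!is.null(standardize)) {
    if (!is.list(standardize) || !all(c("mean", "sd") %in% names(standardize))) {
      stop("crib_model: `standardize` must be NULL or list(mean=, sd=)")
    }
    if (!is.finite(standardize$sd) || standardize$sd <= 0) {
      stop("crib_model: standardization sd must be positive")
    }
  }
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope),
                 feature = "adc_p90", standardize = standardize),
            class = "crib_model")
}

#' Demonstration coefficients
#'
#' Illustrative, unstandardized coefficients (beta0 = 9, beta1 = -0.01 per
#' 10^-6 mm^2/s) that put the 0.5 probability point at an ADC p90 of 900.
#' They encode only the negative ADC-cribriform association and are intended
#' for demos and synthetic-cohort experiments; fit or load real coefficients
#' for any other use.
#'
#' @return A [crib_model()].
#' @export
default_crib_model <- function() crib_model(intercept = 9, slope = -0.01)

#' @export
print.crib_model <- function(x, ...) {
  cat(sprintf("<crib_model> logit(p) = %.6g %+.6g * %s%s\n",
              x$intercept, x$slope, x$feature,
              if (is.null(x$standardize)) "" else
                sprintf(" (standardized: mean %.6g, sd %.6g)",
                        x$standardize$mean, x$standardize$sd)))
  invisible(x)
}

#' 90th-percentile ADC feature
#'
#' The model's only input. Uses the linear-interpolation percentile
#' convention: with n sorted values, the percentile sits at fractional rank
#' 0.9 * (n - 1) and is interpolated between the two bracketing order
#' statistics (type-7 quantile).
#'
#' @param values Numeric ADC samples; non-finite entries are dropped.
#' @return The 90th percentile as a single number.
#' @export
extract_p90 <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("extract_p90: need at least one finite value")
  stats::quantile(values, probs = 0.9, type = 7, names = FALSE)
}

#' Predict GP4Crib+ probability from a p90-ADC feature
#'
#' @param model A [crib_model()].
#' @param p90 Numeric vector of p90 ADC features (10^-6 mm^2/s).
#' @return Probabilities in (0, 1), vectorized over `p90`.
#' @export
predict_prob <- function(model, p90) {
  stopifnot(inherits(model, "crib_model"))
  if (any(!is.finite(p90))) stop("predict_prob: `p90` must be finite")
  x <- p90
  if (!is.null(model$standardize)) {
    x <- (x - model$standardize$mean) / model$standardize$sd
  }
  stats::plogis(model$intercept + model$slope * x)
}

#' Fit the single-feature cribriform logistic model
#'
#' Maximizes the (optionally L2-penalized) binomial log-likelihood of the
#' GP4Crib+ label given `intercept + slope * x` by Newton-Raphson, where `x`
#' is the p90-ADC feature (standardized internally when `standardize = TRUE`).
#' The penalty `l2/2 * slope^2` applies to the slope only, never the
#' intercept. Iterations stop when the max-norm of the penalized score drops
#' to 1e-8 (on the internally rescaled problem).
#'
#' With a single feature, complete (or quasi-complete) separation is exactly
#' the condition that the two label groups' feature ranges do not overlap;
#' in that case the unpenalized MLE diverges and the fit errors with advice
#' to set `l2 > 0`.
#'
#' @param samples Data frame with columns `p90_adc` (numeric) and `label`
#'   (logical, or character where `"GP4Crib+"` is the positive class).
#' @param l2 L2 penalty strength on the slope, >= 0.
#' @param standardize Store and apply feature standardization (mean/sd of the
#'   training feature)? Default `FALSE`.
#' @return A [crib_model()] with attributes `n_iter` and `se`
#'   (unpenalized asymptotic standard errors of intercept and slope).
#' @export
fit_crib_model <- function(samples, l2 = 0, standardize = FALSE) {
  stopifnot(is.data.frame(samples), all(c("p90_adc", "label") %in% names(samples)))
  if (!is.finite(l2) || l2 < 0) stop("fit_crib_model: `l2` must be >= 0")
  x_raw <- as.numeric(samples$p90_adc)
  y <- samples$label
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "GP4Crib+"
  y <- as.numeric(y)
  if (any(!is.finite(x_raw)) || any(x_raw < 0)) {
    stop("fit_crib_model: `p90_adc` must be finite and >= 0")
  }
  if (length(unique(y)) < 2L) stop("fit_crib_model: both labels must be present")

  if (l2 == 0) {
    x1 <- x_raw[y == 1]; x0 <- x_raw[y == 0]
    if (max(x1) <= min(x0) || max(x0) <= min(x1)) {
      stop("fit_crib_model: complete separation of the feature; ",
           "refit with a nonzero L2 penalty (`l2 > 0`)")
    }
  }

  # optimize on a centered/scaled feature for conditioning, map back after
  mu <- mean(x_raw); sdx <- stats::sd(x_raw)
  if (!is.finite(sdx) || sdx == 0) stop("fit_crib_model: feature is constant")
  xs <- (x_raw - mu) / sdx
  l2s <- l2 * sdx^2  # penalty on the scaled slope equivalent to l2 on raw slope
  if (standardize) l2s <- l2    # penalty applies to the reported slope's scale

  beta <- c(stats::qlogis(max(min(mean(y), 1 - 1e-3), 1e-3)), 0)
  X <- cbind(1, xs)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(200L)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - p)) - c(0, l2s * beta[2])
    if (max(abs(grad)) <= 1e-8) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X) + diag(c(0, l2s))
    step <- solve(H, grad)
    # damped step to keep the likelihood climb monotone on hard problems
    beta_new <- beta + step
    halvings <- 0L
    pen_ll <- function(b) {
      e <- drop(X %*% b)
      # numerically stable log(1 + exp(e)) = max(e, 0) + log1p(exp(-|e|))
      sum(y * e - (pmax(e, 0) + log1p(exp(-abs(e))))) - l2s / 2 * b[2]^2
    }
    while (pen_ll(beta_new) < pen_ll(beta) && halvings < 30L) {
      step <- step / 2
      beta_new <- beta + step
      halvings <- halvings + 1L
    }
    beta <- beta_new
    if (max(abs(beta)) > 1e6) break
  }
  if (!converged) {
    stop("fit_crib_model: Newton iterations did not reach gradient norm 1e-8",
         if (l2 == 0) "; the data may be nearly separated (try `l2 > 0`)" else "")
  }

  p <- stats::plogis(drop(X %*% beta))
  w <- pmax(p * (1 - p), 1e-12)
  H <- crossprod(X * w, X)
  se_s <- sqrt(diag(solve(H)))

  if (standardize) {
    model <- crib_model(beta[1], beta[2], standardize = list(mean = mu, sd = sdx))
    se <- se_s
  } else {
    # back-transform: eta = b0 + b1*(x - mu)/sd = (b0 - b1*mu/sd) + (b1/sd)*x
    model <- crib_model(beta[1] - beta[2] * mu / sdx, beta[2] / sdx)
    J <- rbind(c(1, -mu / sdx), c(0, 1 / sdx))
    se <- sqrt(diag(J %*% solve(H) %*% t(J)))
  }
  attr(model, "n_iter") <- iter
  attr(model, "se") <- stats::setNames(se, c("intercept", "slope"))
  model
}

#' Serialize a cribriform model to and from JSON
#'
#' Schema: `{intercept, slope, feature: "adc_p90", standardize: {mean, sd} | null}`.
#' Coefficients are written at full precision so a round trip reproduces
#' predictions bit-identically.
#'
#' @param model A [crib_model()].
#' @param path File path for the JSON document.
#' @return `write_crib_model()` invisibly returns `path`;
#'   `read_crib_model()` returns the [crib_model()].
#' @export
write_crib_model <- function(model, path) {
  stopifnot(inherits(model, "crib_model"))
  jsonlite::write_json(
    list(intercept = model$intercept, slope = model$slope,
         feature = model$feature, standardize = model$standardize),
    path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_crib_model
#' @export
read_crib_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$feature, "adc_p90")) {
    stop("read_crib_model: expected feature \"adc_p90\", got ", obj$feature)
  }
  std <- obj$standardize
  if (!is.null(std)) std <- list(mean = std$mean, sd = std$sd)
  crib_model(obj$intercept, obj$slope, standardize = std)
}
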
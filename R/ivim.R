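#' Multi-b-value DWI series
#'
#' Container for a diffusion-weighted acquisition: one 3-D signal volume per
#' b-value. b-values are in s/mm^2, strictly increasing and starting at 0.
#'
#' @param volumes List of numeric 3-D arrays of identical shape.
#' @param b_values Numeric vector, one per volume.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, b_values, spacing) {
  b_values <- as.numeric(b_values)
  if (length(volumes) != length(b_values)) {
    stop("dwi_series: need one volume per b-value")
  }
  if (length(b_values) < 3L) stop("dwi_series: need at least 3 b-values")
  if (b_values[1] != 0) stop("dwi_series: b-values must start at 0")
  if (any(diff(b_values) <= 0)) stop("dwi_series: b-values must be strictly increasing")
  d <- dim(volumes[[1]])
  if (length(d) != 3L) stop("dwi_series: volumes must be 3-D arrays")
  for (v in volumes) {
    if (!identical(dim(v), d)) stop("dwi_series: volumes differ in shape")
    if (any(v < 0, na.rm = TRUE)) stop("dwi_series: signals must be >= 0")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("dwi_series: `spacing` must be 3 positive sizes in mm")
  }
  structure(list(volumes = volumes, b_values = b_values, spacing = spacing),
            class = "dwi_series")
}

#' Simulate bi-exponential IVIM signals
#'
#' Forward model for testing the fitter: the intravoxel-incoherent-motion
#' signal `S(b) = S0 * (f * exp(-b * D*) + (1 - f) * exp(-b * D))`, where `D`
#' is the tissue diffusion coefficient, `D*` the pseudo-diffusion coefficient
#' of the perfusion compartment and `f` the perfusion (fractional blood
#' volume) fraction. Noiseless; add noise with [rician_noise()] if needed.
#'
#' @param adc An [adc_volume()] carrying `D` in 10^-6 mm^2/s.
#' @param fbv Perfusion fraction `f` in `[0, 1]`: a scalar or an array of the
#'   grid shape.
#' @param pseudo_diffusion `D*` in 10^-6 mm^2/s (scalar); must exceed every
#'   `D`.
#' @param b_values b-values in s/mm^2, starting at 0.
#' @param s0 Baseline signal `S(0)`; scalar or array.
#' @return A [dwi_series()].
#' @export
simulate_ivim_signal <- function(adc, fbv, pseudo_diffusion, b_values, s0 = 1000) {
  stopifnot(inherits(adc, "adc_volume"))
  b_values <- as.numeric(b_values)
  if (length(b_values) < 1L || b_values[1] != 0) {
    stop("simulate_ivim_signal: b-values must start at 0")
  }
  d <- dim(adc$data)
  f <- if (length(fbv) == 1L) array(fbv, dim = d) else as.array(fbv)
  if (!identical(dim(f), d)) stop("simulate_ivim_signal: `fbv` shape mismatch")
  if (any(f < 0 | f > 1)) stop("simulate_ivim_signal: `fbv` must lie in [0, 1]")
  if (pseudo_diffusion <= max(adc$data)) {
    stop("simulate_ivim_signal: D* must exceed every tissue D")
  }
  S0 <- if (length(s0) == 1L) array(s0, dim = d) else as.array(s0)
  D <- adc$data * 1e-6       # to mm^2/s
  Dstar <- pseudo_diffusion * 1e-6
  vols <- lapply(b_values, function(b) {
    S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
  })
  dwi_series(vols, b_values, adc$spacing)
}

#' Add Rician noise to magnitude MRI signals
#'
#' Magnitude of a complex Gaussian perturbation:
#' `sqrt((x + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`.
#'
#' @param x Numeric array or vector of noiseless magnitudes.
#' @param sigma Noise standard deviation per channel.
#' @return Noisy values, same shape as `x`.
#' @export
rician_noise <- function(x, sigma) {
  if (sigma < 0) stop("rician_noise: `sigma` must be >= 0")
  if (sigma == 0) return(x)
  n <- length(x)
  out <- sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Segmented IVIM fit: ADC and fractional blood volume maps
#'
#' Two-step (segmented) estimation per masked voxel: (1) the tissue diffusion
#' coefficient `D` comes from an ordinary least-squares line fit of
#' log-signal against b over the high-b regime (`b_threshold <= b <= b_max`),
#' where the perfusion compartment has decayed away; (2) extrapolating that
#' line to b = 0 gives an intercept `S0'` attributable to tissue alone, and
#' the perfusion fraction is `f = 1 - S0' / S(0)`, clipped to `[0, 1]`.
#' `D*` itself is not estimated.
#'
#' Voxels with `S(0) <= 0` or any non-positive high-b signal are flagged
#' invalid rather than silently zeroed; their map entries are `NA`. Fitted
#' `D` is floored at 0.
#'
#' @param dwi A [dwi_series()].
#' @param mask A [prostate_mask()] on the DWI grid.
#' @param b_threshold Smallest b-value (s/mm^2) treated as perfusion-free;
#'   default 200, the smallest high b of typical prostate protocols.
#' @param b_max Largest b-value included in the fit (default 1000), so that
#'   optional very-high-b acquisitions (1400-2000) do not bias the
#'   mono-exponential regime.
#' @return List of class `ivim_maps`: `adc` (an [adc_volume()], 10^-6 mm^2/s,
#'   `NA` outside mask/invalid), `fbv` (array, `[0,1]`, `NA` likewise), and
#'   `valid` (logical array of successfully fitted voxels).
#' @export
fit_segmented_ivim <- function(dwi, mask, b_threshold = 200, b_max = 1000) {
  stopifnot(inherits(dwi, "dwi_series"), inherits(mask, "prostate_mask"))
  d <- dim(dwi$volumes[[1]])
  if (!identical(d, dim(mask$data))) {
    stop("fit_segmented_ivim: mask grid does not match the DWI grid")
  }
  hi <- which(dwi$b_values >= b_threshold & dwi$b_values <= b_max)
  if (length(hi) < 2L) {
    stop("fit_segmented_ivim: need at least 2 b-values in [b_threshold, b_max]")
  }
  b <- dwi$b_values[hi]
  nvox <- prod(d)
  S <- vapply(dwi$volumes[hi], as.vector, numeric(nvox))  # nvox x nb
  S0 <- as.vector(dwi$volumes[[1]])
  inmask <- as.vector(mask$data)

  floor_val <- .Machine$double.eps
  valid <- inmask & S0 > 0 & apply(S > floor_val, 1, all) &
    is.finite(S0) & apply(is.finite(S), 1, all)

  adc <- array(NA_real_, dim = d)
  fbv <- array(NA_real_, dim = d)
  if (any(valid)) {
    logS <- log(S[valid, , drop = FALSE])
    bc <- b - mean(b)
    slope <- drop(logS %*% bc) / sum(bc^2)
    intercept <- rowMeans(logS) - slope * mean(b)
    D <- pmax(-slope, 0)          # mm^2/s
    f <- 1 - exp(intercept) / S0[valid]
    adc[valid] <- D * 1e6
    fbv[valid] <- pmin(pmax(f, 0), 1)
  }
  structure(list(adc = adc_volume(adc, dwi$spacing), fbv = fbv,
                 valid = array(valid, dim = d)),
            class = "ivim_maps")
}
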
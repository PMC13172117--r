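#' ADC volume
#'
#' A 3-D grid of apparent diffusion coefficient values, the single imaging
#' carrier of the cribriform model's feature. Values are in 10^-6 mm^2/s
#' (so typical prostate tissue is ~700-1600).
#'
#' @param data Numeric 3-D array (nx, ny, nz); the third axis is the slice
#'   (z) axis.
#' @param spacing Numeric length-3 vector of voxel spacing in mm
#'   (in-plane x, in-plane y, slice thickness).
#' @return An object of class `adc_volume`: a list with elements `data` and
#'   `spacing`.
#' @export
adc_volume <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("adc_volume: `data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("adc_volume: `spacing` must be 3 positive voxel sizes in mm")
  }
  structure(list(data = data, spacing = spacing), class = "adc_volume")
}

#' Binary prostate mask
#'
#' Defines the inference domain of the probability map. Must share grid shape
#' and spacing with the ADC volume it accompanies.
#'
#' @param data Logical or 0/1 numeric 3-D array.
#' @param spacing Voxel spacing in mm, as in [adc_volume()].
#' @return An object of class `prostate_mask` with logical `data` and
#'   `spacing`.
#' @export
prostate_mask <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("prostate_mask: `data` must be a 3-D array")
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1))) stop("prostate_mask: values must be 0/1")
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.logical(data)) stop("prostate_mask: `data` must be logical or 0/1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("prostate_mask: `spacing` must be 3 positive voxel sizes in mm")
  }
  structure(list(data = data, spacing = spacing), class = "prostate_mask")
}

#' @export
print.adc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<adc_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  fin <- x$data[is.finite(x$data)]
  if (length(fin)) {
    cat(sprintf("  ADC range [%.0f, %.0f] x 10^-6 mm^2/s\n", min(fin), max(fin)))
  }
  invisible(x)
}

#' @export
print.prostate_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prostate_mask> %d x %d x %d voxels, %d in mask, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sum(x$data), x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

check_aligned <- function(adc, mask) {
  if (!identical(dim(adc$data), dim(mask$data))) {
    stop("ADC volume and mask have different grid shapes")
  }
  if (max(abs(adc$spacing - mask$spacing)) > 1e-6) {
    stop("ADC volume and mask have different voxel spacings")
  }
  invisible(TRUE)
}

#' Read and write volumes as NIfTI
#'
#' Thin wrappers over the RNifti reader/writer that carry voxel spacing in the
#' header. Masks are binarised on read.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_adc_volume()` returns an [adc_volume()];
#'   `read_prostate_mask()` a [prostate_mask()]. `write_volume()` invisibly
#'   returns `path`.
#' @export
read_adc_volume <- function(path) {
  img <- RNifti::readNifti(path)
  adc_volume(as.array(img), RNifti::pixdim(img)[1:3])
}

#' @rdname read_adc_volume
#' @export
read_prostate_mask <- function(path) {
  img <- RNifti::readNifti(path)
  prostate_mask(as.array(img) > 0.5, RNifti::pixdim(img)[1:3])
}

#' @rdname read_adc_volume
#' @param x An `adc_volume`, `prostate_mask`, or plain 3-D array.
#' @param spacing Voxel spacing in mm; ignored when `x` carries its own.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, c("adc_volume", "prostate_mask"))) {
    spacing <- x$spacing
    x <- x$data
  }
  if (is.null(spacing)) stop("write_volume: `spacing` required for plain arrays")
  if (is.logical(x)) x <- array(as.integer(x), dim = dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
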
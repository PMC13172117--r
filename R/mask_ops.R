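#' Slice-restricted boundary erosion of a prostate mask
#'
#' Removes a single boundary voxel in-plane to absorb segmentation
#' uncertainty at the gland edge. The structuring element is a cylinder of
#' one-voxel radius and one-slice height: each eligible slice is replaced by
#' its 2-D morphological erosion, all other slices pass through unchanged.
#' A slice is eligible only when both the slice above and the slice below
#' contain at least one mask voxel, so apex/base edge slices (where
#' segmentations are least reliable) are never eroded away.
#'
#' @param mask A [prostate_mask()].
#' @param element In-plane structuring element: `"cross"` (4-connected
#'   radius-1 disk, the default reading of a one-voxel cylinder) or
#'   `"square"` (8-connected 3x3).
#' @param restricted What to do with ineligible slices: `"keep"` them
#'   unchanged (default) or `"drop"` them from the mask entirely.
#' @return An eroded [prostate_mask()]; always a subset of the input.
#' @export
erode_mask <- function(mask, element = c("cross", "square"),
                       restricted = c("keep", "drop")) {
  stopifnot(inherits(mask, "prostate_mask"))
  element <- match.arg(element)
  restricted <- match.arg(restricted)
  m <- mask$data
  nz <- dim(m)[3]
  out <- m
  slice_has <- apply(m, 3, any)
  for (z in seq_len(nz)) {
    eligible <- z > 1L && z < nz && slice_has[z - 1L] && slice_has[z + 1L]
    if (eligible) {
      out[, , z] <- erode_slice(m[, , z], element)
    } else if (restricted == "drop") {
      out[, , z] <- FALSE
    }
  }
  prostate_mask(out, mask$spacing)
}

# 2-D binary erosion by intersection of shifted copies; outside the slice
# counts as background, so slice-edge voxels erode.
erode_slice <- function(s, element) {
  nx <- nrow(s); ny <- ncol(s)
  shift2 <- function(dx, dy) {
    out <- matrix(FALSE, nx, ny)
    xs <- seq_len(nx) + dx
    ys <- seq_len(ny) + dy
    okx <- xs >= 1L & xs <= nx
    oky <- ys >= 1L & ys <= ny
    out[okx, oky] <- s[xs[okx], ys[oky]]
    out
  }
  offsets <- if (element == "cross") {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  out <- s
  for (o in offsets) out <- out & shift2(o[1], o[2])
  out
}

#' Nearest-neighbour resampling of a mask onto a target grid
#'
#' Coregisters a mask to the ADC grid under the axis-aligned, shared-origin
#' convention: voxel centre `i` (1-based) sits at physical coordinate
#' `(i - 1) * spacing` along each axis. Each target voxel takes the value of
#' the nearest source voxel centre; target voxels outside the source extent
#' are background.
#'
#' @param mask A [prostate_mask()].
#' @param target_shape Integer length-3 voxel counts of the target grid.
#' @param target_spacing Numeric length-3 voxel spacing (mm) of the target.
#' @return A [prostate_mask()] on the target grid. Errors if the resampled
#'   mask is empty, which signals grid misalignment.
#' @export
resample_mask_to_grid <- function(mask, target_shape, target_spacing) {
  stopifnot(inherits(mask, "prostate_mask"))
  target_shape <- as.integer(target_shape)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_shape) != 3L || any(target_shape < 1L)) {
    stop("resample_mask_to_grid: `target_shape` must be 3 positive counts")
  }
  if (length(target_spacing) != 3L || any(target_spacing <= 0)) {
    stop("resample_mask_to_grid: `target_spacing` must be 3 positive sizes")
  }
  if (identical(dim(mask$data), target_shape) &&
      max(abs(mask$spacing - target_spacing)) < 1e-9) {
    return(mask)
  }
  src_dim <- dim(mask$data)
  idx <- vector("list", 3L)
  for (ax in 1:3) {
    phys <- (seq_len(target_shape[ax]) - 1) * target_spacing[ax]
    i <- as.integer(round(phys / mask$spacing[ax])) + 1L
    i[i < 1L | i > src_dim[ax]] <- NA_integer_
    idx[[ax]] <- i
  }
  out <- array(FALSE, dim = target_shape)
  okx <- !is.na(idx[[1]]); oky <- !is.na(idx[[2]]); okz <- !is.na(idx[[3]])
  if (any(okx) && any(oky) && any(okz)) {
    out[okx, oky, okz] <- mask$data[idx[[1]][okx], idx[[2]][oky], idx[[3]][okz]]
  }
  if (!any(out)) {
    stop("resample_mask_to_grid: resampled mask is empty; ",
         "source and target grids do not overlap where the mask lies")
  }
  prostate_mask(out, target_spacing)
}
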
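# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# linear-interpolation 90th percentile by explicit sort
oracle_p90 <- function(values) {
  v <- sort(values)
  n <- length(v)
  if (n == 1L) return(v)
  pos <- 0.9 * (n - 1)
  lo <- floor(pos)
  frac <- pos - lo
  if (lo + 1 >= n) return(v[n])
  v[lo + 1] + frac * (v[lo + 2] - v[lo + 1])
}

oracle_logistic <- function(intercept, slope, x) 1 / (1 + exp(-(intercept + slope * x)))

# exhaustive window enumeration for the sliding-window probability map
oracle_window_map <- function(adc_arr, mask_arr, intercept, slope,
                              sizes, aggregation, min_frac) {
  d <- dim(adc_arr)
  prob <- array(NA_real_, dim = d)
  for (z in seq_len(d[3])) {
    for (w in sizes) {
      if (w > d[1] || w > d[2]) next
      half <- (w - 1) / 2
      for (x0 in seq_len(d[1] - w + 1)) {
        for (y0 in seq_len(d[2] - w + 1)) {
          sel_m <- mask_arr[x0:(x0 + w - 1), y0:(y0 + w - 1), z]
          cnt <- sum(sel_m)
          if (cnt < 1 || cnt < min_frac * w * w - 1e-9) next
          vals <- adc_arr[x0:(x0 + w - 1), y0:(y0 + w - 1), z][sel_m]
          p <- oracle_logistic(intercept, slope, oracle_p90(vals))
          if (aggregation == "cover") {
            for (x in x0:(x0 + w - 1)) {
              for (y in y0:(y0 + w - 1)) {
                if (!mask_arr[x, y, z]) next
                if (is.na(prob[x, y, z]) || p > prob[x, y, z]) prob[x, y, z] <- p
              }
            }
          } else {
            cx <- x0 + half; cy <- y0 + half
            if (mask_arr[cx, cy, z] &&
                (is.na(prob[cx, cy, z]) || p > prob[cx, cy, z])) {
              prob[cx, cy, z] <- p
            }
          }
        }
      }
    }
  }
  prob
}

# O(n^2) pair-counting AUROC
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# threshold-sweep average precision
oracle_pr_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  area <- 0
  r_prev <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# per-voxel neighbourhood test for slice erosion
oracle_erode_slice <- function(s, element) {
  nx <- nrow(s); ny <- ncol(s)
  offs <- if (element == "cross") {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  out <- matrix(FALSE, nx, ny)
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!s[x, y]) next
      keep <- TRUE
      for (o in offs) {
        xx <- x + o[1]; yy <- y + o[2]
        if (xx < 1 || xx > nx || yy < 1 || yy > ny || !s[xx, yy]) {
          keep <- FALSE
          break
        }
      }
      out[x, y] <- keep
    }
  }
  out
}

# random blob mask: union of a few random discs per slice
random_blob_mask <- function(d, n_seeds = 3, r_range = c(2, 5)) {
  m <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    for (k in seq_len(n_seeds)) {
      cx <- runif(1, 1, d[1]); cy <- runif(1, 1, d[2])
      r <- runif(1, r_range[1], r_range[2])
      xs <- matrix(seq_len(d[1]), d[1], d[2])
      ys <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
      m[, , z] <- m[, , z] | ((xs - cx)^2 + (ys - cy)^2 <= r^2)
    }
  }
  m
}

small_phantom_config <- function(...) {
  args <- list(grid_shape = c(40L, 40L, 12L),
               voxel_spacing = c(1.1, 1.1, 3),
               prostate_semiaxes_mm = c(16, 14, 12),
               lesion_diameter_range = c(6, 9))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_config, args)
}
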
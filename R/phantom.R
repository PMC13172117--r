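#' Phantom generator configuration
#'
#' Study conditions for the synthetic imaging cohort: an ellipsoidal prostate
#' on an anisotropic grid, ellipsoidal tumour foci of three histologic
#' classes, and class-specific ADC distributions in which cribriform tissue
#' (GP4Crib+) has systematically the lowest ADC — the negative
#' ADC-cribriform association the deployed model exploits.
#'
#' Defaults (all user-overridable): a 48 x 48 x 14 grid at 1.1 x 1.1 x 3 mm
#' (within typical prostate DWI resolution and slice thickness); background
#' ADC 1400 +/- 200, GP3 1000 +/- 150, GP4Crib- 900 +/- 150, GP4Crib+
#' 700 +/- 120 (10^-6 mm^2/s); 1-3 lesions per gland with maximum in-plane
#' diameters of 6-12 mm, the size range of MRI-conspicuous index lesions.
#' Class standard deviations already carry tissue heterogeneity, so the
#' additional measurement-noise model defaults to `"none"`.
#'
#' @param grid_shape Voxel counts (nx, ny, nz).
#' @param voxel_spacing mm per axis (in-plane x, in-plane y, slice).
#' @param background_adc `c(mean, sd)` of non-lesion prostate ADC.
#' @param lesion_adc Named list with elements `GP3`, `GP4CribNeg`,
#'   `GP4CribPos`, each `c(mean, sd)`.
#' @param lesion_count_range Integer `c(min, max)` lesions per phantom.
#' @param lesion_diameter_range `c(min, max)` maximum in-plane lesion
#'   diameter in mm.
#' @param prostate_semiaxes_mm Ellipsoid semi-axes of the gland in mm
#'   (x, y, z), jittered +/- 5% per phantom.
#' @param noise_model `"none"`, `"gaussian"`, or `"rician"` measurement
#'   noise added on top of the class draws.
#' @param noise_sigma Noise standard deviation (same units as ADC).
#' @param seed Optional default seed used by [generate_phantom()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 14L),
                           voxel_spacing = c(1.1, 1.1, 3),
                           background_adc = c(mean = 1400, sd = 200),
                           lesion_adc = list(GP3 = c(mean = 1000, sd = 150),
                                             GP4CribNeg = c(mean = 900, sd = 150),
                                             GP4CribPos = c(mean = 700, sd = 120)),
                           lesion_count_range = c(1L, 3L),
                           lesion_diameter_range = c(6, 12),
                           prostate_semiaxes_mm = c(20, 17, 15),
                           noise_model = c("none", "gaussian", "rician"),
                           noise_sigma = 0,
                           seed = NULL) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  sds <- c(background_adc[2], vapply(lesion_adc, `[`, numeric(1), 2))
  if (any(sds < 0)) stop("phantom_config: ADC sds must be >= 0")
  if (!all(c("GP3", "GP4CribNeg", "GP4CribPos") %in% names(lesion_adc))) {
    stop("phantom_config: `lesion_adc` needs GP3, GP4CribNeg, GP4CribPos")
  }
  if (lesion_adc$GP4CribPos[1] >= lesion_adc$GP3[1]) {
    stop("phantom_config: GP4Crib+ mean ADC must be below the GP3 mean ",
         "(the model's feature is negatively associated with cribriform growth)")
  }
  if (any(lesion_diameter_range <= 0) || diff(lesion_diameter_range) < 0) {
    stop("phantom_config: lesion diameters must be positive and ordered")
  }
  if (any(lesion_count_range < 0) || diff(lesion_count_range) < 0) {
    stop("phantom_config: `lesion_count_range` must be nonnegative and ordered")
  }
  if (noise_sigma < 0) stop("phantom_config: `noise_sigma` must be >= 0")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing = as.numeric(voxel_spacing),
                 background_adc = as.numeric(background_adc),
                 lesion_adc = lapply(lesion_adc, as.numeric),
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_diameter_range = as.numeric(lesion_diameter_range),
                 prostate_semiaxes_mm = as.numeric(prostate_semiaxes_mm),
                 noise_model = noise_model,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = seed),
            class = "phantom_config")
}

#' Remove lesion/background ADC contrast from a configuration
#'
#' Negative-control configuration: every lesion class draws from the
#' background ADC distribution, so patient scores carry no signal and
#' patient-level discrimination collapses to chance.
#'
#' @param config A [phantom_config()].
#' @return The configuration with all class distributions set to background.
#' @export
zero_contrast_config <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  bg <- config$background_adc
  config$lesion_adc <- list(GP3 = bg + c(0, 0),          # means equal; sign
                            GP4CribNeg = bg,             # constraint waived by
                            GP4CribPos = bg - c(1e-9, 0)) # an epsilon
  config
}

# class codes in the lesion label grid
LESION_CLASSES <- c(GP3 = 1L, GP4CribNeg = 2L, GP4CribPos = 3L)

#' Generate a synthetic prostate phantom
#'
#' Builds one patient: a discretized ellipsoidal prostate mask, ellipsoidal
#' lesions placed fully inside the mask without overlap by rejection
#' sampling, voxel ADC drawn from the class distribution of the voxel's
#' label, optional measurement noise, and a clinical record consistent with
#' the imaging ground truth (cribriform positivity at patient level iff at
#' least one GP4Crib+ lesion exists; recorded maximum cribriform diameter =
#' the largest in-plane extent over GP4Crib+ lesions).
#'
#' @param config A [phantom_config()].
#' @param record Partial patient record (list or one-row data frame): any of
#'   `patient_id`, `crib_positive`, `max_crib_diameter_mm`, `cpg` (1-3,
#'   where 3 means CPG-3 with biopsy GG2), `psa`, `biopsy_gg`,
#'   `clinical_t_stage`, `prostatectomy_gg`. Missing fields are sampled
#'   consistently; contradictory fields error.
#' @param seed Integer seed (defaults to `config$seed`); fixed seed gives
#'   bit-identical phantoms.
#' @return An object of class `phantom`: list with `adc` ([adc_volume()]),
#'   `mask` ([prostate_mask()]), `lesion_labels` (integer array, 0 =
#'   background, codes per `LESION_CLASSES`), `lesions` (per-lesion geometry
#'   data frame) and `record` (one-row data frame).
#' @export
generate_phantom <- function(config, record = list(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  record <- as.list(record)
  sp <- config$voxel_spacing
  gs <- config$grid_shape

  # --- prostate mask: discretized ellipsoid at the grid centre ---
  semi <- config$prostate_semiaxes_mm * stats::runif(3, 0.95, 1.05)
  if (2 * min(semi[1] / sp[1], semi[2] / sp[2]) < 15) {
    stop("generate_phantom: prostate must span >= 15 voxels in-plane")
  }
  ext <- (gs - 1) * sp
  centre <- ext / 2
  if (any(semi > ext / 2)) {
    stop("generate_phantom: grid too small to contain the prostate ellipsoid")
  }
  xs <- (seq_len(gs[1]) - 1) * sp[1]
  ys <- (seq_len(gs[2]) - 1) * sp[2]
  zs <- (seq_len(gs[3]) - 1) * sp[3]
  qx <- ((xs - centre[1]) / semi[1])^2
  qy <- ((ys - centre[2]) / semi[2])^2
  qz <- ((zs - centre[3]) / semi[3])^2
  mask <- outer(outer(qx, qy, `+`), qz, `+`) <= 1

  # --- lesion classes for this patient ---
  crib_target <- record$crib_positive
  n_lesions <- if (diff(config$lesion_count_range) == 0L) {
    config$lesion_count_range[1]
  } else {
    sample(seq(config$lesion_count_range[1], config$lesion_count_range[2]), 1L)
  }
  if (isTRUE(crib_target)) {
    if (config$lesion_count_range[2] < 1L) {
      stop("generate_phantom: crib_positive = TRUE but lesion count is fixed at 0")
    }
    n_lesions <- max(n_lesions, 1L)
    classes <- c(LESION_CLASSES[["GP4CribPos"]],
                 if (n_lesions > 1L)
                   sample(LESION_CLASSES[c("GP3", "GP4CribNeg")], n_lesions - 1L,
                          replace = TRUE))
  } else if (isFALSE(crib_target)) {
    classes <- if (n_lesions > 0L)
      sample(LESION_CLASSES[c("GP3", "GP4CribNeg")], n_lesions, replace = TRUE)
    else integer(0)
  } else {
    classes <- if (n_lesions > 0L)
      sample(LESION_CLASSES, n_lesions, replace = TRUE)
    else integer(0)
  }

  forced_diam <- record$max_crib_diameter_mm
  if (!is.null(forced_diam) && !is.na(forced_diam) && forced_diam > 0 &&
      isFALSE(crib_target)) {
    stop("generate_phantom: positive cribriform diameter contradicts ",
         "crib_positive = FALSE")
  }

  # --- rejection-sampled lesion placement (fully in mask, no overlap) ---
  labels <- array(0L, dim = gs)
  lesions <- list()
  mask_idx <- which(mask, arr.ind = TRUE)
  for (k in seq_along(classes)) {
    cls <- classes[k]
    diam <- if (cls == LESION_CLASSES[["GP4CribPos"]] && k == 1L &&
                !is.null(forced_diam) && !is.na(forced_diam)) {
      as.numeric(forced_diam)
    } else {
      stats::runif(1, config$lesion_diameter_range[1],
                   config$lesion_diameter_range[2])
    }
    a <- diam / 2
    b <- a * stats::runif(1, 0.8, 1)
    cz <- max(a * stats::runif(1, 0.5, 1), 0.6 * sp[3])
    theta <- stats::runif(1, 0, 2 * pi)
    placed <- FALSE
    for (attempt in seq_len(200L)) {
      ctr_vox <- mask_idx[sample.int(nrow(mask_idx), 1L), ]
      ctr <- (ctr_vox - 1) * sp
      inside <- lesion_membership(gs, sp, ctr, a, b, cz, theta)
      if (!any(inside)) next
      if (all(mask[inside]) && all(labels[inside] == 0L)) {
        labels[inside] <- cls
        lesions[[length(lesions) + 1L]] <- data.frame(
          class = names(LESION_CLASSES)[cls], diameter_mm = diam,
          a = a, b = b, c = cz, theta = theta,
          cx = ctr[1], cy = ctr[2], cz_mm = ctr[3],
          n_voxels = sum(inside))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("generate_phantom: could not place a ", diam,
           " mm lesion inside the prostate after 200 attempts; ",
           "enlarge the gland or shrink the lesions")
    }
  }
  lesions <- if (length(lesions)) do.call(rbind, lesions) else
    data.frame(class = character(0), diameter_mm = numeric(0), a = numeric(0),
               b = numeric(0), c = numeric(0), theta = numeric(0),
               cx = numeric(0), cy = numeric(0), cz_mm = numeric(0),
               n_voxels = integer(0))

  # --- ADC draws: background everywhere, then per-lesion class draws ---
  adc <- array(stats::rnorm(prod(gs), config$background_adc[1],
                            config$background_adc[2]), dim = gs)
  for (cls_name in names(LESION_CLASSES)) {
    sel <- labels == LESION_CLASSES[[cls_name]]
    nsel <- sum(sel)
    if (nsel > 0L) {
      par <- config$lesion_adc[[cls_name]]
      adc[sel] <- stats::rnorm(nsel, par[1], par[2])
    }
  }
  if (config$noise_model == "gaussian" && config$noise_sigma > 0) {
    adc <- adc + stats::rnorm(prod(gs), 0, config$noise_sigma)
  } else if (config$noise_model == "rician" && config$noise_sigma > 0) {
    adc <- rician_noise(adc, config$noise_sigma)
  }

  # --- clinical record, consistent with the imaging ground truth ---
  crib_positive <- any(labels == LESION_CLASSES[["GP4CribPos"]])
  crib_diams <- lesions$diameter_mm[lesions$class == "GP4CribPos"]
  max_crib <- if (crib_positive) max(crib_diams) else 0

  clin <- complete_clinical_record(record, crib_positive)
  rec <- data.frame(patient_id = clin$patient_id, psa = clin$psa,
                    clinical_t_stage = clin$clinical_t_stage,
                    biopsy_gg = clin$biopsy_gg,
                    prostatectomy_gg = clin$prostatectomy_gg,
                    crib_positive = crib_positive,
                    max_crib_diameter_mm = max_crib,
                    cpg = clin$cpg, stringsAsFactors = FALSE)

  structure(list(adc = adc_volume(adc, sp),
                 mask = prostate_mask(mask, sp),
                 lesion_labels = labels, lesions = lesions, record = rec),
            class = "phantom")
}

# voxel membership of a rotated ellipsoid (in-plane rotation theta)
lesion_membership <- function(gs, sp, ctr, a, b, cz, theta) {
  dx <- (seq_len(gs[1]) - 1) * sp[1] - ctr[1]
  dy <- (seq_len(gs[2]) - 1) * sp[2] - ctr[2]
  dz <- (seq_len(gs[3]) - 1) * sp[3] - ctr[3]
  ct <- cos(theta); st <- sin(theta)
  # quadratic form in rotated in-plane coordinates, separable pieces cached
  xr <- outer(dx * ct, dy * st, `+`)   # x' = dx cos + dy sin
  yr <- outer(-dx * st, dy * ct, `+`)  # y' = -dx sin + dy cos
  q2d <- (xr / a)^2 + (yr / b)^2
  inside <- array(FALSE, dim = gs)
  for (iz in seq_along(dz)) {
    inside[, , iz] <- q2d + (dz[iz] / cz)^2 <= 1
  }
  inside
}

complete_clinical_record <- function(record, crib_positive) {
  pid <- record$patient_id %||% "P001"
  if (!is.null(record$psa) || !is.null(record$biopsy_gg) ||
      !is.null(record$clinical_t_stage)) {
    psa <- record$psa %||% 7
    gg <- record$biopsy_gg %||% 2L
    tt <- record$clinical_t_stage %||% 2L
  } else {
    cl <- sample_clinical_for_cpg(record$cpg %||% 2L)
    psa <- cl$psa; gg <- cl$biopsy_gg; tt <- cl$clinical_t_stage
  }
  cpg <- assign_cpg(psa, gg, tt)
  if (!is.null(record$cpg) && cpg != as.integer(record$cpg)) {
    stop("generate_phantom: supplied clinical variables give CPG-", cpg,
         ", contradicting the requested CPG-", record$cpg)
  }
  pgg <- record$prostatectomy_gg %||% if (crib_positive) {
    sample(2:4, 1L, prob = c(0.55, 0.35, 0.10))
  } else {
    sample(1:3, 1L, prob = c(0.25, 0.60, 0.15))
  }
  if (crib_positive && pgg < 2L) {
    stop("generate_phantom: cribriform growth implies prostatectomy GG >= 2")
  }
  list(patient_id = pid, psa = psa, biopsy_gg = as.integer(gg),
       clinical_t_stage = as.integer(tt), prostatectomy_gg = as.integer(pgg),
       cpg = cpg)
}

# clinical variables that assign_cpg() maps back to the requested group;
# CPG-3 is always realized as the GG2 + PSA 10-20 cell (the only CPG-3
# flavour the decision scenarios admit)
sample_clinical_for_cpg <- function(cpg) {
  cpg <- as.integer(cpg)
  if (cpg == 1L) {
    list(psa = stats::runif(1, 3, 9.5), biopsy_gg = 1L,
         clinical_t_stage = sample(1:2, 1L, prob = c(0.38, 0.62)))
  } else if (cpg == 2L) {
    if (stats::runif(1) < 0.9) {
      list(psa = stats::runif(1, 3, 9.5), biopsy_gg = 2L,
           clinical_t_stage = sample(1:2, 1L, prob = c(0.3, 0.7)))
    } else {
      list(psa = stats::runif(1, 10.5, 18), biopsy_gg = 1L,
           clinical_t_stage = sample(1:2, 1L, prob = c(0.3, 0.7)))
    }
  } else if (cpg == 3L) {
    list(psa = stats::runif(1, 10.5, 19), biopsy_gg = 2L,
         clinical_t_stage = sample(1:2, 1L, prob = c(0.25, 0.75)))
  } else {
    stop("sample_clinical_for_cpg: only CPG 1-3 are simulated")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell counts for a cohort case mix
#'
#' Converts target proportions over CPG x cribriform cells into realized
#' counts, either by multinomial draw or exactly by the largest-remainder
#' quota method.
#'
#' @param n Number of patients.
#' @param class_mix Data frame with columns `cpg` (1, 2, or 3 = CPG-3(GG2)),
#'   `crib` (logical) and `prop` (summing to 1).
#' @param exact Use exact quotas instead of a multinomial draw?
#' @return `class_mix` with an added integer `count` column summing to `n`.
#' @export
cohort_cell_counts <- function(n, class_mix = default_class_mix(), exact = FALSE) {
  stopifnot(is.data.frame(class_mix),
            all(c("cpg", "crib", "prop") %in% names(class_mix)))
  if (abs(sum(class_mix$prop) - 1) > 1e-8) {
    stop("cohort_cell_counts: proportions must sum to 1")
  }
  if (exact) {
    raw <- n * class_mix$prop
    cnt <- floor(raw)
    short <- n - sum(cnt)
    if (short > 0) {
      order_rem <- order(raw - cnt, decreasing = TRUE)
      cnt[order_rem[seq_len(short)]] <- cnt[order_rem[seq_len(short)]] + 1
    }
  } else {
    cnt <- drop(stats::rmultinom(1, n, class_mix$prop))
  }
  class_mix$count <- as.integer(cnt)
  class_mix
}

#' Default cohort case mix
#'
#' CPG x cribriform cell proportions matching the package's 127-record
#' fixture cohort ([fixture_cohort()]): CPG-1 20%, CPG-2 57%, CPG-3(GG2) 23%,
#' with an overall cribriform prevalence of 41%.
#'
#' @return A data frame usable as `class_mix` in [generate_cohort()].
#' @export
default_class_mix <- function() {
  data.frame(cpg = c(1L, 1L, 2L, 2L, 3L, 3L),
             crib = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
             prop = c(23, 3, 39, 33, 13, 16) / 127)
}

#' Generate a synthetic cohort of phantoms
#'
#' @param n Number of patients.
#' @param config A [phantom_config()] shared by all phantoms.
#' @param class_mix Target CPG x cribriform proportions; see
#'   [cohort_cell_counts()].
#' @param exact_quota Reproduce cell counts exactly (largest-remainder
#'   quotas) instead of a multinomial draw?
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return List of class `synthetic_cohort`: `phantoms` (list of
#'   [generate_phantom()] results) and `records` (row-bound patient table).
#' @export
generate_cohort <- function(n, config = phantom_config(),
                            class_mix = default_class_mix(),
                            exact_quota = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- cohort_cell_counts(n, class_mix, exact = exact_quota)
  phantoms <- vector("list", n)
  i <- 0L
  for (r in seq_len(nrow(cells))) {
    for (k in seq_len(cells$count[r])) {
      i <- i + 1L
      phantoms[[i]] <- generate_phantom(
        config,
        record = list(patient_id = sprintf("P%03d", i),
                      cpg = cells$cpg[r], crib_positive = cells$crib[r]),
        seed = NULL)  # continue the cohort RNG stream
    }
  }
  structure(list(phantoms = phantoms, records = cohort_records(phantoms)),
            class = "synthetic_cohort")
}

#' @rdname generate_cohort
#' @param phantoms A list of `phantom` objects.
#' @export
cohort_records <- function(phantoms) {
  do.call(rbind, lapply(phantoms, function(p) p$record))
}

#' Simulate region-level training samples
#'
#' Emulates the region-level data the logistic model is fitted on: each
#' sample is the 90th-percentile ADC of a histology-proven region, drawn
#' from the class ADC distribution of a [phantom_config()]. Positives are
#' GP4Crib+ regions; negatives split evenly between GP3 and GP4Crib-.
#'
#' @param n_pos,n_neg Numbers of GP4Crib+ and other-class regions.
#' @param config A [phantom_config()] supplying the class distributions.
#' @param region_voxels Voxels per region the percentile is taken over.
#' @param seed Optional integer seed.
#' @return Data frame with columns `p90_adc` and `label`
#'   (`"GP4Crib+"` / `"other"`), ready for [fit_crib_model()].
#' @export
simulate_region_samples <- function(n_pos, n_neg, config = phantom_config(),
                                    region_voxels = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(par, n) {
    vapply(seq_len(n), function(i)
      extract_p90(stats::rnorm(region_voxels, par[1], par[2])), numeric(1))
  }
  n_gp3 <- n_neg %/% 2L
  p90 <- c(draw(config$lesion_adc$GP4CribPos, n_pos),
           draw(config$lesion_adc$GP3, n_gp3),
           draw(config$lesion_adc$GP4CribNeg, n_neg - n_gp3))
  data.frame(p90_adc = p90,
             label = rep(c("GP4Crib+", "other"), c(n_pos, n_neg)),
             stringsAsFactors = FALSE)
}
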
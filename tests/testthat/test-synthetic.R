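test_that("a lesion-free phantom is a pure background draw and is seed-deterministic", {
  cfg <- small_phantom_config(lesion_count_range = c(0L, 0L))
  ph <- generate_phantom(cfg, seed = 101)
  expect_false(ph$record$crib_positive)
  expect_identical(ph$record$max_crib_diameter_mm, 0)
  expect_true(all(ph$lesion_labels == 0L))
  expect_true(all(is.finite(ph$adc$data)))
  # background distribution: sample mean within 3 SE on >= 1000 mask voxels
  vox <- ph$adc$data[ph$mask$data]
  expect_gt(length(vox), 1000)
  expect_lt(abs(mean(vox) - 1400), 3 * 200 / sqrt(length(vox)))

  ph2 <- generate_phantom(cfg, seed = 101)
  expect_identical(serialize(ph, NULL), serialize(ph2, NULL))
  ph3 <- generate_phantom(cfg, seed = 102)
  expect_false(identical(ph$adc$data, ph3$adc$data))
})

test_that("a 6 mm cribriform lesion has the recorded diameter and a sane discretization", {
  cfg <- phantom_config(grid_shape = c(40L, 40L, 30L),
                        voxel_spacing = c(0.7, 0.7, 1),
                        prostate_semiaxes_mm = c(12, 11, 10),
                        lesion_count_range = c(1L, 1L),
                        lesion_diameter_range = c(6, 6))
  ph <- generate_phantom(cfg, record = list(crib_positive = TRUE), seed = 21)
  expect_true(ph$record$crib_positive)
  # recorded max diameter within one in-plane voxel of 6 mm
  expect_lt(abs(ph$record$max_crib_diameter_mm - 6), 0.7 + 1e-9)

  les <- ph$lesions
  expect_identical(les$class, "GP4CribPos")
  # independent lattice-point count inside the analytic ellipsoid
  n_lat <- 0L
  for (ix in seq_len(40)) for (iy in seq_len(40)) for (iz in seq_len(30)) {
    dx <- (ix - 1) * 0.7 - les$cx
    dy <- (iy - 1) * 0.7 - les$cy
    dz <- (iz - 1) * 1 - les$cz_mm
    xr <- dx * cos(les$theta) + dy * sin(les$theta)
    yr <- -dx * sin(les$theta) + dy * cos(les$theta)
    if ((xr / les$a)^2 + (yr / les$b)^2 + (dz / les$c)^2 <= 1) n_lat <- n_lat + 1L
  }
  expect_identical(sum(ph$lesion_labels == 3L), n_lat)
  # voxelized volume within 25% of the continuous ellipsoid volume
  vol_cont <- 4 / 3 * pi * les$a * les$b * les$c
  vol_vox <- n_lat * prod(cfg$voxel_spacing)
  expect_lt(abs(vol_vox - vol_cont) / vol_cont, 0.25)
  # lesion voxels stay inside the prostate mask
  expect_true(all(ph$mask$data[ph$lesion_labels > 0L]))
})

test_that("generated voxels recover the class ADC means within 3 SE", {
  cfg <- small_phantom_config(lesion_count_range = c(3L, 3L),
                              lesion_diameter_range = c(9, 12),
                              prostate_semiaxes_mm = c(19, 17, 14),
                              grid_shape = c(48L, 48L, 14L))
  pool <- list("1" = numeric(0), "2" = numeric(0), "3" = numeric(0))
  set.seed(42)
  for (i in 1:25) {
    ph <- generate_phantom(cfg, record = list(crib_positive = TRUE))
    for (cls in 1:3) {
      pool[[cls]] <- c(pool[[cls]], ph$adc$data[ph$lesion_labels == cls])
    }
    if (all(vapply(pool, length, 1L) >= 1000)) break
  }
  expected <- list("1" = c(1000, 150), "2" = c(900, 150), "3" = c(700, 120))
  for (cls in c("1", "2", "3")) {
    v <- pool[[cls]]
    expect_gte(length(v), 1000)
    e <- expected[[cls]]
    expect_lt(abs(mean(v) - e[1]), 3 * e[2] / sqrt(length(v)))
  }
})

test_that("exact quotas hit cell counts exactly; multinomial draws stay in 99% bounds", {
  mix <- data.frame(cpg = c(1L, 2L, 2L, 3L),
                    crib = c(FALSE, FALSE, TRUE, TRUE),
                    prop = c(0.24, 0.35, 0.25, 0.16))
  cc <- cohort_cell_counts(200, mix, exact = TRUE)
  expect_identical(sum(cc$count), 200L)
  expect_identical(cc$count[cc$crib][order(cc$cpg[cc$crib])], c(50L, 32L))
  # emulated cribriform prevalence of 0.41 at n = 200 -> exactly 82 crib+
  expect_identical(sum(cohort_cell_counts(200, default_class_mix(),
                                          exact = TRUE)$count[default_class_mix()$crib]),
                   82L)
  set.seed(5)
  cm <- cohort_cell_counts(10000, mix, exact = FALSE)
  expect_identical(sum(cm$count), 10000L)
  for (i in seq_len(nrow(mix))) {
    expect_gte(cm$count[i], qbinom(0.005, 10000, mix$prop[i]))
    expect_lte(cm$count[i], qbinom(0.995, 10000, mix$prop[i]))
  }
})

test_that("cohorts honour CPG/crib cells and are byte-reproducible under a seed", {
  mix <- data.frame(cpg = c(1L, 2L, 3L), crib = c(FALSE, TRUE, TRUE),
                    prop = c(0.5, 0.25, 0.25))
  coh <- generate_cohort(8, small_phantom_config(), mix,
                         exact_quota = TRUE, seed = 33)
  rec <- coh$records
  expect_identical(nrow(rec), 8L)
  expect_identical(sum(rec$cpg == 1L), 4L)
  expect_identical(rec$crib_positive, rec$cpg != 1L)
  # CPG-1 cells are forced to GG1, PSA < 10, stage <= 2
  cpg1 <- rec[rec$cpg == 1L, ]
  expect_true(all(cpg1$biopsy_gg == 1L & cpg1$psa < 10 &
                    cpg1$clinical_t_stage <= 2L))
  expect_identical(assign_cpg(rec$psa, rec$biopsy_gg, rec$clinical_t_stage),
                   rec$cpg)
  # cribriform positivity matches the voxel ground truth and implies size > 0
  expect_true(all(rec$max_crib_diameter_mm[rec$crib_positive] > 0))
  expect_true(all(rec$max_crib_diameter_mm[!rec$crib_positive] == 0))

  coh2 <- generate_cohort(8, small_phantom_config(), mix,
                          exact_quota = TRUE, seed = 33)
  expect_identical(serialize(coh, NULL), serialize(coh2, NULL))
  coh3 <- generate_cohort(8, small_phantom_config(), mix,
                          exact_quota = TRUE, seed = 34)
  expect_false(identical(coh$phantoms[[1]]$adc$data,
                         coh3$phantoms[[1]]$adc$data))
  expect_identical(table(coh3$records$cpg), table(rec$cpg))  # quotas unchanged
})

test_that("contradictory or infeasible phantom specs error explicitly", {
  cfg0 <- small_phantom_config(lesion_count_range = c(0L, 0L))
  expect_error(generate_phantom(cfg0, record = list(crib_positive = TRUE),
                                seed = 1),
               "crib_positive")
  expect_error(generate_phantom(small_phantom_config(),
                                record = list(crib_positive = FALSE,
                                              max_crib_diameter_mm = 4),
                                seed = 1),
               "contradicts")
  expect_error(generate_phantom(small_phantom_config(),
                                record = list(cpg = 1L, psa = 25,
                                              biopsy_gg = 1L,
                                              clinical_t_stage = 1L),
                                seed = 1),
               "contradicting")
  # lesions larger than the gland exhaust rejection sampling
  big <- small_phantom_config(lesion_diameter_range = c(28, 28),
                              lesion_count_range = c(1L, 1L))
  expect_error(generate_phantom(big, record = list(crib_positive = TRUE),
                                seed = 2),
               "could not place")
  # the configuration type itself rejects a reversed contrast
  expect_error(phantom_config(lesion_adc = list(GP3 = c(700, 100),
                                                GP4CribNeg = c(900, 100),
                                                GP4CribPos = c(1000, 100))),
               "negatively associated")
})

test_that("region samples separate classes in the expected direction", {
  rs <- simulate_region_samples(150, 150, seed = 9)
  expect_identical(nrow(rs), 300L)
  expect_lt(mean(rs$p90_adc[rs$label == "GP4Crib+"]),
            mean(rs$p90_adc[rs$label == "other"]))
})
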
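test_that("CPG assignment implements the five-tier criteria", {
  expect_identical(assign_cpg(6.7, 1, 2), 1L)
  expect_identical(assign_cpg(7, 2, 2), 2L)
  expect_identical(assign_cpg(12, 1, 1), 2L)   # PSA 10-20 alone
  expect_identical(assign_cpg(15, 2, 2), 3L)   # GG2 and PSA 10-20 together
  expect_identical(assign_cpg(8, 3, 2), 3L)
  expect_identical(assign_cpg(25, 1, 1), 4L)   # exactly one high-risk factor
  expect_identical(assign_cpg(8, 4, 2), 4L)
  expect_identical(assign_cpg(6, 1, 3), 4L)
  expect_identical(assign_cpg(25, 4, 1), 5L)   # two factors
  expect_identical(assign_cpg(5, 5, 1), 5L)    # GG5
  expect_identical(assign_cpg(5, 1, 4), 5L)    # T4
  expect_identical(assign_cpg(c(6.7, 15), c(1, 2), c(2, 2)), c(1L, 3L))
  expect_error(assign_cpg(-1, 1, 1), "PSA")
  expect_error(assign_cpg(5, 6, 1), "GG")
  expect_error(assign_cpg(5, 1, 5), "T-stage")
})

test_that("the fixture cohort reproduces every demographic marginal", {
  fx <- fixture_cohort()
  expect_identical(nrow(fx), 127L)
  # CPG sizes and cribriform counts per nested group
  expect_identical(sum(fx$cpg == 1L), 26L)
  expect_identical(sum(fx$cpg == 2L), 72L)
  expect_identical(sum(fx$cpg == 3L), 29L)
  expect_identical(sum(fx$crib_positive[fx$cpg == 1L]), 3L)
  expect_identical(sum(fx$crib_positive[fx$cpg <= 2L]), 36L)
  expect_identical(sum(fx$crib_positive), 52L)
  expect_identical(sum(fx$prostatectomy_gg >= 3L & fx$cpg == 1L), 0L)
  expect_identical(sum(fx$prostatectomy_gg >= 3L & fx$cpg <= 2L), 12L)
  expect_identical(sum(fx$prostatectomy_gg >= 3L), 22L)
  # prostatectomy GG distribution 23/82/17/3/2, biopsy GG 33/94, T-stage 37/90
  expect_identical(as.integer(table(factor(fx$prostatectomy_gg, 1:5))),
                   c(23L, 82L, 17L, 3L, 2L))
  expect_identical(as.integer(table(factor(fx$biopsy_gg, 1:2))), c(33L, 94L))
  expect_identical(as.integer(table(factor(fx$clinical_t_stage, 1:2))),
                   c(37L, 90L))
  # internal consistency
  expect_identical(assign_cpg(fx$psa, fx$biopsy_gg, fx$clinical_t_stage),
                   fx$cpg)
  expect_true(all(fx$max_crib_diameter_mm[fx$crib_positive] >= 1.5))
  expect_true(all(fx$prostatectomy_gg[fx$crib_positive] >= 2L))
  # CPG-1: 23/26 cribriform-free
  expect_identical(sum(!fx$crib_positive[fx$cpg == 1L]), 23L)
})

test_that("allocation follows the scenario rules and the strict threshold", {
  fx <- fixture_cohort()
  cpg12 <- filter_cpg_group(fx, "cpg12")
  expect_identical(nrow(cpg12), 98L)
  ref <- allocate(cpg12, scenario = "reference")
  expect_identical(sum(ref$arm == "AS"), 26L)
  expect_identical(sum(ref$arm == "AT"), 72L)
  expect_true(all(ref$source[ref$arm == "AT"] == "rule_reference"))

  scores <- data.frame(patient_id = fx$patient_id,
                       score = seq(0.01, 0.99, length.out = nrow(fx)))
  # threshold 1.0 with strict ">": no score exceeds it, everyone to AS
  a1 <- allocate(fx, scores, "cpg12", threshold = 1.0)
  expect_identical(sum(a1$arm == "AS"), 98L)
  # threshold -1: every model-routed patient exceeds it, only CPG-1 in AS
  a2 <- allocate(fx, scores, "cpg12", threshold = -1)
  expect_identical(sum(a2$arm == "AS"), 26L)
  expect_true(all(a2$source[a2$arm == "AT"] == "model"))
  # cpg123gg2 routes CPG-2 and CPG-3(GG2) through the model
  a3 <- allocate(fx, scores, "cpg123gg2", threshold = -1)
  expect_identical(nrow(a3), 127L)
  expect_identical(sum(a3$arm == "AS"), 26L)
  # missing scores for routed patients error
  expect_error(allocate(fx, scores[1:30, ], "cpg12", threshold = 0.5),
               "missing score")
  expect_error(allocate(fx, scores, "cpg12"), "threshold")
})

test_that("outcome categories follow the six-way rules", {
  rec <- data.frame(
    patient_id = c("a", "b", "c", "d", "e", "f"),
    psa = 7, clinical_t_stage = 2L, biopsy_gg = 2L,
    prostatectomy_gg = c(2L, 3L, 2L, 2L, 3L, 2L),
    crib_positive = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    max_crib_diameter_mm = c(0.9, 0, 0, 6, 2, 0),
    cpg = 2L)
  alloc <- data.frame(patient_id = rec$patient_id,
                      arm = c("AS", "AS", "AT", "AS", "AT", "AS"),
                      source = "model")
  cat <- categorize_outcomes(rec, alloc)$category
  expect_identical(as.character(cat),
                   c("false_AS_crib_small",  # crib+, GG2, 0.9 mm, in AS
                     "false_AS_gg3",         # crib-, GG3, in AS
                     "false_AT",             # crib-, GG2, in AT
                     "false_AS_crib_large",  # crib+, 6 mm, in AS
                     "correct_AT",           # crib+, in AT
                     "correct_AS"))          # crib-, GG2, in AS
  # the cutoff is configurable
  cat2 <- categorize_outcomes(rec, alloc, size_cutoff_mm = 7)$category
  expect_identical(as.character(cat2[4]), "false_AS_crib_small")
})

test_that("reference scenarios reproduce the fixture accounting", {
  fx <- fixture_cohort()
  r12 <- run_scenario(filter_cpg_group(fx, "cpg12"), scenario = "reference")
  expect_identical(r12$n, 98L)
  expect_identical(r12$correct_AS + r12$correct_AT, 60L)
  expect_identical(r12$false_AS_crib_small + r12$false_AS_crib_large +
                     r12$false_AS_gg3, 3L)
  expect_identical(r12$false_AT, 35L)
  expect_equal(r12$appropriate_pct + r12$undertreatment_pct +
                 r12$overtreatment_pct, 100)

  rfull <- run_scenario(fx, scenario = "reference")
  expect_identical(rfull$n, 127L)
  expect_identical(rfull$correct_AS + rfull$correct_AT, 78L)
  expect_identical(rfull$correct_AS, 23L)

  # reference results are invariant to scores (none are consulted)
  r12b <- run_scenario(filter_cpg_group(fx, "cpg12"),
                       scores = data.frame(patient_id = fx$patient_id,
                                           score = runif(127)),
                       scenario = "reference")
  expect_identical(r12, r12b)
})

test_that("category counts partition the cohort and sweeps are monotone", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(40:90, 1)
    cohort <- data.frame(
      patient_id = sprintf("r%02d_%03d", rep, seq_len(n)),
      psa = runif(n, 4, 19),
      clinical_t_stage = sample(1:2, n, replace = TRUE),
      biopsy_gg = sample(1:2, n, replace = TRUE),
      prostatectomy_gg = sample(1:4, n, replace = TRUE,
                                prob = c(0.2, 0.55, 0.2, 0.05)),
      crib_positive = runif(n) < 0.4,
      max_crib_diameter_mm = 0,
      cpg = 0L)
    cohort$psa[cohort$biopsy_gg == 1L] <-
      pmin(cohort$psa[cohort$biopsy_gg == 1L], 9.5)
    cohort$cpg <- assign_cpg(cohort$psa, cohort$biopsy_gg,
                             cohort$clinical_t_stage)
    cohort$prostatectomy_gg <- pmax(cohort$prostatectomy_gg,
                                    ifelse(cohort$crib_positive, 2L, 1L))
    cohort$max_crib_diameter_mm <- ifelse(cohort$crib_positive,
                                          runif(n, 0.5, 8), 0)
    scores <- data.frame(patient_id = cohort$patient_id, score = runif(n))
    th <- seq(0.1, 0.9, by = 0.1)
    for (scen in c("cpg12", "cpg123gg2")) {
      res <- run_scenario(cohort, scores, scen, thresholds = th)
      counts <- res$correct_AS + res$correct_AT + res$false_AS_crib_small +
        res$false_AS_crib_large + res$false_AS_gg3 + res$false_AT
      expect_true(all(counts == res$n))
      n_at <- res$correct_AT + res$false_AT
      expect_true(all(diff(n_at) <= 0))                     # AT non-increasing
      expect_true(all(diff(res$overtreatment_pct) <= 1e-9))
      expect_true(all(diff(res$undertreatment_pct) >= -1e-9))
    }
  }
})

test_that("an all-benign CPG-1 cohort is 100% correctly surveilled", {
  n <- 12L
  cohort <- data.frame(patient_id = sprintf("b%02d", 1:n), psa = 5,
                       clinical_t_stage = 1L, biopsy_gg = 1L,
                       prostatectomy_gg = 1L, crib_positive = FALSE,
                       max_crib_diameter_mm = 0, cpg = 1L)
  for (scen in c("reference", "cpg12", "cpg123gg2")) {
    res <- run_scenario(cohort,
                        scores = data.frame(patient_id = cohort$patient_id,
                                            score = 0.99),
                        scenario = scen, thresholds = 0.5)
    expect_identical(res$correct_AS, n)
    expect_equal(res$appropriate_pct, 100)
  }
})
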
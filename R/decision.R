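#' Cambridge Prognostic Group assignment
#'
#' Five-tier clinical risk stratification from PSA, biopsy grade group and
#' clinical T-stage (the standard CPG criteria):
#' \itemize{
#'   \item CPG-1: GG1, PSA < 10 ng/mL, stage T1-T2.
#'   \item CPG-2: exactly one of \{GG2, PSA 10-20\}, with GG <= 2 and stage
#'     <= T2.
#'   \item CPG-3: GG2 with PSA 10-20 and stage <= T2, or GG3 with PSA <= 20
#'     and stage <= T2.
#'   \item CPG-4: exactly one of \{GG4, PSA > 20, stage T3\}.
#'   \item CPG-5: two or more of those, or GG5, or stage T4.
#' }
#' Only groups 1-3 are exercised by the decision scenarios.
#'
#' @param psa PSA in ng/mL (> 0). Vectorized.
#' @param biopsy_gg Biopsy grade group, 1-5.
#' @param clinical_t_stage Clinical T-stage, 1-4.
#' @return Integer CPG in 1..5.
#' @export
assign_cpg <- function(psa, biopsy_gg, clinical_t_stage) {
  n <- max(length(psa), length(biopsy_gg), length(clinical_t_stage))
  psa <- rep_len(as.numeric(psa), n)
  gg <- rep_len(as.integer(biopsy_gg), n)
  tt <- rep_len(as.integer(clinical_t_stage), n)
  if (any(!is.finite(psa)) || any(psa <= 0)) stop("assign_cpg: PSA must be > 0")
  if (any(is.na(gg)) || any(gg < 1L | gg > 5L)) {
    stop("assign_cpg: biopsy GG must lie in 1..5")
  }
  if (any(is.na(tt)) || any(tt < 1L | tt > 4L)) {
    stop("assign_cpg: clinical T-stage must lie in 1..4")
  }
  high <- (gg == 4L) + (psa > 20) + (tt == 3L)
  out <- integer(n)
  cpg5 <- gg == 5L | tt == 4L | high >= 2L
  cpg4 <- !cpg5 & high == 1L
  psa_mid <- psa >= 10 & psa <= 20
  cpg3 <- !cpg5 & !cpg4 &
    ((gg == 2L & psa_mid & tt <= 2L) | (gg == 3L & psa <= 20 & tt <= 2L))
  cpg2 <- !cpg5 & !cpg4 & !cpg3 & gg <= 2L & tt <= 2L &
    xor(gg == 2L, psa_mid)
  cpg1 <- !cpg5 & !cpg4 & !cpg3 & !cpg2 & gg == 1L & psa < 10 & tt <= 2L
  out[cpg5] <- 5L; out[cpg4] <- 4L; out[cpg3] <- 3L
  out[cpg2] <- 2L; out[cpg1] <- 1L
  if (any(out == 0L)) stop("assign_cpg: unclassifiable input combination")
  out
}

#' The 127-record fixture cohort
#'
#' A fixed synthetic cohort of 127 intermediate-risk patient records used by
#' the decision-scenario examples and tests: CPG-1 n = 26, CPG-2 n = 72,
#' CPG-3(GG2) n = 29, with an overall cribriform prevalence of 41%
#' (52/127) and 22 patients with prostatectomy GG >= 3. The joint
#' cribriform x prostatectomy-GG cells per CPG are:
#'
#' \tabular{lcccc}{
#'   \tab crib+ GG>=3 \tab crib+ GG<3 \tab crib- GG>=3 \tab crib- GG<3 \cr
#'   CPG-1       \tab 0 \tab 3  \tab 0 \tab 23 \cr
#'   CPG-2       \tab 8 \tab 25 \tab 4 \tab 35 \cr
#'   CPG-3(GG2)  \tab 8 \tab 8  \tab 2 \tab 11 \cr
#' }
#'
#' Prostatectomy-GG values within cells are assigned so the marginal GG
#' distribution is 23/82/17/3/2 for GG 1-5 (cribriform positivity always
#' implies prostatectomy GG >= 2), biopsy GG is 33 GG1 / 94 GG2, and
#' clinical T-stage is 37 T1 / 90 T2. PSA values are representative
#' constants consistent with each CPG.
#'
#' @param crib_diameter_mm Maximum cribriform focus diameter recorded for
#'   crib-positive patients (>= 1.5 so none fall under the small-focus
#'   cutoff by default); crib-negative records carry 0.
#' @return Data frame of 127 patient records with columns `patient_id`,
#'   `psa`, `clinical_t_stage`, `biopsy_gg`, `prostatectomy_gg`,
#'   `crib_positive`, `max_crib_diameter_mm`, `cpg`.
#' @export
fixture_cohort <- function(crib_diameter_mm = 6) {
  if (crib_diameter_mm <= 0) stop("fixture_cohort: diameter must be > 0")
  cell <- function(n, cpg, crib, pgg) {
    if (n == 0L) return(NULL)
    data.frame(cpg = rep(cpg, n), crib_positive = rep(crib, n),
               prostatectomy_gg = pgg)
  }
  rows <- rbind(
    # CPG-1: 26 = 3 crib+ (GG2) + 23 crib- (16 GG1 + 7 GG2)
    cell(3L, 1L, TRUE, rep(2L, 3)),
    cell(23L, 1L, FALSE, c(rep(1L, 16), rep(2L, 7))),
    # CPG-2: 72 = 8 crib+ GG>=3 (6 GG3, 2 GG4) + 25 crib+ GG2
    #            + 4 crib- GG>=3 (3 GG3, 1 GG5) + 35 crib- (7 GG1, 28 GG2)
    cell(8L, 2L, TRUE, c(rep(3L, 6), rep(4L, 2))),
    cell(25L, 2L, TRUE, rep(2L, 25)),
    cell(4L, 2L, FALSE, c(rep(3L, 3), 5L)),
    cell(35L, 2L, FALSE, c(rep(1L, 7), rep(2L, 28))),
    # CPG-3(GG2): 29 = 8 crib+ GG>=3 (6 GG3, 1 GG4, 1 GG5) + 8 crib+ GG2
    #                 + 2 crib- GG3 + 11 crib- GG2
    cell(8L, 3L, TRUE, c(rep(3L, 6), 4L, 5L)),
    cell(8L, 3L, TRUE, rep(2L, 8)),
    cell(2L, 3L, FALSE, rep(3L, 2)),
    cell(11L, 3L, FALSE, rep(2L, 11)))

  n <- nrow(rows)  # 127
  # biopsy GG marginals: 33 GG1 (26 CPG-1 + 7 CPG-2), 94 GG2;
  # the 7 CPG-2 GG1 records need PSA 10-20 to classify as CPG-2
  biopsy_gg <- ifelse(rows$cpg == 1L, 1L, 2L)
  psa <- ifelse(rows$cpg == 1L, 6.7, ifelse(rows$cpg == 2L, 7.1, 15))
  idx_cpg2_cribneg_lowgg <- which(rows$cpg == 2L & !rows$crib_positive &
                                    rows$prostatectomy_gg <= 2L)
  gg1_slots <- idx_cpg2_cribneg_lowgg[seq_len(7L)]
  biopsy_gg[gg1_slots] <- 1L
  psa[gg1_slots] <- 14

  # T-stage marginals: CPG-1 10 T1 / 16 T2; CPG-2 20 T1 / 52 T2;
  # CPG-3(GG2) 7 T1 / 22 T2
  t_stage <- rep(2L, n)
  for (g in 1:3) {
    idx <- which(rows$cpg == g)
    t_stage[idx[seq_len(c(10L, 20L, 7L)[g])]] <- 1L
  }

  out <- data.frame(
    patient_id = sprintf("F%03d", seq_len(n)),
    psa = psa,
    clinical_t_stage = t_stage,
    biopsy_gg = biopsy_gg,
    prostatectomy_gg = rows$prostatectomy_gg,
    crib_positive = rows$crib_positive,
    max_crib_diameter_mm = ifelse(rows$crib_positive, crib_diameter_mm, 0),
    cpg = rows$cpg,
    stringsAsFactors = FALSE)
  stopifnot(identical(assign_cpg(out$psa, out$biopsy_gg, out$clinical_t_stage),
                      out$cpg))
  out
}

#' Scenario cohort filters
#'
#' @param cohort Patient-record data frame (see [fixture_cohort()]).
#' @param group `"cpg12"` (CPG-1 and CPG-2) or `"cpg123gg2"` (adds CPG-3
#'   patients with biopsy GG2).
#' @return The filtered cohort.
#' @export
filter_cpg_group <- function(cohort, group = c("cpg12", "cpg123gg2")) {
  group <- match.arg(group)
  keep <- if (group == "cpg12") cohort$cpg <= 2L else
    cohort$cpg <= 2L | (cohort$cpg == 3L & cohort$biopsy_gg == 2L)
  cohort[keep, , drop = FALSE]
}

#' Allocate patients to active surveillance or active treatment
#'
#' Three allocation scenarios:
#' \itemize{
#'   \item `"reference"`: model-free benchmark; CPG-1 patients go to active
#'     surveillance (AS), everyone else in the supplied cohort to active
#'     treatment (AT). Scores and threshold are ignored. Apply
#'     [filter_cpg_group()] first to pick the scenario cohort.
#'   \item `"cpg12"`: restricts to CPG-1+2; CPG-1 goes to AS by rule, CPG-2
#'     goes to AT iff the patient's score strictly exceeds `threshold`.
#'   \item `"cpg123gg2"`: restricts to CPG-1+2+3(GG2); CPG-1 to AS by rule,
#'     CPG-2 and CPG-3(GG2) routed by the model as above.
#' }
#'
#' @param cohort Patient-record data frame.
#' @param scores Data frame with `patient_id` and `score` (the maximum
#'   probability over the patient's map); required for the model scenarios.
#' @param scenario One of `"reference"`, `"cpg12"`, `"cpg123gg2"`.
#' @param threshold Probability threshold in `[0, 1]` (or any real; the
#'   comparison is strict `score > threshold`).
#' @return Data frame with `patient_id`, `arm` (`"AS"`/`"AT"`) and `source`
#'   (`"rule_cpg1"`, `"model"`, `"rule_reference"`).
#' @export
allocate <- function(cohort, scores = NULL,
                     scenario = c("reference", "cpg12", "cpg123gg2"),
                     threshold = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "reference") {
    return(data.frame(
      patient_id = cohort$patient_id,
      arm = ifelse(cohort$cpg == 1L, "AS", "AT"),
      source = ifelse(cohort$cpg == 1L, "rule_cpg1", "rule_reference"),
      stringsAsFactors = FALSE))
  }
  cohort <- filter_cpg_group(cohort,
                             if (scenario == "cpg12") "cpg12" else "cpg123gg2")
  if (is.null(threshold) || !is.numeric(threshold) || length(threshold) != 1L) {
    stop("allocate: model scenarios need a single numeric `threshold`")
  }
  routed <- cohort$cpg != 1L
  arm <- rep("AS", nrow(cohort))
  src <- rep("rule_cpg1", nrow(cohort))
  if (any(routed)) {
    if (is.null(scores)) stop("allocate: model scenarios need `scores`")
    m <- match(cohort$patient_id[routed], scores$patient_id)
    if (anyNA(m)) {
      stop("allocate: missing score for model-routed patient(s): ",
           paste(cohort$patient_id[routed][is.na(m)], collapse = ", "))
    }
    s <- scores$score[m]
    arm[routed] <- ifelse(s > threshold, "AT", "AS")
    src[routed] <- "model"
  }
  data.frame(patient_id = cohort$patient_id, arm = arm, source = src,
             stringsAsFactors = FALSE)
}

#' The six allocation-outcome categories
#'
#' @return Character vector of the category names, in reporting order.
#' @export
outcome_categories <- function() {
  c("correct_AS", "correct_AT", "false_AS_crib_small", "false_AS_crib_large",
    "false_AS_gg3", "false_AT")
}

#' Categorize each allocated patient against histologic ground truth
#'
#' Exhaustive, mutually exclusive outcome accounting given the allocation
#' arm, patient-level cribriform status, prostatectomy GG and the maximum
#' cribriform focus diameter:
#' \itemize{
#'   \item AS, crib-, GG < 3: `correct_AS` (appropriately surveilled).
#'   \item AT, crib+ (any GG), or AT, crib- with GG >= 3: `correct_AT`
#'     (adverse histology appropriately treated).
#'   \item AS, crib+, diameter below `size_cutoff_mm`: `false_AS_crib_small`
#'     (undertreated; focus likely below MRI's detection limit).
#'   \item AS, crib+, diameter at or above the cutoff: `false_AS_crib_large`.
#'   \item AS, crib-, GG >= 3: `false_AS_gg3` (undertreated for grade, not
#'     cribriform).
#'   \item AT, crib-, GG < 3: `false_AT` (overtreated).
#' }
#'
#' @param cohort Patient-record data frame.
#' @param allocation Output of [allocate()] for (a subset of) the cohort.
#' @param size_cutoff_mm Cribriform-diameter cutoff separating small from
#'   large missed foci; default 1.5 mm, the nominal MRI detection limit.
#' @return The allocation joined with the records, plus a `category` factor
#'   with levels [outcome_categories()].
#' @export
categorize_outcomes <- function(cohort, allocation, size_cutoff_mm = 1.5) {
  m <- match(allocation$patient_id, cohort$patient_id)
  if (anyNA(m)) stop("categorize_outcomes: allocation has unknown patient ids")
  rec <- cohort[m, , drop = FALSE]
  as_arm <- allocation$arm == "AS"
  crib <- rec$crib_positive
  gg_hi <- rec$prostatectomy_gg >= 3L
  small <- rec$max_crib_diameter_mm < size_cutoff_mm
  cat <- character(nrow(rec))
  cat[as_arm & !crib & !gg_hi] <- "correct_AS"
  cat[as_arm & crib & small] <- "false_AS_crib_small"
  cat[as_arm & crib & !small] <- "false_AS_crib_large"
  cat[as_arm & !crib & gg_hi] <- "false_AS_gg3"
  cat[!as_arm & (crib | gg_hi)] <- "correct_AT"
  cat[!as_arm & !crib & !gg_hi] <- "false_AT"
  out <- cbind(allocation,
               rec[, c("crib_positive", "prostatectomy_gg",
                       "max_crib_diameter_mm", "cpg")])
  out$category <- factor(cat, levels = outcome_categories())
  out
}

#' Run a decision scenario over a threshold grid
#'
#' Allocates, categorizes and tabulates the six outcome categories for each
#' threshold, with the derived over-/undertreatment summaries:
#' undertreatment is the sum of the three falsely-in-AS categories,
#' overtreatment the falsely-in-AT category, and appropriate management the
#' two correct categories. The reference scenario is threshold-free and
#' yields a single row.
#'
#' @inheritParams allocate
#' @param thresholds Sorted numeric thresholds (ignored for `"reference"`).
#' @param size_cutoff_mm Passed to [categorize_outcomes()].
#' @return Data frame, one row per threshold, with `scenario`, `threshold`,
#'   `n`, a count and a percentage column per category (`pct_` columns, in
#'   percent), and `appropriate_pct`, `undertreatment_pct`,
#'   `overtreatment_pct`, `as_eligible_pct`.
#' @export
run_scenario <- function(cohort, scores = NULL,
                         scenario = c("reference", "cpg12", "cpg123gg2"),
                         thresholds = NULL, size_cutoff_mm = 1.5) {
  scenario <- match.arg(scenario)
  if (scenario == "reference") {
    thresholds <- NA_real_
  } else {
    if (is.null(thresholds) || length(thresholds) < 1L) {
      stop("run_scenario: model scenarios need `thresholds`")
    }
    if (is.unsorted(thresholds)) stop("run_scenario: `thresholds` must be sorted")
  }
  rows <- lapply(thresholds, function(th) {
    alloc <- if (scenario == "reference") {
      allocate(cohort, scenario = "reference")
    } else {
      allocate(cohort, scores, scenario, threshold = th)
    }
    catg <- categorize_outcomes(cohort, alloc, size_cutoff_mm)
    n <- nrow(catg)
    counts <- table(catg$category)
    stopifnot(sum(counts) == n)  # categories partition the scenario cohort
    pct <- 100 * as.numeric(counts) / n
    under <- sum(counts[c("false_AS_crib_small", "false_AS_crib_large",
                          "false_AS_gg3")])
    over <- counts[["false_AT"]]
    appr <- counts[["correct_AS"]] + counts[["correct_AT"]]
    out <- data.frame(scenario = scenario, threshold = th, n = n)
    for (i in seq_along(counts)) {
      out[[names(counts)[i]]] <- as.integer(counts[i])
      out[[paste0("pct_", names(counts)[i])]] <- pct[i]
    }
    out$appropriate_pct <- 100 * appr / n
    out$undertreatment_pct <- 100 * under / n
    out$overtreatment_pct <- 100 * over / n
    out$as_eligible_pct <- 100 * sum(alloc$arm == "AS") / n
    out
  })
  do.call(rbind, rows)
}
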
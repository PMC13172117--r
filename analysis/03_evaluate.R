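#!/usr/bin/env Rscript
# Step 3: standalone diagnostic performance of the patient scores.
#
# AUROC and PR-AUC against the histologic ground truth, overall and within
# the model-routed subgroups, with 95% percentile-bootstrap intervals
# (1000 patient-level resamples).

suppressPackageStartupMessages(library(cribmap))

cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
scores <- read.csv("results/scores.csv", stringsAsFactors = FALSE)
m <- match(cohort$patient_id, scores$patient_id)
stopifnot(!anyNA(m))
cohort$score <- scores$score[m]

eval_group <- function(df, name) {
  if (length(unique(df$crib_positive)) < 2L) {
    cat(sprintf("%s: single-class subgroup (n = %d), skipped\n", name, nrow(df)))
    return(NULL)
  }
  ev <- evaluate_scores(df$score, df$crib_positive, n_boot = 1000, seed = 11)
  cat(sprintf("%-12s n = %3d prev %.2f  AUROC %.2f (%.2f-%.2f)  AUPRC %.2f (%.2f-%.2f)\n",
              name, ev$n, ev$prevalence, ev$auroc, ev$auroc_ci[1],
              ev$auroc_ci[2], ev$auprc, ev$auprc_ci[1], ev$auprc_ci[2]))
  list(group = name, n = ev$n, prevalence = ev$prevalence,
       auroc = ev$auroc, auroc_ci = as.numeric(ev$auroc_ci),
       auprc = ev$auprc, auprc_ci = as.numeric(ev$auprc_ci))
}

res <- Filter(Negate(is.null), list(
  eval_group(cohort, "ALL"),
  eval_group(cohort[cohort$cpg == 2L, ], "CPG2"),
  eval_group(cohort[cohort$cpg == 3L, ], "CPG3GG2")))

jsonlite::write_json(res, "results/eval.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/eval.json\n")
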
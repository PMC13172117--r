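#!/usr/bin/env Rscript
# Step 4: active-surveillance decision scenarios.
#
# Two accountings:
#   (a) the fixed 127-record fixture cohort under the model-free reference
#       allocation (only CPG-1 to AS) - the benchmark every model scenario
#       is compared against; and
#   (b) the simulated imaging cohort (steps 1-2) swept over probability
#       thresholds in the CPG-1+2 and CPG-1+2+3(GG2) scenarios, with the
#       six-category over/undertreatment breakdown and a stacked-bar figure.

suppressPackageStartupMessages(library(cribmap))

# (a) fixture reference accounting
fx <- fixture_cohort()
ref12 <- run_scenario(filter_cpg_group(fx, "cpg12"), scenario = "reference")
reffull <- run_scenario(fx, scenario = "reference")
cat("fixture cohort, reference allocation (no model):\n")
cat(sprintf("  CPG-1+2        (n = %3d): appropriate %.0f%%, undertreatment %.0f%%, overtreatment %.0f%%\n",
            ref12$n, ref12$appropriate_pct, ref12$undertreatment_pct,
            ref12$overtreatment_pct))
cat(sprintf("  CPG-1+2+3(GG2) (n = %3d): appropriate %.0f%%, correctly in AS %.0f%%\n",
            reffull$n, reffull$appropriate_pct,
            100 * reffull$correct_AS / reffull$n))

# (b) threshold sweep on the simulated cohort
cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
scores <- read.csv("results/scores.csv", stringsAsFactors = FALSE)
th <- seq(0.05, 0.95, by = 0.05)

sweep <- do.call(rbind, lapply(c("cpg12", "cpg123gg2"), function(scen) {
  rbind(run_scenario(filter_cpg_group(cohort,
                                      if (scen == "cpg12") "cpg12" else "cpg123gg2"),
                     scenario = "reference"),
        run_scenario(cohort, scores, scen, thresholds = th))
}))
# long format: scenario, threshold, category, count, pct
long <- do.call(rbind, lapply(seq_len(nrow(sweep)), function(i) {
  row <- sweep[i, ]
  data.frame(scenario = row$scenario, threshold = row$threshold, n = row$n,
             category = outcome_categories(),
             count = as.integer(row[outcome_categories()]),
             pct = as.numeric(row[paste0("pct_", outcome_categories())]))
}))
write.table(long, "results/scenarios.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

best <- sweep[!is.na(sweep$threshold), ]
best <- best[which.max(best$appropriate_pct), ]
cat(sprintf("best simulated sweep point: %s at threshold %.2f -> appropriate %.0f%% (undertreatment %.0f%%, overtreatment %.0f%%)\n",
            best$scenario, best$threshold, best$appropriate_pct,
            best$undertreatment_pct, best$overtreatment_pct))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  long$category <- factor(long$category, levels = rev(outcome_categories()))
  long$xlab <- ifelse(is.na(long$threshold), "ref",
                      sprintf("%.2f", long$threshold))
  pal <- c(correct_AS = "#2e7d32", correct_AT = "#6a4fa3",
           false_AS_crib_small = "#fff176", false_AS_crib_large = "#fbc02d",
           false_AS_gg3 = "#c49000", false_AT = "#ef6c00")
  p <- ggplot(long, aes(x = xlab, y = pct, fill = category)) +
    geom_col() +
    scale_fill_manual(values = pal) +
    facet_wrap(~scenario, ncol = 1) +
    labs(x = "probability threshold", y = "% of scenario cohort",
         fill = NULL) +
    theme_minimal(base_size = 9)
  ggsave("results/scenario_bars.pdf", p, width = 7.5, height = 5.5)
  cat("wrote results/scenario_bars.pdf\n")
}
cat("wrote results/scenarios.tsv\n")
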
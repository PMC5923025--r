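#!/usr/bin/env Rscript
# Step 2 — evaluate every endpoint per assessment session.
#
# Reads the simulated study from step 1 and computes, per session on the
# records retained by the inclusion rule: accuracy, sensitivity and
# specificity for red patients, the four mutually exclusive error rates,
# intervention decision accuracies, raw and category-weighted triage
# times, the 100-point performance score and the pass rate. Writes
# results/metrics.csv (one row per session, Wilson/t 95% CIs).
#
#   Rscript analysis/02_evaluate.R

suppressPackageStartupMessages(library(triagesim))
study <- readRDS("results/study.rds")

tab <- study_metric_table(study)
utils::write.csv(tab, "results/metrics.csv", row.names = FALSE)

fmt_pct <- function(e, lo, hi) sprintf("%3.0f%% (%.0f-%.0f)", 100 * e, 100 * lo, 100 * hi)
cat("Session endpoints (included records):\n")
for (i in seq_len(nrow(tab))) {
  cat(sprintf("\nsession %d (month %.1f, n = %d procedures):\n",
              tab$session[i], tab$month[i], tab$n[i]))
  cat(sprintf("  accuracy    %s   sensitivity %s   specificity %s\n",
              fmt_pct(tab$accuracy[i], tab$accuracy_lo[i], tab$accuracy_hi[i]),
              fmt_pct(tab$sensitivity[i], tab$sensitivity_lo[i], tab$sensitivity_hi[i]),
              fmt_pct(tab$specificity[i], tab$specificity_lo[i], tab$specificity_hi[i])))
  cat(sprintf("  under %s (critical %s)   over %s (critical %s)\n",
              fmt_pct(tab$under_rate[i], tab$under_rate_lo[i], tab$under_rate_hi[i]),
              fmt_pct(tab$critical_under_rate[i], tab$critical_under_rate_lo[i],
                      tab$critical_under_rate_hi[i]),
              fmt_pct(tab$over_rate[i], tab$over_rate_lo[i], tab$over_rate_hi[i]),
              fmt_pct(tab$critical_over_rate[i], tab$critical_over_rate_lo[i],
                      tab$critical_over_rate_hi[i])))
  cat(sprintf("  time %.1f s (weighed to 20/20/60 casualty mix: %.1f s)\n",
              tab$mean_time_s[i], tab$weighted_time_s[i]))
  cat(sprintf("  performance score %.1f, pass rate %s\n",
              tab$performance_score[i],
              fmt_pct(tab$pass_rate[i], tab$pass_rate_lo[i], tab$pass_rate_hi[i])))
}

# pooled vs provider-averaged error rates (the two readings can differ
# when providers contribute unequal procedure counts)
cat("\nProvider-averaged accuracy per session (vs pooled):\n")
for (s in tab$session) {
  recs <- study$records_included[study$records_included$session == s, ]
  pa <- compute_metrics_by_provider(recs)
  cat(sprintf("  session %d: provider-averaged %.0f%%, pooled %.0f%%\n",
              s, 100 * pa$accuracy, 100 * tab$accuracy[tab$session == s]))
}
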
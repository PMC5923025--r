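#!/usr/bin/env Rscript
# Step 3 — statistical comparisons between assessment time points.
#
# Part A endpoints (per-provider rates within session) are compared by
# one-way ANOVA with Bonferroni post-hoc contrasts; Part B endpoints
# (performance score, pass indicator) by paired t-test and Wilcoxon
# signed-rank (Pratt). Writes results/comparisons.csv.
#
#   Rscript analysis/03_compare.R

suppressPackageStartupMessages(library(triagesim))
study <- readRDS("results/study.rds")
recs <- study$records_included
alpha <- study$config$alpha

rows <- list()
part_a <- c(accuracy = TRUE, sensitivity = TRUE, specificity = TRUE,
            under_rate = FALSE, critical_under_rate = FALSE,
            over_rate = FALSE, critical_over_rate = FALSE,
            airway_accuracy = TRUE, bleeding_accuracy = TRUE,
            mean_time_s = FALSE)
cat("Part A (procedure level, per-provider rates, ANOVA + Bonferroni):\n")
for (ep in names(part_a)) {
  pr <- provider_rates(recs, ep)
  cmp <- compare_sessions(pr, "value", "session",
                          higher_better = part_a[[ep]], alpha = alpha)
  cmp$endpoint <- ep
  cmp$part <- "A"
  rows[[ep]] <- cmp
  pw <- cmp[cmp$contrast != "omnibus", ]
  mark <- c(improvement = "UP", decline = "DOWN", none = "")[pw$direction]
  cat(sprintf("  %-22s %s\n", ep,
              paste(sprintf("%s p=%.3f %s", pw$contrast, pw$p_value, mark),
                    collapse = "  ")))
}

cat("\nPart B (provider level, paired tests):\n")
scores <- lapply(study$sessions$session, function(s)
  provider_scores(recs[recs$session == s, ]))
pairs <- utils::combn(seq_along(scores), 2, simplify = FALSE)
for (pr in pairs) {
  res <- tryCatch(
    compare_provider_level(scores[[pr[1]]], scores[[pr[2]]],
                           threshold = study$config$pass_threshold, alpha = alpha),
    error = function(e) NULL)
  if (is.null(res)) next
  cmp <- res$comparisons
  cmp$contrast <- sprintf("%d vs %d", pr[2], pr[1])
  cmp$part <- "B"
  rows[[paste0("B", pr[1], pr[2])]] <- cmp
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf("  %-18s %s: %s p=%.3f %s (n=%d pairs)\n", cmp$endpoint[i],
                cmp$contrast[i], cmp$test[i], cmp$p_value[i],
                c(improvement = "UP", decline = "DOWN", none = "")[cmp$direction[i]],
                res$n_pairs))
  }
}

all_rows <- do.call(rbind, rows)
utils::write.csv(all_rows, "results/comparisons.csv", row.names = FALSE)
cat(sprintf("\n%d comparison rows written to results/comparisons.csv\n", nrow(all_rows)))

# normality of the provider scores feeding the paired t-test
for (s in seq_along(scores)) {
  if (nrow(scores[[s]]) >= 3 && stats::sd(scores[[s]]$score) > 0) {
    nc <- normality_check(scores[[s]]$score)
    cat(sprintf("Shapiro-Wilk, session %d scores: W = %.3f, p = %.3f\n",
                s, nc[["statistic"]], nc[["p_value"]]))
  }
}
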
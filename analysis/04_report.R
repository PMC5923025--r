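#!/usr/bin/env Rscript
# Step 4 — render the markdown study report (Part A / Part B blocks with
# direction markers) to results/report.md.
#
#   Rscript analysis/04_report.R

suppressPackageStartupMessages(library(triagesim))
study <- readRDS("results/study.rds")
lines <- render_report(study)
writeLines(lines, "results/report.md")
cat(sprintf("report written to results/report.md (%d lines)\n", length(lines)))
cat(lines[seq_len(min(12, length(lines)))], sep = "\n")
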
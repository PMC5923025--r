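#' Read and write triage record tables
#'
#' Triage records are exchanged as plain CSV, one row per triage
#' procedure, with categories serialised as `RED`/`YELLOW`/`GREEN`/`DEAD`.
#' `write_records()` then `read_records()` is the identity on the record
#' schema. Reading validates the category columns and reports the first
#' offending line by number.
#'
#' @param path CSV file path.
#' @param records record data frame (see [simulate_session()]).
#' @return `read_records()`: the validated record data frame.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("assigned", "expected"), names(df))) {
    bad <- which(!df[[col]] %in% triage_categories())
    if (length(bad) > 0L) {
      stop(sprintf("%s line %d: invalid triage category `%s` in column `%s`",
                   path, bad[1] + 1L, df[[col]][bad[1]], col), call. = FALSE)
    }
  }
  if ("time_s" %in% names(df) && any(df$time_s <= 0, na.rm = TRUE)) {
    stop(path, ": non-positive triage time", call. = FALSE)
  }
  df
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Load a study configuration from YAML
#'
#' Reads a YAML document of [study_config()] overrides and merges it
#' with the defaults; nested lists (`skill`, `time`) are merged
#' field-wise and their numeric vectors keep their names.
#'
#' @param path YAML file path.
#' @return a validated `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (nested in c("skill", "time")) {
    if (!is.null(raw[[nested]])) {
      base <- if (nested == "skill") default_skill_params() else default_time_params()
      ov <- raw[[nested]]
      for (fld in names(ov)) {
        base[[fld]] <- if (is.list(ov[[fld]])) unlist(ov[[fld]]) else ov[[fld]]
      }
      raw[[nested]] <- base
    }
  }
  for (fld in c("category_mix", "weights")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  do.call(study_config, raw)
}

#' Configuration fingerprint
#'
#' MD5 hash of a canonical serialisation of a study configuration, so
#' runs can log "config hash + seed" and identical pairs are guaranteed
#' to produce identical outputs.
#'
#' @param config a `study_config`.
#' @return character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Session-by-session metric table for a study
#'
#' Computes the full endpoint panel (see [compute_metrics()]) plus the
#' provider-level performance score and pass rate for every assessment
#' session of a simulated or recorded study, on the records retained by
#' the inclusion rule.
#'
#' @param study a `triage_study` (or a list with `records_included`,
#'   `sessions`, `config`).
#' @return data frame, one row per session: the [compute_metrics()]
#'   columns plus `session`, `month`, `performance_score` (mean with
#'   `_lo`/`_hi`), `pass_rate` (with `_lo`/`_hi`) and `n2`.
#' @export
study_metric_table <- function(study) {
  cfg <- study$config
  rows <- lapply(study$sessions$session, function(s) {
    recs <- study$records_included[study$records_included$session == s, ]
    m <- compute_metrics(recs, weights = cfg$weights)
    sc <- provider_scores(recs)
    ps <- t_ci(sc$score)
    pr <- pass_rate(sc$score, cfg$pass_threshold)
    cbind(data.frame(session = s,
                     month = study$sessions$month[study$sessions$session == s]),
          m,
          data.frame(performance_score = ps[["estimate"]],
                     performance_score_lo = ps[["lower"]],
                     performance_score_hi = ps[["upper"]],
                     pass_rate = pr[["estimate"]],
                     pass_rate_lo = pr[["lower"]],
                     pass_rate_hi = pr[["upper"]],
                     n2 = nrow(sc)))
  })
  do.call(rbind, rows)
}

#' Render a markdown study report
#'
#' Produces a compact markdown report of a simulated study in the
#' familiar two-block layout: Part A (procedure-level endpoints per
#' session with ANOVA/Bonferroni contrasts) and Part B (provider-level
#' performance score and pass rate with paired tests), using up- and
#' down-arrows for significant improvement and decline.
#'
#' @param study a `triage_study`.
#' @return character vector of markdown lines (invisibly returned by
#'   `cat`-ing them with `writeLines`).
#' @export
render_report <- function(study) {
  cfg <- study$config
  tab <- study_metric_table(study)
  recs <- study$records_included
  pct <- function(x) ifelse(is.na(x), "-", sprintf("%.0f%%", 100 * x))
  ci <- function(lo, hi, f = pct) sprintf("(%s-%s)", f(lo), f(hi))
  sec <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", x))

  lines <- c(
    sprintf("# Simulated triage study report (%s)", cfg$tree),
    "",
    sprintf("- Sessions at months: %s", paste(tab$month, collapse = ", ")),
    sprintf("- N1 = %d triage procedures analyzed, N2 = %d providers", study$n1, study$n2),
    sprintf("- Config hash: %s", config_hash(cfg)),
    "",
    "## Part A: level of triage procedures", "")
  hdr <- paste0("| Endpoint | ", paste(sprintf("Session %d (m=%s)", tab$session,
                                               tab$month), collapse = " | "), " |")
  lines <- c(lines, hdr,
             paste0("|", paste(rep("---|", nrow(tab) + 1), collapse = "")))
  add_row <- function(label, est, lo, hi, f = pct) {
    vals <- sprintf("%s %s", f(est), ci(lo, hi, f))
    paste0("| ", label, " | ", paste(vals, collapse = " | "), " |")
  }
  lines <- c(lines,
    add_row("Accuracy", tab$accuracy, tab$accuracy_lo, tab$accuracy_hi),
    add_row("Sensitivity", tab$sensitivity, tab$sensitivity_lo, tab$sensitivity_hi),
    add_row("Specificity", tab$specificity, tab$specificity_lo, tab$specificity_hi),
    add_row("Under-triage", tab$under_rate, tab$under_rate_lo, tab$under_rate_hi),
    add_row("Critical under-triage", tab$critical_under_rate,
            tab$critical_under_rate_lo, tab$critical_under_rate_hi),
    add_row("Over-triage", tab$over_rate, tab$over_rate_lo, tab$over_rate_hi),
    add_row("Critical over-triage", tab$critical_over_rate,
            tab$critical_over_rate_lo, tab$critical_over_rate_hi),
    add_row("Airway handling accurate", tab$airway_accuracy,
            tab$airway_accuracy_lo, tab$airway_accuracy_hi),
    add_row("Bleeding management accurate", tab$bleeding_accuracy,
            tab$bleeding_accuracy_lo, tab$bleeding_accuracy_hi),
    add_row("Time requirement (s)", tab$mean_time_s, tab$mean_time_s_lo,
            tab$mean_time_s_hi, sec),
    add_row("Time requirement (s), weighed", tab$weighted_time_s,
            tab$weighted_time_s_lo, tab$weighted_time_s_hi, sec),
    "", "### Statistical comparisons (per-provider rates, ANOVA + Bonferroni)", "")

  arrows <- function(row) {
    mark <- c(improvement = " ⇑", decline = " ⇓", none = "")[row$direction]
    sprintf("%s: p = %.3f%s", row$contrast, row$p_value, mark)
  }
  for (ep in c("accuracy", "under_rate", "over_rate", "mean_time_s")) {
    pr <- provider_rates(recs, ep)
    cmp <- compare_sessions(pr, "value", "session",
                            higher_better = ep == "accuracy", alpha = cfg$alpha)
    pw <- cmp[cmp$contrast != "omnibus", ]
    lines <- c(lines, sprintf("- %s: %s", ep, paste(arrows(pw), collapse = "; ")))
  }

  lines <- c(lines, "", "## Part B: level of providers", "",
    add_row("Performance measure", tab$performance_score / 100,
            tab$performance_score_lo / 100, tab$performance_score_hi / 100,
            function(x) sprintf("%.0f", 100 * x)),
    add_row("Pass rate (>= 90)", tab$pass_rate, tab$pass_rate_lo, tab$pass_rate_hi),
    "", "### Paired comparisons vs baseline", "")
  base_scores <- provider_scores(recs[recs$session == 1, ])
  for (s in tab$session[-1]) {
    sc <- provider_scores(recs[recs$session == s, ])
    res <- tryCatch(compare_provider_level(base_scores, sc, cfg$pass_threshold,
                                           cfg$alpha),
                    error = function(e) NULL)
    if (is.null(res)) {
      lines <- c(lines, sprintf("- session %d vs 1: too few matched providers", s))
    } else {
      lines <- c(lines, sprintf("- session %d vs 1 (n = %d pairs): %s", s,
                                res$n_pairs,
                                paste(sprintf("%s %s", res$comparisons$endpoint,
                                              arrows(res$comparisons)),
                                      collapse = "; ")))
    }
  }
  lines
}
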
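#' Compare a procedure-level endpoint across assessment sessions
#'
#' Procedure-level endpoints (accuracy, sensitivity, specificity, error
#' rates, intervention accuracies, triage time) are compared between
#' assessment time points by one-way ANOVA with Bonferroni-adjusted
#' pairwise post-hoc t-tests (pooled SD). Because procedures by the
#' same provider are not independent, the default unit of analysis is
#' the per-provider rate within each session (`unit = "provider"`);
#' `unit = "procedure"` uses the raw per-procedure values instead.
#'
#' @param data data frame with one row per analysis unit.
#' @param value name of the numeric outcome column.
#' @param group name of the session/time-point column.
#' @param higher_better direction that counts as improvement (`TRUE`
#'   for accuracy-like endpoints, `FALSE` for error rates and times).
#' @param alpha significance level (default 0.05).
#' @return data frame of `comparison_result` rows: the omnibus ANOVA
#'   followed by every pairwise contrast, with columns `endpoint`,
#'   `contrast`, `test`, `statistic`, `p_value`, `direction`
#'   (`improvement`/`decline`/`none`), `significant`.
#' @export
compare_sessions <- function(data, value, group, higher_better = TRUE, alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least two sessions to compare", call. = FALSE)
  fit <- stats::aov(x ~ g)
  om <- summary(fit)[[1]]
  rows <- list(comparison_row(value, "omnibus", "ANOVA", om$`F value`[1],
                              om$`Pr(>F)`[1], NA, alpha))
  ph <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni", pool.sd = TRUE)
  means <- tapply(x, g, mean)
  lv <- levels(g)
  for (j in seq_len(nlevels(g) - 1)) {
    for (i in seq(j + 1, nlevels(g))) {
      p <- ph$p.value[lv[i], lv[j]]
      delta <- means[[lv[i]]] - means[[lv[j]]]
      rows[[length(rows) + 1L]] <- comparison_row(
        value, paste0(lv[i], " vs ", lv[j]), "ANOVA_BONFERRONI",
        NA_real_, p, delta * ifelse(higher_better, 1, -1), alpha)
    }
  }
  do.call(rbind, rows)
}

comparison_row <- function(endpoint, contrast, test, statistic, p, signed_delta, alpha) {
  sig <- !is.na(p) && p < alpha
  direction <- if (!sig || is.na(signed_delta)) {
    "none"
  } else if (signed_delta > 0) "improvement" else "decline"
  data.frame(endpoint = endpoint, contrast = contrast, test = test,
             statistic = as.numeric(statistic), p_value = as.numeric(p),
             direction = direction, significant = sig,
             stringsAsFactors = FALSE)
}

#' Per-provider endpoint rates within each session
#'
#' Helper producing the default analysis units for [compare_sessions()]:
#' one row per provider and session holding the rate of the requested
#' endpoint over the procedures that provider led.
#'
#' @param records study records (see [simulate_study()]).
#' @param endpoint one of `"accuracy"`, `"sensitivity"`, `"specificity"`,
#'   `"under_rate"`, `"critical_under_rate"`, `"over_rate"`,
#'   `"critical_over_rate"`, `"airway_accuracy"`, `"bleeding_accuracy"`,
#'   `"mean_time_s"`.
#' @return data frame `session`, `provider_id`, `value` (`NA` when the
#'   endpoint is undefined for a provider's case mix, e.g. sensitivity
#'   with no expected-RED patients).
#' @export
provider_rates <- function(records, endpoint = "accuracy") {
  fun <- switch(endpoint,
    accuracy = function(d) mean(d$assigned == d$expected),
    sensitivity = function(d) {
      pos <- d$expected == "RED"
      if (!any(pos)) NA_real_ else mean(d$assigned[pos] == "RED")
    },
    specificity = function(d) {
      neg <- d$expected != "RED"
      if (!any(neg)) NA_real_ else mean(d$assigned[neg] != "RED")
    },
    under_rate = function(d) mean(classify_error(d$assigned, d$expected) == "UNDER"),
    critical_under_rate = function(d) mean(classify_error(d$assigned, d$expected) == "CRITICAL_UNDER"),
    over_rate = function(d) mean(classify_error(d$assigned, d$expected) == "OVER"),
    critical_over_rate = function(d) mean(classify_error(d$assigned, d$expected) == "CRITICAL_OVER"),
    airway_accuracy = function(d) mean(d$airway_indicated == d$airway_performed),
    bleeding_accuracy = function(d) mean(d$bleeding_indicated == d$bleeding_performed),
    mean_time_s = function(d) mean(d$time_s),
    stop("unknown endpoint: ", endpoint, call. = FALSE))
  parts <- split(records, list(records$session, records$leader_id), drop = TRUE)
  out <- lapply(parts, function(d) {
    data.frame(session = d$session[1], provider_id = d$leader_id[1],
               value = fun(d), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$session, res$provider_id), ]
}

#' Compare provider-level performance between two sessions
#'
#' Provider-level endpoints are compared with paired tests on the
#' providers present in both sessions (unmatched providers are dropped
#' and counted): the performance score by a paired t-test, and the
#' binary qualification indicator (score at or above the threshold) by
#' the Wilcoxon signed-rank test with Pratt's treatment of zero
#' differences. When all paired differences are zero the t-test is
#' undefined and flagged (`p_value = NA`), not an error.
#'
#' @param scores_a,scores_b data frames `provider_id`, `score` for the
#'   two sessions (see [provider_scores()]).
#' @param threshold qualification threshold (default 90).
#' @param alpha significance level.
#' @param higher_better direction counting as improvement.
#' @return list: `comparisons` (two `comparison_result` rows:
#'   `PAIRED_T` on scores, `WILCOXON` on pass indicators), `n_pairs`,
#'   `n_dropped`.
#' @export
compare_provider_level <- function(scores_a, scores_b, threshold = 90,
                                   alpha = 0.05, higher_better = TRUE) {
  m <- merge(scores_a, scores_b, by = "provider_id", suffixes = c("_a", "_b"))
  n_dropped <- nrow(scores_a) + nrow(scores_b) - 2 * nrow(m)
  if (nrow(m) < 2) stop("fewer than two matched providers", call. = FALSE)
  d <- m$score_b - m$score_a
  sgn <- ifelse(higher_better, 1, -1)
  if (stats::sd(d) == 0) {
    t_row <- comparison_row("performance_score", "paired", "PAIRED_T",
                            NA_real_, NA_real_, NA_real_, alpha)
  } else {
    tt <- stats::t.test(m$score_b, m$score_a, paired = TRUE)
    t_row <- comparison_row("performance_score", "paired", "PAIRED_T",
                            tt$statistic, tt$p.value, mean(d) * sgn, alpha)
  }
  pass_d <- as.integer(m$score_b >= threshold) - as.integer(m$score_a >= threshold)
  w <- wilcoxon_pratt(pass_d)
  w_row <- comparison_row("pass_indicator", "paired", "WILCOXON",
                          w["statistic"], w["p_value"], mean(pass_d) * sgn, alpha)
  list(comparisons = rbind(t_row, w_row), n_pairs = nrow(m), n_dropped = n_dropped)
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' One-sample (paired-difference) signed-rank test. Unlike the
#' classical procedure, zero differences are not discarded before
#' ranking: all absolute differences (zeros included) are ranked with
#' mid-ranks, then the ranks of the zeros are dropped from the
#' statistic (Pratt's method), which keeps the test honest when many
#' pairs are tied — the typical situation for binary indicators such as
#' pass/fail. Normal approximation with tie and zero corrections and
#' continuity correction.
#'
#' @param d numeric vector of paired differences.
#' @return named vector `c(statistic, p_value)`; `p_value = NA` when
#'   every difference is zero.
#' @export
wilcoxon_pratt <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L || all(d == 0)) {
    return(c(statistic = NA_real_, p_value = NA_real_))
  }
  r <- rank(abs(d))                       # zeros included in the ranking
  nz <- d != 0
  v <- sum(r[nz & d > 0])                 # V+, over non-zero differences only
  n0 <- sum(!nz)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  ties <- table(r[nz])
  sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sigma2 <= 0) return(c(statistic = v, p_value = NA_real_))
  z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
  c(statistic = v, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper used before choosing parametric provider-level tests.
#'
#' @param x numeric vector (3 to 5000 values).
#' @return named vector `c(statistic, p_value)`.
#' @export
normality_check <- function(x) {
  s <- stats::shapiro.test(x)
  c(statistic = unname(s$statistic), p_value = s$p.value)
}
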
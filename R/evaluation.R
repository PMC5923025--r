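#' Classify a triage assignment against the consented standard solution
#'
#' The five-class triage error taxonomy partitions all 16
#' (assigned, expected) category pairs: the diagonal is `OK`; assigning
#' RED to a non-RED patient is `CRITICAL_OVER`; missing a RED patient is
#' `CRITICAL_UNDER`; any other assignment more urgent than expected is
#' `OVER`, any less urgent is `UNDER`. Urgency ordering:
#' RED > YELLOW > GREEN > DEAD.
#'
#' @param assigned,expected triage category labels (vectorised).
#' @return character vector over
#'   `{OK, OVER, UNDER, CRITICAL_OVER, CRITICAL_UNDER}`.
#' @export
#' @examples
#' classify_error("RED", "YELLOW")   # CRITICAL_OVER
#' classify_error("GREEN", "RED")    # CRITICAL_UNDER
#' classify_error("YELLOW", "GREEN") # OVER
classify_error <- function(assigned, expected) {
  assert_category(assigned); assert_category(expected)
  a <- category_urgency(assigned)
  e <- category_urgency(expected)
  out <- rep("OK", length(a))
  out[a > e] <- "OVER"
  out[a < e] <- "UNDER"
  out[assigned == "RED" & expected != "RED"] <- "CRITICAL_OVER"
  out[expected == "RED" & assigned != "RED"] <- "CRITICAL_UNDER"
  out
}

error_classes <- function() c("OK", "OVER", "UNDER", "CRITICAL_OVER", "CRITICAL_UNDER")

#' Confusion table of assigned versus expected categories
#'
#' @param assigned,expected category label vectors of equal length.
#' @return 4x4 integer table, rows = assigned, columns = expected, in
#'   urgency order RED, YELLOW, GREEN, DEAD; entries sum to the number
#'   of records.
#' @export
confusion <- function(assigned, expected) {
  assert_category(assigned); assert_category(expected)
  lv <- triage_categories()
  table(assigned = factor(assigned, lv), expected = factor(expected, lv))
}

#' Wilson score confidence interval for a proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(estimate, lower, upper)`; all `NA` when
#'   `n == 0` (the proportion is undefined, not zero).
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

t_ci <- function(x, conf = 0.95) {
  n <- sum(!is.na(x))
  m <- mean(x, na.rm = TRUE)
  if (n < 2) return(c(estimate = m, lower = NA_real_, upper = NA_real_))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x, na.rm = TRUE) / sqrt(n)
  c(estimate = m, lower = m - half, upper = m + half)
}

#' Endpoint metrics for a set of triage records
#'
#' Computes the full endpoint panel for one assessment session (or any
#' record subset): accuracy (fraction of records whose assigned category
#' equals the consented standard), the four mutually exclusive error
#' rates from [classify_error()] (which together with accuracy sum to
#' one), sensitivity and specificity for RED patients (all non-RED
#' categories count as negatives), the accuracy of the airway and
#' bleeding-control intervention decisions (performed if and only if
#' indicated), mean triage time and the category-weighted mean time (see
#' [weighted_time()]). Proportions carry Wilson 95% confidence
#' intervals; times carry t-based intervals.
#'
#' With zero expected-RED records sensitivity is `NA` (undefined), never
#' zero; likewise specificity with zero non-RED records.
#'
#' @param records a triage record data frame with columns `assigned`,
#'   `expected`, and optionally `airway_indicated`/`airway_performed`,
#'   `bleeding_indicated`/`bleeding_performed`, `time_s`.
#' @param weights category weights for the weighted time; see
#'   [weighted_time()].
#' @param conf confidence level for the intervals.
#' @return A one-row data frame of class `triage_metrics` with columns
#'   `<metric>`, `<metric>_lo`, `<metric>_hi` and `n`.
#' @export
compute_metrics <- function(records, weights = default_time_weights(), conf = 0.95) {
  stopifnot(is.data.frame(records), all(c("assigned", "expected") %in% names(records)))
  n <- nrow(records)
  err <- classify_error(records$assigned, records$expected)
  prop <- function(x, d) wilson_ci(x, d, conf)
  out <- list(n = n)
  cls_counts <- table(factor(err, error_classes()))
  add <- function(name, ci) {
    out[[name]] <<- unname(ci[1]); out[[paste0(name, "_lo")]] <<- unname(ci[2])
    out[[paste0(name, "_hi")]] <<- unname(ci[3])
  }
  add("accuracy", prop(cls_counts[["OK"]], n))
  add("over_rate", prop(cls_counts[["OVER"]], n))
  add("under_rate", prop(cls_counts[["UNDER"]], n))
  add("critical_over_rate", prop(cls_counts[["CRITICAL_OVER"]], n))
  add("critical_under_rate", prop(cls_counts[["CRITICAL_UNDER"]], n))
  pos <- records$expected == "RED"
  add("sensitivity", prop(sum(records$assigned[pos] == "RED"), sum(pos)))
  add("specificity", prop(sum(records$assigned[!pos] != "RED"), sum(!pos)))
  if (all(c("airway_indicated", "airway_performed") %in% names(records))) {
    add("airway_accuracy",
        prop(sum(records$airway_indicated == records$airway_performed), n))
  }
  if (all(c("bleeding_indicated", "bleeding_performed") %in% names(records))) {
    add("bleeding_accuracy",
        prop(sum(records$bleeding_indicated == records$bleeding_performed), n))
  }
  if ("time_s" %in% names(records)) {
    add("mean_time_s", t_ci(records$time_s, conf))
    wt <- weighted_time_records(records, weights, conf)
    add("weighted_time_s", wt)
  }
  structure(as.data.frame(out), class = c("triage_metrics", "data.frame"))
}

#' Category-weighted mean triage time
#'
#' Because urgent categories take longer to triage and training vignette
#' pools deliberately over-represent RED and YELLOW patients, raw mean
#' times are re-weighted to a realistic casualty distribution before
#' comparison between sessions. The default distribution is 20% red,
#' 20% yellow, 60% green (dead patients carry no weight).
#'
#' @param mean_time_by_category named numeric vector of per-category mean
#'   times (seconds), names among the triage categories.
#' @param weights named numeric weights summing to 1.
#' @return Weighted mean time in seconds.
#' @export
#' @examples
#' weighted_time(c(RED = 50, YELLOW = 40, GREEN = 20, DEAD = 10))  # 30
weighted_time <- function(mean_time_by_category, weights = default_time_weights()) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  assert_category(names(weights))
  active <- names(weights)[weights > 0]
  missing <- active[!active %in% names(mean_time_by_category) |
                      is.na(mean_time_by_category[active])]
  if (length(missing) > 0L) {
    stop("no mean time for weighted category: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(weights[active] * mean_time_by_category[active])
}

#' @rdname weighted_time
#' @return `default_time_weights()`: the assumed realistic MCI casualty
#'   distribution, `c(RED = 0.2, YELLOW = 0.2, GREEN = 0.6, DEAD = 0)`.
#' @export
default_time_weights <- function() c(RED = 0.2, YELLOW = 0.2, GREEN = 0.6, DEAD = 0)

# weighted time over records with a per-record CI via the delta of
# independent per-category t intervals (variance of the weighted sum)
weighted_time_records <- function(records, weights, conf = 0.95) {
  # weight by the resulting (assigned) category: triage duration depends on
  # what the team concluded, not on the consented solution
  by_cat <- split(records$time_s, factor(records$assigned, triage_categories()))
  means <- vapply(by_cat, function(x) mean(x), numeric(1))
  est <- weighted_time(means, weights)
  active <- names(weights)[weights > 0]
  vars <- vapply(by_cat[active], function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::var(x) / length(x)
  }, numeric(1))
  se <- sqrt(sum(weights[active]^2 * vars))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(estimate = est, lower = est - z * se, upper = est + z * se)
}

#' Ten-item triage performance score
#'
#' Team performance is rated per procedure on a binary checklist: six
#' items while leading (correct role behavior, explicit communication,
#' correct bleeding-control indication, correct airway-control
#' indication, correct triage category, correct triage labeling) and
#' four while assisting (correct role behavior, explicit communication,
#' compliance to algorithm steps, correct documentation). Each fulfilled
#' item scores one point. Over a 20-procedure session with a role switch
#' after ten patients, a provider can score at most
#' 10 x 6 + 10 x 4 = 100 points; 90 or more qualifies the provider.
#'
#' `performance_sheet()` extracts one provider's sheet from a record
#' set; `score_performance()` sums it.
#'
#' @param sheet a data frame with a `role` column (`"LEADER"` or
#'   `"ASSISTANT"`) and logical criterion columns: the six
#'   `leader_criteria()` filled on LEADER rows and the four
#'   `assistant_criteria()` on ASSISTANT rows.
#' @param rescale if `TRUE` and the sheet does not hold the regular 10
#'   leader + 10 assistant rows, the score is rescaled to the 100-point
#'   ceiling; by default the raw sum is returned with a warning.
#' @return Integer score in `0..100` (raw points unless `rescale`).
#' @export
score_performance <- function(sheet, rescale = FALSE) {
  stopifnot(is.data.frame(sheet), "role" %in% names(sheet))
  lead <- sheet[sheet$role == "LEADER", leader_criteria(), drop = FALSE]
  asst <- sheet[sheet$role == "ASSISTANT", assistant_criteria(), drop = FALSE]
  pts <- sum(as.matrix(lead)) + sum(as.matrix(asst))
  regular <- nrow(lead) == 10L && nrow(asst) == 10L
  if (!regular) {
    if (rescale) {
      max_pts <- 6L * nrow(lead) + 4L * nrow(asst)
      if (max_pts == 0L) stop("empty performance sheet", call. = FALSE)
      return(100 * pts / max_pts)
    }
    warning(sprintf("irregular sheet (%d leader / %d assistant rows); raw score returned",
                    nrow(lead), nrow(asst)), call. = FALSE)
  }
  as.integer(pts)
}

#' @rdname score_performance
#' @export
leader_criteria <- function() {
  c("role_behavior", "communication", "bleeding_indication",
    "airway_indication", "triage_category", "triage_labeling")
}

#' @rdname score_performance
#' @export
assistant_criteria <- function() {
  c("role_behavior", "communication", "algorithm_compliance", "documentation")
}

#' @rdname score_performance
#' @param records a triage record data frame (see [simulate_session()]).
#' @param provider_id the provider whose sheet to assemble.
#' @export
performance_sheet <- function(records, provider_id) {
  lead <- records[records$leader_id == provider_id, , drop = FALSE]
  asst <- records[records$assistant_id == provider_id, , drop = FALSE]
  pick <- function(df, role, crits) {
    if (nrow(df) == 0L) {
      out <- as.data.frame(matrix(logical(0), 0, length(crits)))
      names(out) <- crits
    } else {
      prefix <- c(LEADER = "lead", ASSISTANT = "asst")[[role]]
      out <- df[, paste0(prefix, "_", crits), drop = FALSE]
      names(out) <- crits
    }
    all_crit <- union(leader_criteria(), assistant_criteria())
    for (m in setdiff(all_crit, crits)) out[[m]] <- NA
    cbind(role = rep(role, nrow(out)), out[all_crit])
  }
  rbind(pick(lead, "LEADER", leader_criteria()),
        pick(asst, "ASSISTANT", assistant_criteria()))
}

#' Provider scores and pass rate
#'
#' `provider_scores()` computes the performance score of every provider
#' appearing in a session's records; `pass_rate()` is the fraction of
#' scores at or above the qualification threshold, with a Wilson 95%
#' confidence interval.
#'
#' @param records session records (see [simulate_session()]).
#' @return `provider_scores()`: data frame `provider_id`, `score`.
#' @export
provider_scores <- function(records) {
  ids <- sort(unique(c(records$leader_id, records$assistant_id)))
  scores <- vapply(ids, function(p) {
    suppressWarnings(as.numeric(score_performance(performance_sheet(records, p))))
  }, numeric(1))
  data.frame(provider_id = ids, score = scores, stringsAsFactors = FALSE)
}

#' @rdname provider_scores
#' @param scores numeric vector of performance scores.
#' @param threshold qualification threshold (default 90 points).
#' @param conf confidence level.
#' @return `pass_rate()`: named vector `c(estimate, lower, upper, n)`.
#' @export
pass_rate <- function(scores, threshold = 90, conf = 0.95) {
  if (length(scores) == 0L) stop("no scores supplied", call. = FALSE)
  ci <- wilson_ci(sum(scores >= threshold), length(scores), conf)
  c(ci, n = length(scores))
}

#' Probability that a team retains at least one qualified member
#'
#' For a team of `k` providers who each still meet the qualification
#' criterion independently with probability `p`, the probability that at
#' least one member is qualified is `1 - (1 - p)^k`. With the 70%
#' pass-rate floor used as an early-stopping rule and two-person
#' ambulance teams this is `1 - 0.3^2 = 0.91`, i.e. about 90% of teams
#' keep a qualified member even at the stopping threshold.
#'
#' @param p individual qualification probability in `[0, 1]` (vectorised).
#' @param k team size (default 2).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' team_pass_probability(0.70)  # 0.91
team_pass_probability <- function(p, k = 2) {
  stopifnot(all(p >= 0 & p <= 1), k >= 1)
  1 - (1 - p)^k
}

#' Provider-averaged endpoint metrics
#'
#' Pooled-procedure rates (as in [compute_metrics()]) and means of
#' per-provider rates differ when providers contribute unequal numbers
#' of procedures; published session tables can mix the two readings.
#' This variant computes each provider's per-session rate first (from
#' the procedures they led) and averages across providers, with t-based
#' confidence intervals.
#'
#' @param records session records with a `leader_id` column.
#' @param conf confidence level.
#' @return one-row data frame: provider-averaged `accuracy`,
#'   `under_rate`, `critical_under_rate`, `over_rate`,
#'   `critical_over_rate` with `_lo`/`_hi` bounds, and `n_providers`.
#' @export
compute_metrics_by_provider <- function(records, conf = 0.95) {
  stopifnot("leader_id" %in% names(records))
  err <- classify_error(records$assigned, records$expected)
  per <- lapply(split(err, records$leader_id), function(e) {
    tab <- table(factor(e, error_classes()))
    tab / length(e)
  })
  mat <- do.call(rbind, per)
  out <- list(n_providers = nrow(mat))
  nm <- c(OK = "accuracy", OVER = "over_rate", UNDER = "under_rate",
          CRITICAL_OVER = "critical_over_rate", CRITICAL_UNDER = "critical_under_rate")
  for (cls in names(nm)) {
    ci <- t_ci(mat[, cls], conf)
    out[[nm[[cls]]]] <- unname(ci[1])
    out[[paste0(nm[[cls]], "_lo")]] <- unname(ci[2])
    out[[paste0(nm[[cls]], "_hi")]] <- unname(ci[3])
  }
  as.data.frame(out)
}
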
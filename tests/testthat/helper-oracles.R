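# Independent oracles and fixture builders shared across the suite.

# Literal 16-cell error table: rows = triaged as, cols = expected.
error_table_oracle <- function() {
  m <- matrix(c(
    # expected:  RED              YELLOW           GREEN            DEAD
    "OK",             "CRITICAL_OVER",  "CRITICAL_OVER", "CRITICAL_OVER",   # triaged RED
    "CRITICAL_UNDER", "OK",             "OVER",          "OVER",            # triaged YELLOW
    "CRITICAL_UNDER", "UNDER",          "OK",            "OVER",            # triaged GREEN
    "CRITICAL_UNDER", "UNDER",          "UNDER",         "OK"               # triaged DEAD
  ), nrow = 4, byrow = TRUE,
  dimnames = list(assigned = c("RED", "YELLOW", "GREEN", "DEAD"),
                  expected = c("RED", "YELLOW", "GREEN", "DEAD")))
  m
}

# Brute-force endpoint recount from raw record lists, written without
# reference to compute_metrics internals.
brute_force_metrics <- function(assigned, expected) {
  n <- length(assigned)
  ok <- sum(assigned == expected)
  tab <- error_table_oracle()
  cls <- vapply(seq_len(n), function(i) tab[assigned[i], expected[i]], character(1))
  tp <- sum(expected == "RED" & assigned == "RED")
  fn <- sum(expected == "RED" & assigned != "RED")
  tn <- sum(expected != "RED" & assigned != "RED")
  fp <- sum(expected != "RED" & assigned == "RED")
  list(
    accuracy = ok / n,
    over = sum(cls == "OVER") / n,
    under = sum(cls == "UNDER") / n,
    critical_over = sum(cls == "CRITICAL_OVER") / n,
    critical_under = sum(cls == "CRITICAL_UNDER") / n,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp))
}

# Hand-written interpretation of the shipped ASAV tree, kept deliberately
# independent of the engine's traversal code.
asav_oracle <- function(f) {
  interventions <- character(0)
  category <- NULL
  if (isTRUE(f$can_walk)) {
    category <- "GREEN"
  } else if (!isTRUE(f$spontaneous_breathing) &&
             !isTRUE(f$breathing_after_airway_opening)) {
    category <- "DEAD"
  } else if (!isTRUE(f$spontaneous_breathing)) {
    interventions <- "OROPHARYNGEAL_TUBE"
    category <- "RED"
  } else {
    if (isTRUE(f$severe_bleeding)) interventions <- "BLEEDING_CONTROL"
    if (f$respiratory_rate < 10 || f$respiratory_rate >= 30) {
      category <- "RED"
    } else if (!isTRUE(f$radial_pulse_palpable)) {
      category <- "RED"
    } else if (!isTRUE(f$obeys_commands)) {
      category <- "RED"
    } else {
      category <- "YELLOW"
    }
  }
  list(category = category, interventions = interventions)
}

# Full combination grid over the ASAV finding domains (numeric domains
# represented by one value per declared branch interval plus boundaries).
asav_finding_grid <- function() {
  expand.grid(
    can_walk = c(TRUE, FALSE),
    spontaneous_breathing = c(TRUE, FALSE),
    breathing_after_airway_opening = c(TRUE, FALSE),
    severe_bleeding = c(TRUE, FALSE),
    respiratory_rate = c(0, 5, 9, 10, 20, 29, 30, 45, 80),
    radial_pulse_palpable = c(TRUE, FALSE),
    obeys_commands = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
}

# A minimal two-leaf tree: walkable -> GREEN else RED.
two_leaf_spec <- function() {
  list(
    algorithm = "minimal",
    findings = list(can_walk = list(type = "logical")),
    root = "walk",
    nodes = list(
      walk = list(finding = "can_walk",
                  edges = list(list(value = TRUE, goto = "minor"),
                               list(value = FALSE, goto = "immediate"))),
      minor = list(leaf = "GREEN"),
      immediate = list(leaf = "RED")))
}

# Random record sets with all four categories represented in expectation.
random_records <- function(n) {
  lv <- c("RED", "YELLOW", "GREEN", "DEAD")
  data.frame(assigned = sample(lv, n, TRUE), expected = sample(lv, n, TRUE),
             stringsAsFactors = FALSE)
}

# A perfect provider: every skill probability 1, no decay.
perfect_provider <- function(id = "P001") {
  row <- data.frame(provider_id = id, qualification = "paramedic",
                    employment = "professional", stringsAsFactors = FALSE)
  for (s in skill_names()) row[[paste0("p_", s)]] <- 1
  row$decay_rate <- 0; row$floor <- 0; row$retrain_gain <- 0
  row
}
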
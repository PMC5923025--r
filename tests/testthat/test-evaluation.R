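test_that("error classification reproduces the full 16-cell taxonomy", {
  tab <- error_table_oracle()
  for (a in rownames(tab)) {
    for (e in colnames(tab)) {
      expect_equal(classify_error(a, e), tab[a, e], info = paste(a, "vs", e))
    }
  }
  # vectorised call agrees with the cell-wise one
  g <- expand.grid(a = rownames(tab), e = colnames(tab), stringsAsFactors = FALSE)
  expect_equal(classify_error(g$a, g$e), tab[cbind(g$a, g$e)])
  expect_error(classify_error("BLUE", "RED"), "invalid triage category")
})

test_that("the five error classes partition every record set (counts, not floats)", {
  set.seed(101)
  for (rep in 1:200) {
    rec <- random_records(sample(1:60, 1))
    cls <- classify_error(rec$assigned, rec$expected)
    expect_equal(sum(table(factor(cls, c("OK", "OVER", "UNDER", "CRITICAL_OVER",
                                         "CRITICAL_UNDER")))), nrow(rec))
    m <- compute_metrics(rec)
    expect_equal(m$accuracy + m$over_rate + m$under_rate +
                   m$critical_over_rate + m$critical_under_rate, 1)
  }
})

test_that("confusion table counts sum to n and diagonal matches accuracy", {
  set.seed(5)
  rec <- random_records(300)
  cm <- confusion(rec$assigned, rec$expected)
  expect_equal(sum(cm), 300)
  expect_equal(sum(diag(cm)) / 300, compute_metrics(rec)$accuracy)
})

test_that("metrics equal brute-force recounts on shuffled record lists", {
  set.seed(33)
  for (rep in 1:50) {
    rec <- random_records(sample(5:200, 1))
    rec <- rec[sample(nrow(rec)), ]
    m <- compute_metrics(rec)
    o <- brute_force_metrics(rec$assigned, rec$expected)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$over_rate, o$over)
    expect_equal(m$under_rate, o$under)
    expect_equal(m$critical_over_rate, o$critical_over)
    expect_equal(m$critical_under_rate, o$critical_under)
    expect_equal(m$sensitivity, o$sensitivity)
    expect_equal(m$specificity, o$specificity)
  }
})

test_that("sensitivity is NA (flagged), not zero, without expected-RED records", {
  rec <- data.frame(assigned = c("GREEN", "YELLOW"), expected = c("GREEN", "YELLOW"))
  m <- compute_metrics(rec)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
})

test_that("known counts give the expected sensitivity", {
  rec <- data.frame(assigned = c(rep("RED", 8), rep("GREEN", 2)),
                    expected = rep("RED", 10))
  expect_equal(compute_metrics(rec)$sensitivity, 0.8)
})

test_that("Wilson interval matches the score interval from prop.test", {
  for (case in list(c(8, 10), c(0, 15), c(15, 15), c(450, 990))) {
    got <- wilson_ci(case[1], case[2])
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(got[c("lower", "upper")]), as.numeric(ref), tolerance = 1e-8)
  }
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("intervention decision accuracy counts matches-to-indication", {
  rec <- data.frame(
    assigned = rep("RED", 4), expected = rep("RED", 4),
    airway_indicated  = c(TRUE, TRUE, FALSE, FALSE),
    airway_performed  = c(TRUE, FALSE, FALSE, TRUE),
    bleeding_indicated = c(TRUE, FALSE, FALSE, FALSE),
    bleeding_performed = c(TRUE, FALSE, FALSE, FALSE))
  m <- compute_metrics(rec)
  expect_equal(m$airway_accuracy, 0.5)
  expect_equal(m$bleeding_accuracy, 1)
})

test_that("performance score: ceiling 100, floor 0, and asymmetric role maxima", {
  full <- data.frame(role = rep(c("LEADER", "ASSISTANT"), each = 10))
  for (cr in union(leader_criteria(), assistant_criteria())) full[[cr]] <- TRUE
  expect_identical(score_performance(full), 100L)

  none <- full
  for (cr in union(leader_criteria(), assistant_criteria())) none[[cr]] <- FALSE
  expect_identical(score_performance(none), 0L)

  # perfect leader rows, nothing while assisting: 10 x 6
  half <- full
  half[half$role == "ASSISTANT", assistant_criteria()] <- FALSE
  expect_identical(score_performance(half), 60L)

  expect_length(leader_criteria(), 6L)
  expect_length(assistant_criteria(), 4L)
})

test_that("irregular sheets are flagged and only rescale on request", {
  sheet <- data.frame(role = rep("LEADER", 5))
  for (cr in union(leader_criteria(), assistant_criteria())) sheet[[cr]] <- TRUE
  expect_warning(raw <- score_performance(sheet), "irregular")
  expect_identical(raw, 30L)
  expect_equal(score_performance(sheet, rescale = TRUE), 100)
  expect_error(score_performance(sheet[0, ], rescale = TRUE), "empty")
})

test_that("pass rate thresholds at 90 points and rejects empty input", {
  expect_equal(unname(pass_rate(rep(100, 5))["estimate"]), 1)
  expect_equal(unname(pass_rate(c(95, 85))["estimate"]), 0.5)
  expect_equal(unname(pass_rate(c(90, 89.9))["estimate"]), 0.5)  # >= is inclusive
  expect_error(pass_rate(numeric(0)), "no scores")
})

test_that("team qualification probability follows 1 - (1-p)^k and is monotone", {
  expect_equal(team_pass_probability(0.70, 2), 0.91)
  expect_equal(team_pass_probability(1), 1)
  expect_equal(team_pass_probability(0), 0)
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(team_pass_probability(p, 2)) > 0))
  expect_true(all(team_pass_probability(0.4, 2:5) ==
                    cummax(team_pass_probability(0.4, 2:5))))
  expect_true(all(diff(team_pass_probability(0.4, 1:6)) > 0))
})

test_that("weighted time: convexity, defaults, and missing-category error", {
  expect_equal(weighted_time(c(RED = 30, YELLOW = 30, GREEN = 30, DEAD = 30)), 30)
  expect_equal(weighted_time(c(RED = 50, YELLOW = 40, GREEN = 20, DEAD = 10)), 30)
  expect_error(weighted_time(c(RED = 50, YELLOW = 40, DEAD = 10)), "GREEN")
  set.seed(2)
  for (rep in 1:25) {
    t_bar <- stats::setNames(runif(4, 10, 60), triage_categories())
    w <- weighted_time(t_bar)
    active <- names(default_time_weights())[default_time_weights() > 0]
    expect_gte(w, min(t_bar[active]))
    expect_lte(w, max(t_bar[active]))
  }
})
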
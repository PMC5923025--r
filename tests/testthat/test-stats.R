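test_that("session comparison: omnibus plus Bonferroni pairwise contrasts", {
  set.seed(1)
  d <- data.frame(session = rep(1:3, each = 50),
                  value = c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 2)))
  res <- compare_sessions(d, "value", "session")
  expect_equal(res$test, c("ANOVA", rep("ANOVA_BONFERRONI", 3)))
  expect_true(res$significant[res$contrast == "omnibus"])
  # with a 2-sd shift at n = 50 the (1,3) contrast has power > 0.99
  expect_true(res$significant[res$contrast == "3 vs 1"])
  expect_false(res$significant[res$contrast == "2 vs 1"])
  expect_equal(res$direction[res$contrast == "3 vs 1"], "improvement")
  res_bad <- compare_sessions(d, "value", "session", higher_better = FALSE)
  expect_equal(res_bad$direction[res_bad$contrast == "3 vs 1"], "decline")
})

test_that("Bonferroni-adjusted p-values are never below raw ones and cap at 1", {
  set.seed(2)
  for (rep in 1:20) {
    x <- rnorm(60)
    g <- factor(rep(1:3, each = 20))
    adj <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                                  pool.sd = TRUE)$p.value
    raw <- stats::pairwise.t.test(x, g, p.adjust.method = "none",
                                  pool.sd = TRUE)$p.value
    ok <- !is.na(adj)
    expect_true(all(adj[ok] >= raw[ok]))
    expect_true(all(adj[ok] <= 1))
  }
  # identical groups: every Bonferroni post-hoc p capped at 1
  d <- data.frame(session = rep(1:3, each = 10), value = rep(rep(c(1, 2), 5), 3))
  res <- compare_sessions(d, "value", "session")
  expect_true(all(res$p_value[res$test == "ANOVA_BONFERRONI"] == 1))
})

test_that("per-provider rates aggregate the procedures each provider led", {
  recs <- data.frame(
    session = c(1, 1, 1, 1),
    leader_id = c("A", "A", "B", "B"),
    assigned = c("RED", "GREEN", "RED", "RED"),
    expected = c("RED", "RED", "RED", "YELLOW"),
    stringsAsFactors = FALSE)
  acc <- provider_rates(recs, "accuracy")
  expect_equal(acc$value[acc$provider_id == "A"], 0.5)
  expect_equal(acc$value[acc$provider_id == "B"], 0.5)
  sens <- provider_rates(recs, "sensitivity")
  expect_equal(sens$value[sens$provider_id == "A"], 0.5)
  expect_equal(sens$value[sens$provider_id == "B"], 1)
  # provider with no expected-RED cases: sensitivity undefined, not zero
  recs2 <- data.frame(session = 1, leader_id = "C",
                      assigned = "GREEN", expected = "GREEN")
  expect_true(is.na(provider_rates(recs2, "sensitivity")$value))
})

test_that("provider-level comparison pairs providers and drops unmatched ones", {
  a <- data.frame(provider_id = c("A", "B", "C", "D"), score = c(95, 92, 88, 97))
  b <- data.frame(provider_id = c("A", "B", "C", "E"), score = c(85, 80, 78, 99))
  res <- compare_provider_level(a, b)
  expect_equal(res$n_pairs, 3)
  expect_equal(res$n_dropped, 2)
  tt <- res$comparisons[res$comparisons$test == "PAIRED_T", ]
  ref <- stats::t.test(c(85, 80, 78), c(95, 92, 88), paired = TRUE)
  expect_equal(tt$p_value, ref$p.value)
  expect_equal(tt$direction, "decline")
  ww <- res$comparisons[res$comparisons$test == "WILCOXON", ]
  expect_true(ww$p_value >= 0 && ww$p_value <= 1)
})

test_that("identical paired scores flag the t-test instead of crashing", {
  a <- data.frame(provider_id = c("A", "B", "C"), score = c(90, 95, 92))
  res <- compare_provider_level(a, a)
  tt <- res$comparisons[res$comparisons$test == "PAIRED_T", ]
  expect_true(is.na(tt$p_value))
  expect_false(tt$significant)
  ww <- res$comparisons[res$comparisons$test == "WILCOXON", ]
  expect_true(is.na(ww$p_value))   # all differences zero: undefined, flagged
})

test_that("Pratt signed-rank agrees with the classical test when no zeros exist", {
  set.seed(4)
  for (rep in 1:20) {
    d <- round(rnorm(25, 0.3), 2)
    d <- d[d != 0]
    got <- wilcoxon_pratt(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE, correct = TRUE))
    expect_equal(unname(got["statistic"]), unname(ref$statistic))
    expect_equal(unname(got["p_value"]), ref$p.value, tolerance = 1e-8)
  }
})

test_that("Pratt signed-rank keeps direction sensitivity with many zero differences", {
  # 12 improvements, 1 decline, 12 zeros: clearly one-sided evidence
  d <- c(rep(1, 12), -1, rep(0, 12))
  res <- wilcoxon_pratt(d)
  expect_lt(res[["p_value"]], 0.05)
  # symmetric evidence: no signal
  d2 <- c(rep(1, 6), rep(-1, 6), rep(0, 10))
  expect_gt(wilcoxon_pratt(d2)[["p_value"]], 0.5)
})

test_that("Shapiro-Wilk wrapper returns the base-R statistic", {
  set.seed(8)
  x <- rnorm(40)
  got <- normality_check(x)
  ref <- stats::shapiro.test(x)
  expect_equal(got[["statistic"]], unname(ref$statistic))
  expect_equal(got[["p_value"]], ref$p.value)
})

test_that("null rejection rates of all three tests sit near the nominal level", {
  # scaled-down version of the full calibration in the acceptance suite
  set.seed(10)
  n_rep <- 300
  alpha <- 0.05
  rej <- c(anova = 0, t = 0, wilcoxon = 0)
  for (r in seq_len(n_rep)) {
    g <- factor(rep(1:3, each = 30))
    x <- rnorm(90)
    rej["anova"] <- rej["anova"] +
      (summary(stats::aov(x ~ g))[[1]]$`Pr(>F)`[1] < alpha)
    d <- rnorm(30)
    rej["t"] <- rej["t"] + (stats::t.test(d)$p.value < alpha)
    rej["wilcoxon"] <- rej["wilcoxon"] + (wilcoxon_pratt(d)[["p_value"]] < alpha)
  }
  rates <- rej / n_rep
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_true(all(abs(rates - alpha) < 3 * se))
})
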
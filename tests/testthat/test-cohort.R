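test_that("vignette pool stores engine-derived ground truth and interventions", {
  tree <- asav_tree()
  pool <- generate_vignette_pool(n = 40, seed = 11)
  expect_equal(nrow(pool), 40)
  for (i in seq_len(nrow(pool))) {
    dec <- apply_algorithm(as.list(pool[i, ]), tree)
    expect_equal(dec$category, pool$ground_truth[i])
    expect_equal("OROPHARYNGEAL_TUBE" %in% dec$interventions, pool$airway_indicated[i])
    expect_equal("BLEEDING_CONTROL" %in% dec$interventions, pool$bleeding_indicated[i])
  }
  # the default mix over-represents RED and YELLOW
  mix <- default_category_mix()
  expect_gt(mix[["RED"]] + mix[["YELLOW"]], 0.5)
})

test_that("a point-mass GREEN pool is a single walkable vignette", {
  pool <- generate_vignette_pool(n = 1, category_mix = c(RED = 0, YELLOW = 0,
                                                        GREEN = 1, DEAD = 0),
                                 seed = 3)
  expect_equal(pool$ground_truth, "GREEN")
  expect_true(pool$can_walk)
})

test_that("pool generation is reproducible and unreachable categories error", {
  p1 <- generate_vignette_pool(n = 12, seed = 99)
  p2 <- generate_vignette_pool(n = 12, seed = 99)
  expect_identical(p1, p2)

  two_leaf <- build_tree(two_leaf_spec())  # cannot produce YELLOW
  expect_error(
    generate_vignette_pool(n = 2, category_mix = c(RED = 0, YELLOW = 1,
                                                   GREEN = 0, DEAD = 0),
                           tree = two_leaf, seed = 1, max_attempts = 25),
    "YELLOW.*not reached")
})

test_that("session draws are distinct, order-shuffled and seed-stable", {
  pool <- generate_vignette_pool(n = 40, seed = 2)
  s <- draw_session_vignettes(pool, k = 20, seed = 4)
  expect_equal(nrow(s), 20)
  expect_equal(anyDuplicated(s$vignette_id), 0)
  expect_identical(s, draw_session_vignettes(pool, k = 20, seed = 4))
  perm <- draw_session_vignettes(pool, k = 40, seed = 8)
  expect_setequal(perm$vignette_id, pool$vignette_id)
})

test_that("skill decay follows the closed-form exponential toward the floor", {
  r <- make_roster(1, seed = 6)
  r$decay_rate <- -log((0.75 - 0.5) / (0.9 - 0.5)) / 14.6
  r$floor <- 0.5
  for (s in skill_names()) r[[paste0("p_", s)]] <- 0.9

  expect_equal(unname(skill_at(r[1, ], 0)), rep(0.9, 8))            # dt = 0
  expect_equal(unname(skill_at(r[1, ], 14.6)), rep(0.75, 8),        # inverted analytically
               tolerance = 1e-12)
  expect_equal(unname(skill_at(r[1, ], 1e6)), rep(0.5, 8))          # floor is the limit

  r$decay_rate <- 0
  expect_equal(unname(skill_at(r[1, ], 120)), rep(0.9, 8))          # rate 0: constant
})

test_that("re-training resets skills toward (slightly above) the post-initial level", {
  r <- make_roster(1, seed = 6)
  for (s in skill_names()) r[[paste0("p_", s)]] <- 0.9
  r$decay_rate <- 0.05; r$floor <- 0.5; r$retrain_gain <- 0.02

  decayed <- skill_at(r[1, ], 12)
  expect_true(all(decayed < 0.9))
  refreshed <- skill_at(r[1, ], 12, retrain_months = 12)
  expect_equal(unname(refreshed), rep(0.92, 8))
  # decay after the re-training restarts from the refreshed level
  later <- skill_at(r[1, ], 18, retrain_months = 12)
  expect_equal(unname(later), rep(0.5 + 0.42 * exp(-0.05 * 6), 8), tolerance = 1e-12)
})

test_that("a perfect provider triages flawlessly and GREEN patients stay untagged", {
  tree <- asav_tree()
  skills <- skill_at(perfect_provider()[1, ], 0)
  pool <- generate_vignette_pool(n = 30, seed = 21)
  set.seed(1)
  for (i in seq_len(nrow(pool))) {
    rec <- simulate_procedure(skills, skills, pool[i, ], tree)
    expect_equal(rec$assigned, rec$expected)
    expect_equal(rec$error, "OK")
    expect_equal(rec$airway_performed, rec$airway_indicated)
    expect_equal(rec$bleeding_performed, rec$bleeding_indicated)
    crit <- unlist(rec[grep("^(lead|asst)_", names(rec))])
    expect_true(all(crit))
    if (rec$assigned == "GREEN") expect_true(is.na(rec$tag_applied))
    else expect_equal(rec$tag_applied, rec$assigned)
    expect_gt(rec$time_s, 0)
  }
})

test_that("zero categorization skill forces a wrong branch on a two-leaf tree", {
  tree <- build_tree(two_leaf_spec())
  skills <- skill_at(perfect_provider()[1, ], 0)
  skills["categorization_step"] <- 0
  vignette <- data.frame(vignette_id = "V1", can_walk = TRUE)
  set.seed(9)
  for (i in 1:25) {
    rec <- simulate_procedure(skills, skills, vignette, tree)
    expect_equal(rec$assigned, "RED")     # always the wrong leaf
    expect_equal(rec$error, "CRITICAL_OVER")
  }
})

test_that("observed accuracy recovers the per-procedure categorization probability", {
  tree <- asav_tree()
  pool <- generate_vignette_pool(n = 40, seed = 31)
  skills <- skill_at(perfect_provider()[1, ], 0)
  p <- 0.9
  skills["categorization_step"] <- p
  n <- 400
  set.seed(17)
  idx <- sample(nrow(pool), n, replace = TRUE)
  hits <- vapply(idx, function(i) {
    rec <- simulate_procedure(skills, skills, pool[i, ], tree,
                              error_model = "per_procedure")
    rec$assigned == rec$expected
  }, logical(1))
  expect_lt(abs(mean(hits) - p), 1.96 * sqrt(p * (1 - p) / n))
})

test_that("expected accuracy is non-increasing as skills decay (Monte Carlo)", {
  tree <- asav_tree()
  pool <- generate_vignette_pool(n = 40, seed = 41)
  r <- make_roster(1, seed = 5)
  for (s in skill_names()) r[[paste0("p_", s)]] <- 0.95
  r$decay_rate <- 0.04; r$floor <- 0.6
  acc <- vapply(c(0, 9, 18, 27), function(month) {
    skills <- skill_at(r[1, ], month)
    set.seed(month + 1)
    idx <- sample(nrow(pool), 1000, replace = TRUE)
    mean(vapply(idx, function(i) {
      rec <- simulate_procedure(skills, skills, pool[i, ], tree)
      rec$assigned == rec$expected
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(acc) < 0.02))   # non-increasing up to Monte-Carlo noise
})

test_that("sessions switch roles after half the vignettes", {
  pool <- generate_vignette_pool(n = 40, seed = 51)
  roster <- rbind(perfect_provider("A"), perfect_provider("B"))
  class(roster) <- c("provider_roster", "data.frame")
  teams <- data.frame(team_id = "T1", member1 = "A", member2 = "B")
  set.seed(3)
  recs <- simulate_session(teams, roster, pool, month = 0, k = 20)
  expect_equal(nrow(recs), 20)
  expect_equal(recs$leader_id, rep(c("A", "B"), each = 10))
  expect_equal(recs$assistant_id, rep(c("B", "A"), each = 10))
  # both members accumulate a full 10 + 10 sheet worth 100 points
  expect_identical(score_performance(performance_sheet(recs, "A")), 100L)
  expect_identical(score_performance(performance_sheet(recs, "B")), 100L)
})

test_that("identical config and seed reproduce the identical study", {
  cfg <- study_config(n_providers = 8, session_months = c(0, 12), retention = 0.9)
  s1 <- simulate_study(cfg, seed = 77)
  s2 <- simulate_study(cfg, seed = 77)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$sessions, s2$sessions)
  s3 <- simulate_study(cfg, seed = 78)
  expect_false(identical(s1$records, s3$records))
})

test_that("the inclusion rule keeps runs with a baseline-plus-follow-up member", {
  recs <- data.frame(
    session = c(1, 2, 2),
    leader_id = c("A", "A", "C"),
    assistant_id = c("B", "C", "D"),
    stringsAsFactors = FALSE)
  kept <- apply_inclusion_rule(recs)
  # A was at baseline and at a follow-up; C and D never saw the baseline
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$leader_id == "A"))
  expect_equal(n_providers_included(recs), 1)
})

test_that("the stop rule flags sessions whose pass rate falls below 70%", {
  sk <- default_skill_params()
  sk$decay_rate <- 0.12   # aggressive decay drives the follow-up below threshold
  cfg <- study_config(n_providers = 12, session_months = c(0, 14), retention = 1,
                      retrain_before_session = 99,  # i.e. never re-train
                      skill = sk)
  st <- simulate_study(cfg, seed = 13)
  expect_false(st$sessions$stop_flag[1])
  expect_true(st$sessions$stop_flag[2])
  expect_true(all(st$sessions$pass_rate >= 0 & st$sessions$pass_rate <= 1))
})
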
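#' Time model defaults
#'
#' Per-procedure triage time is drawn from a lognormal distribution
#' whose mean depends on the resulting triage category — urgent (RED,
#' YELLOW) patients take considerably longer than GREEN or DEAD ones.
#' Walking time between dummies is folded into the draw rather than
#' modelled separately. The two life-saving interventions (placing the
#' material on the dummy) consume no relevant time by default;
#' `intervention_s` adds a fixed cost per performed intervention if a
#' different setting is wanted.
#'
#' @return list with `mean` (named per-category mean seconds), `sdlog`
#'   (lognormal shape), `intervention_s` (seconds per performed
#'   intervention, default 0).
#' @export
default_time_params <- function() {
  list(mean = c(RED = 44, YELLOW = 40, GREEN = 18, DEAD = 16),
       sdlog = 0.35, intervention_s = 0)
}

# error-free traversal category from an arbitrary node
traverse_from <- function(id, vignette, tree) {
  repeat {
    node <- tree$nodes[[id]]
    if (!is.null(node$leaf)) return(node$leaf)
    id <- match_edge(node, vignette[[node$finding]], tree$findings[[node$finding]])$goto
  }
}

#' Simulate one triage procedure by a two-person team
#'
#' The team leader walks the decision tree on the vignette. Under the
#' default per-node error model the leader branches wrongly at each
#' decision node with a probability anchored at
#' `1 - p_categorization_step`; errors toward branches whose outcome is
#' less urgent than the ground truth are `1 + under_bias` times as
#' likely as errors toward more urgent branches, reproducing the
#' empirically higher share of under-triage. Interventions annotated on traversed nodes
#' are performed with probability `p_airway_indication` /
#' `p_bleeding_indication`. Under `error_model = "per_procedure"` the
#' whole categorisation is instead correct with probability
#' `p_categorization_step` (useful for parameter-recovery checks, where
#' observed accuracy should estimate that probability directly).
#'
#' Checklist criteria are sampled from the corresponding skill
#' probabilities of the current leader and assistant; the
#' category-dependent criteria (correct category, correct intervention
#' indications) are taken from the simulated outcome itself. Triage
#' time is drawn from the per-category lognormal time model.
#'
#' @param leader_skill,assistant_skill named skill probability vectors
#'   (see [skill_at()]).
#' @param vignette one vignette row (from [generate_vignette_pool()]).
#' @param tree a `triage_tree`.
#' @param error_model `"per_node"` (default) or `"per_procedure"`.
#' @param under_bias nonnegative; additional weight `1 + under_bias`
#'   on wrong branches leading to a less urgent category than the truth.
#' @param time_params see [default_time_params()].
#' @return one-row data frame: `vignette_id`, `expected`, `assigned`,
#'   `error`, intervention indication/performance flags, `tag_applied`,
#'   `time_s` and the ten checklist criterion columns (`lead_*`,
#'   `asst_*`).
#' @export
simulate_procedure <- function(leader_skill, assistant_skill, vignette, tree,
                               error_model = c("per_node", "per_procedure"),
                               under_bias = 1,
                               time_params = default_time_params()) {
  error_model <- match.arg(error_model)
  v <- as.list(vignette)
  truth <- apply_algorithm(v, tree)
  p_cat <- leader_skill[["categorization_step"]]

  if (error_model == "per_node") {
    walk <- walk_with_errors(v, tree, p_cat, under_bias, truth$category)
    assigned <- walk$category
    visited_iv <- walk$interventions
  } else {
    assigned <- if (stats::runif(1) < p_cat) {
      truth$category
    } else {
      wrong <- setdiff(triage_categories(), truth$category)
      w <- ifelse(category_urgency(wrong) < category_urgency(truth$category),
                  1 + under_bias, 1)
      sample(wrong, 1, prob = w)
    }
    visited_iv <- truth$interventions
  }

  perform <- function(code, p_name) {
    opportunity <- code %in% visited_iv
    if (error_model == "per_procedure") {
      indicated <- code %in% truth$interventions
      if (stats::runif(1) < leader_skill[[p_name]]) indicated else !indicated
    } else {
      opportunity && stats::runif(1) < leader_skill[[p_name]]
    }
  }
  airway_performed <- perform("OROPHARYNGEAL_TUBE", "airway_indication")
  bleeding_performed <- perform("BLEEDING_CONTROL", "bleeding_indication")

  labeling_ok <- stats::runif(1) < leader_skill[["labeling"]]
  tag <- if (labeling_ok) {
    if (assigned == "GREEN") NA_character_ else assigned
  } else {
    if (assigned == "GREEN") sample(c("RED", "YELLOW", "DEAD"), 1) else NA_character_
  }

  n_iv <- sum(airway_performed, bleeding_performed)
  mu <- time_params$mean[[assigned]]
  time_s <- stats::rlnorm(1, log(mu) - time_params$sdlog^2 / 2, time_params$sdlog) +
    n_iv * time_params$intervention_s

  data.frame(
    vignette_id = v$vignette_id %||% NA_character_,
    expected = truth$category,
    assigned = assigned,
    error = classify_error(assigned, truth$category),
    airway_indicated = "OROPHARYNGEAL_TUBE" %in% truth$interventions,
    airway_performed = airway_performed,
    bleeding_indicated = "BLEEDING_CONTROL" %in% truth$interventions,
    bleeding_performed = bleeding_performed,
    tag_applied = tag,
    time_s = time_s,
    lead_role_behavior = stats::runif(1) < leader_skill[["role_behavior"]],
    lead_communication = stats::runif(1) < leader_skill[["communication"]],
    lead_bleeding_indication = bleeding_performed == ("BLEEDING_CONTROL" %in% truth$interventions),
    lead_airway_indication = airway_performed == ("OROPHARYNGEAL_TUBE" %in% truth$interventions),
    lead_triage_category = assigned == truth$category,
    lead_triage_labeling = labeling_ok,
    asst_role_behavior = stats::runif(1) < assistant_skill[["role_behavior"]],
    asst_communication = stats::runif(1) < assistant_skill[["communication"]],
    asst_algorithm_compliance = stats::runif(1) < assistant_skill[["algorithm_compliance"]],
    asst_documentation = stats::runif(1) < assistant_skill[["documentation"]],
    stringsAsFactors = FALSE)
}

# tree walk where each decision node branches wrongly with prob 1 - p_cat
walk_with_errors <- function(v, tree, p_cat, under_bias, truth_category) {
  id <- tree$root
  interventions <- character(0)
  repeat {
    node <- tree$nodes[[id]]
    if (!is.null(node$intervention)) interventions <- union(interventions, node$intervention)
    if (!is.null(node$leaf)) return(list(category = node$leaf, interventions = interventions))
    correct <- match_edge(node, v[[node$finding]], tree$findings[[node$finding]])
    others <- Filter(function(e) !identical(e, correct), node$edges)
    if (length(others) == 0L) {
      id <- correct$goto
    } else {
      # errors toward less urgent outcomes are (1 + under_bias) times as
      # likely as errors toward more urgent ones
      nominal <- vapply(others, function(e) traverse_from(e$goto, v, tree), character(1))
      w <- ifelse(category_urgency(nominal) < category_urgency(truth_category),
                  1 + under_bias, 1)
      q_node <- min(1, (1 - p_cat) * mean(w))
      if (stats::runif(1) < q_node) {
        id <- others[[sample.int(length(others), 1, prob = w)]]$goto
      } else {
        id <- correct$goto
      }
    }
  }
}

#' Simulate one assessment session
#'
#' Each two-person team triages `k` vignettes drawn at random from the
#' pool; after `k/2` patients the members switch roles, so over a
#' standard 20-procedure session each provider leads 10 procedures and
#' assists in 10 — accumulating both leader and assistant checklist
#' criteria, as required by the 100-point performance score.
#'
#' @param teams data frame with columns `team_id`, `member1`, `member2`
#'   (provider ids present in `roster`).
#' @param roster a `provider_roster` (see [make_roster()]).
#' @param pool a `vignette_pool`.
#' @param month months since initial training.
#' @param retrain_months months of re-training events (see [skill_at()]).
#' @param tree a `triage_tree`.
#' @param k vignettes per team and session (even; default 20).
#' @param ... passed to [simulate_procedure()] (`error_model`,
#'   `under_bias`, `time_params`).
#' @return data frame of triage records, one row per procedure, with
#'   `team_id`, `leader_id`, `assistant_id`, `months_since_training`
#'   prepended to the [simulate_procedure()] columns.
#' @export
simulate_session <- function(teams, roster, pool, month, retrain_months = numeric(0),
                             tree = asav_tree(), k = 20, ...) {
  stopifnot(k %% 2 == 0)
  out <- vector("list", nrow(teams))
  for (t in seq_len(nrow(teams))) {
    m1 <- teams$member1[t]; m2 <- teams$member2[t]
    s1 <- skill_at(roster[roster$provider_id == m1, ], month, retrain_months)
    s2 <- skill_at(roster[roster$provider_id == m2, ], month, retrain_months)
    vign <- draw_session_vignettes(pool, k)
    recs <- vector("list", k)
    for (i in seq_len(k)) {
      first_leads <- i <= k / 2
      rec <- simulate_procedure(
        leader_skill = if (first_leads) s1 else s2,
        assistant_skill = if (first_leads) s2 else s1,
        vignette = vign[i, ], tree = tree, ...)
      rec <- cbind(
        data.frame(team_id = teams$team_id[t],
                   leader_id = if (first_leads) m1 else m2,
                   assistant_id = if (first_leads) m2 else m1,
                   months_since_training = month,
                   stringsAsFactors = FALSE),
        rec)
      recs[[i]] <- rec
    }
    out[[t]] <- do.call(rbind, recs)
  }
  do.call(rbind, out)
}

#' Default longitudinal study configuration
#'
#' The simulated study follows the yearly re-assessment design:
#' a 40-vignette pool with RED/YELLOW over-represented, an initial
#' cohort assessed right after training, a second assessment about 15
#' months later, and a third assessment immediately after a brief
#' re-training at about 25 months. Participation thins between sessions
#' (independent Bernoulli retention per provider). A stop rule flags
#' any session whose pass rate falls below 70%.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    tree = "asav",
    n_providers = 34,
    pool_size = 40,
    category_mix = default_category_mix(),
    session_months = c(0, 14.6, 25.1),
    retrain_before_session = 3,
    retention = c(0.67, 0.86),
    k_per_session = 20,
    skill = default_skill_params(),
    time = default_time_params(),
    error_model = "per_node",
    under_bias = 1,
    pass_threshold = 90,
    stop_threshold = 0.70,
    weights = default_time_weights(),
    alpha = 0.05)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L) stop("unknown study_config field(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  stopifnot(
    cfg$n_providers >= 2, cfg$pool_size >= cfg$k_per_session,
    abs(sum(cfg$category_mix) - 1) < 1e-8,
    length(cfg$retention) == length(cfg$session_months) - 1,
    all(cfg$retention >= 0 & cfg$retention <= 1),
    cfg$pass_threshold >= 0 && cfg$pass_threshold <= 100,
    cfg$stop_threshold >= 0 && cfg$stop_threshold <= 1,
    cfg$k_per_session %% 2 == 0)
  invisible(cfg)
}

#' Simulate a complete longitudinal triage study
#'
#' Generates the vignette pool and provider roster, then runs every
#' configured assessment session: providers are retained between
#' sessions with the configured probabilities, re-paired into new
#' two-person teams at each session, and re-trained before the
#' configured session. Records are pooled, the inclusion rule applied
#' (a triage run is kept only if at least one team member participated
#' in the baseline and in at least one follow-up), and per-session pass
#' rates and the early-stopping flag computed.
#'
#' All randomness flows from the single `seed`, so identical
#' configuration + seed reproduces the identical study.
#'
#' @param config a [study_config()].
#' @param seed integer master seed.
#' @return list of class `triage_study`: `config`, `pool`, `roster`,
#'   `sessions` (per-session summary with `n_teams`, `n1`, `pass_rate`,
#'   `stop_flag`), `records` (all), `records_included` (after the
#'   inclusion rule), `n1`, `n2`.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  validate_study_config(config)
  set.seed(seed)
  tree <- if (inherits(config$tree, "triage_tree")) config$tree else load_tree(config$tree)
  pool <- generate_vignette_pool(config$pool_size, config$category_mix, tree)
  roster <- make_roster(config$n_providers, config$skill)
  # retrain_before_session outside the session range means: never re-train
  retrain_months <- config$session_months[config$retrain_before_session]
  retrain_months <- retrain_months[!is.na(retrain_months)]

  active <- roster$provider_id
  all_records <- list()
  session_rows <- list()
  for (s in seq_along(config$session_months)) {
    month <- config$session_months[s]
    if (s > 1) {
      keep <- stats::runif(length(active)) < config$retention[s - 1]
      active <- active[keep]
      if (length(active) %% 2 == 1) active <- active[-sample.int(length(active), 1)]
      if (length(active) < 2) stop("roster collapsed before session ", s, call. = FALSE)
    }
    paired <- matrix(sample(active), ncol = 2)
    teams <- data.frame(team_id = sprintf("S%d_T%02d", s, seq_len(nrow(paired))),
                        member1 = paired[, 1], member2 = paired[, 2],
                        stringsAsFactors = FALSE)
    rm_here <- retrain_months[retrain_months <= month]
    recs <- simulate_session(teams, roster, pool, month, rm_here, tree,
                             k = config$k_per_session,
                             error_model = config$error_model,
                             under_bias = config$under_bias,
                             time_params = config$time)
    recs <- cbind(data.frame(session = s, stringsAsFactors = FALSE), recs)
    all_records[[s]] <- recs
    session_rows[[s]] <- data.frame(session = s, month = month,
                                    n_teams = nrow(teams),
                                    retrained = length(rm_here) > 0)
  }
  records <- do.call(rbind, all_records)
  included <- apply_inclusion_rule(records)
  sessions <- do.call(rbind, session_rows)
  sessions$n1 <- vapply(sessions$session,
                        function(s) sum(included$session == s), integer(1))
  sessions$pass_rate <- vapply(sessions$session, function(s) {
    sc <- provider_scores(records[records$session == s, ])
    unname(pass_rate(sc$score, config$pass_threshold)["estimate"])
  }, numeric(1))
  sessions$stop_flag <- sessions$pass_rate < config$stop_threshold
  structure(
    list(config = config, pool = pool, roster = roster, sessions = sessions,
         records = records, records_included = included,
         n1 = nrow(included), n2 = n_providers_included(records)),
    class = "triage_study")
}

#' Longitudinal inclusion rule
#'
#' A triage run is analyzed only if at least one of the two team
#' members participated in the baseline session and in at least one
#' follow-up session; `n_providers_included()` counts the providers who
#' themselves satisfy the rule (the N2 of a study dataset; the kept
#' record count is N1).
#'
#' @param records study records with `session`, `leader_id`,
#'   `assistant_id` columns (session 1 = baseline).
#' @return `apply_inclusion_rule()`: the qualifying subset of `records`.
#' @export
apply_inclusion_rule <- function(records) {
  q <- qualifying_providers(records)
  records[records$leader_id %in% q | records$assistant_id %in% q, , drop = FALSE]
}

#' @rdname apply_inclusion_rule
#' @export
n_providers_included <- function(records) length(qualifying_providers(records))

qualifying_providers <- function(records) {
  long <- rbind(data.frame(provider = records$leader_id, session = records$session),
                data.frame(provider = records$assistant_id, session = records$session))
  per <- split(long$session, long$provider)
  names(Filter(function(s) 1 %in% s && any(s > 1), per))
}

#' @export
print.triage_study <- function(x, ...) {
  cat(sprintf("<triage_study> %d sessions, N1 = %d included procedures, N2 = %d providers\n",
              nrow(x$sessions), x$n1, x$n2))
  print(x$sessions, row.names = FALSE)
  invisible(x)
}
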
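#' Generate a pool of simulated patient vignettes
#'
#' A vignette is a dummy description card: vital findings (ambulation,
#' breathing, respiratory rate, pulse status, response to commands,
#' severe bleeding) plus demographic colour (age, sex, pain level). The
#' generator samples findings from category-specific proposal
#' distributions and accepts a draw only when [apply_algorithm()] on the
#' target tree reproduces the target category (rejection sampling), so
#' the stored `ground_truth` is by construction the consented standard
#' solution under that tree, and the stored indicated interventions are
#' the decision's interventions.
#'
#' Training pools deliberately over-represent RED and YELLOW patients;
#' the default mix is 35% red, 35% yellow, 25% green, 5% dead.
#'
#' Every vignette carries a value for every declared finding (also on
#' branches its own path never tests, e.g. `breathing_after_airway_opening`
#' for a breathing patient), so a provider who errs onto a different
#' branch still finds a well-defined vignette value there.
#'
#' @param n pool size (the study design uses 40).
#' @param category_mix named probability vector over the four categories,
#'   summing to 1.
#' @param tree a `triage_tree`; defaults to the shipped ASAV tree.
#' @param seed integer seed for reproducibility.
#' @param max_attempts rejection-sampling bound per vignette; exceeding
#'   it means the requested category is (practically) unreachable under
#'   the tree.
#' @return data frame of class `vignette_pool`: one row per vignette
#'   with columns `vignette_id`, all finding keys, `age`, `sex`,
#'   `pain_level`, `ground_truth`, `airway_indicated`,
#'   `bleeding_indicated`.
#' @export
#' @examples
#' pool <- generate_vignette_pool(n = 6, seed = 1)
#' table(pool$ground_truth)
generate_vignette_pool <- function(n = 40,
                                   category_mix = default_category_mix(),
                                   tree = asav_tree(),
                                   seed = NULL,
                                   max_attempts = 1000L) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8)
  assert_category(names(category_mix))
  if (!is.null(seed)) set.seed(seed)
  targets <- sample(names(category_mix), n, replace = TRUE, prob = category_mix)
  rows <- lapply(seq_len(n), function(i) {
    sample_vignette(targets[i], tree, max_attempts, id = sprintf("V%02d", i))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vignette_pool", "data.frame")
  out
}

#' @rdname generate_vignette_pool
#' @export
default_category_mix <- function() c(RED = 0.35, YELLOW = 0.35, GREEN = 0.25, DEAD = 0.05)

# One vignette by rejection sampling toward a target category.
sample_vignette <- function(target, tree, max_attempts, id) {
  for (attempt in seq_len(max_attempts)) {
    f <- propose_findings(target)
    dec <- apply_algorithm(f, tree)
    if (dec$category == target) {
      return(data.frame(
        vignette_id = id,
        can_walk = f$can_walk,
        spontaneous_breathing = f$spontaneous_breathing,
        breathing_after_airway_opening = f$breathing_after_airway_opening,
        severe_bleeding = f$severe_bleeding,
        respiratory_rate = f$respiratory_rate,
        radial_pulse_palpable = f$radial_pulse_palpable,
        obeys_commands = f$obeys_commands,
        age = f$age, sex = f$sex, pain_level = f$pain_level,
        ground_truth = dec$category,
        airway_indicated = "OROPHARYNGEAL_TUBE" %in% dec$interventions,
        bleeding_indicated = "BLEEDING_CONTROL" %in% dec$interventions,
        stringsAsFactors = FALSE))
    }
  }
  stop("category `", target, "` not reached after ", max_attempts,
       " attempts; unreachable under tree `", tree$algorithm, "`?", call. = FALSE)
}

# Category-conditioned proposal distributions over the ASAV finding set.
# Values are clinically plausible for the target but the ground truth is
# always re-derived through the tree, never assumed.
propose_findings <- function(target) {
  f <- list(
    can_walk = FALSE,
    spontaneous_breathing = TRUE,
    breathing_after_airway_opening = TRUE,
    severe_bleeding = stats::runif(1) < 0.20,
    respiratory_rate = round(stats::runif(1, 12, 28)),
    radial_pulse_palpable = TRUE,
    obeys_commands = TRUE,
    age = sample(18:90, 1),
    sex = sample(c("F", "M"), 1),
    pain_level = sample(0:10, 1)
  )
  if (target == "GREEN") {
    f$can_walk <- TRUE
    f$respiratory_rate <- round(stats::runif(1, 12, 20))
    f$severe_bleeding <- FALSE
    f$pain_level <- sample(0:5, 1)
  } else if (target == "DEAD") {
    f$spontaneous_breathing <- FALSE
    f$breathing_after_airway_opening <- FALSE
    f$respiratory_rate <- 0
    f$radial_pulse_palpable <- FALSE
    f$obeys_commands <- FALSE
    f$pain_level <- 0
  } else if (target == "RED") {
    route <- sample(c("apnea_revivable", "resp_rate", "pulse", "consciousness"), 1)
    if (route == "apnea_revivable") {
      f$spontaneous_breathing <- FALSE
      f$breathing_after_airway_opening <- TRUE
      f$respiratory_rate <- round(stats::runif(1, 4, 9))
    } else if (route == "resp_rate") {
      f$respiratory_rate <- if (stats::runif(1) < 0.5) {
        round(stats::runif(1, 4, 9))
      } else {
        round(stats::runif(1, 31, 45))
      }
    } else if (route == "pulse") {
      f$radial_pulse_palpable <- FALSE
      if (stats::runif(1) < 0.5) f$obeys_commands <- FALSE
    } else {
      f$obeys_commands <- FALSE
    }
  }
  # YELLOW: the baseline proposal already walks the delayed path
  f
}

#' Draw the vignettes for one triage session
#'
#' Sessions present a random subset of the pool in random order: `k`
#' distinct vignettes drawn uniformly without replacement and shuffled
#' (the study design draws 20 out of 40).
#'
#' @param pool a `vignette_pool`.
#' @param k number of vignettes per session.
#' @param seed optional integer seed.
#' @return the selected pool rows in presentation order.
#' @export
draw_session_vignettes <- function(pool, k = 20, seed = NULL) {
  stopifnot(k <= nrow(pool))
  if (!is.null(seed)) set.seed(seed)
  pool[sample(nrow(pool), k, replace = FALSE), , drop = FALSE]
}

#' Build a provider roster with per-provider skill states
#'
#' Providers carry a qualification (`paramedic`, `EMT`, `other`), an
#' employment status (`professional`, `volunteer`) and a skill state:
#' one correct-execution probability per checklist skill
#' (`categorization_step`, `airway_indication`, `bleeding_indication`,
#' `documentation`, `labeling`, `role_behavior`, `communication`,
#' `algorithm_compliance`) plus decay parameters. Between-provider
#' heterogeneity is created on the logit scale by a provider-level
#' aptitude effect shared across all skills plus residual per-skill
#' jitter.
#'
#' @param n number of providers.
#' @param skill skill parameter list, see [default_skill_params()].
#' @param qualification_mix,employment_mix named probability vectors.
#' @param seed optional integer seed.
#' @return data frame of class `provider_roster`: `provider_id`,
#'   `qualification`, `employment`, one `p_<skill>` column per skill,
#'   `decay_rate`, `floor`, `retrain_gain`.
#' @export
make_roster <- function(n,
                        skill = default_skill_params(),
                        qualification_mix = c(paramedic = 0.58, EMT = 0.12, other = 0.30),
                        employment_mix = c(professional = 0.73, volunteer = 0.27),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n))
  out <- data.frame(
    provider_id = ids,
    qualification = sample(names(qualification_mix), n, TRUE, qualification_mix),
    employment = sample(names(employment_mix), n, TRUE, employment_mix),
    stringsAsFactors = FALSE)
  aptitude <- stats::rnorm(n, 0, skill$aptitude_sd)   # shared across skills
  for (s in skill_names()) {
    base <- skill$p0[[s]]
    out[[paste0("p_", s)]] <-
      stats::plogis(stats::qlogis(base) + aptitude + stats::rnorm(n, 0, skill$jitter_sd))
  }
  out$decay_rate <- skill$decay_rate
  out$floor <- skill$floor
  out$retrain_gain <- skill$retrain_gain
  class(out) <- c("provider_roster", "data.frame")
  out
}

#' @rdname make_roster
#' @export
skill_names <- function() {
  c("categorization_step", "airway_indication", "bleeding_indication",
    "documentation", "labeling", "role_behavior", "communication",
    "algorithm_compliance")
}

#' Default skill parameters
#'
#' Post-initial-training correct-execution probabilities per skill, the
#' exponential decay rate toward a residual floor, the skill gain of a
#' brief re-training, and the between-provider logit jitter. The
#' defaults are calibrated so that a simulated cohort reproduces the
#' decline-and-recovery trajectory typical of yearly triage
#' re-assessment: a mean performance score in the mid 90s and a pass
#' rate around 90% right after training, a pass rate around 50% some 15
#' months later, and recovery after re-training.
#'
#' @return list with elements `p0` (named per-skill probabilities),
#'   `decay_rate` (per month), `floor`, `retrain_gain`, `aptitude_sd`
#'   (between-provider effect shared across skills, logit scale) and
#'   `jitter_sd` (residual per-skill variation, logit scale).
#' @export
default_skill_params <- function() {
  list(
    p0 = c(categorization_step = 0.97, airway_indication = 0.96,
           bleeding_indication = 0.96, documentation = 0.97,
           labeling = 0.97, role_behavior = 0.97, communication = 0.97,
           algorithm_compliance = 0.97),
    decay_rate = 0.017,   # per month
    floor = 0.70,
    retrain_gain = 0.005,
    aptitude_sd = 0.60,   # provider-level effect shared across skills (logit scale)
    jitter_sd = 0.20      # residual per-skill variation (logit scale)
  )
}

#' Skill state at a given time since training
#'
#' Skills decay exponentially toward a residual floor:
#' `p(t) = floor + (p_train - floor) * exp(-rate * dt)` where `dt` is
#' the time since the most recent training event. A re-training event
#' resets each skill to its post-initial level plus `retrain_gain`
#' (capped at 1) — brief re-education can push performance slightly
#' above the initial level.
#'
#' @param provider one roster row (see [make_roster()]).
#' @param month assessment time in months since initial training.
#' @param retrain_months months at which re-training events occurred.
#' @return named numeric vector of current per-skill probabilities.
#' @export
#' @examples
#' r <- make_roster(1, seed = 1)
#' skill_at(r[1, ], month = 0)
#' skill_at(r[1, ], month = 12)
skill_at <- function(provider, month, retrain_months = numeric(0)) {
  p0 <- unlist(provider[paste0("p_", skill_names())])
  names(p0) <- skill_names()
  past <- retrain_months[retrain_months <= month]
  if (length(past) > 0L) {
    p_train <- pmin(1, p0 + provider$retrain_gain)
    dt <- month - max(past)
  } else {
    p_train <- p0
    dt <- month
  }
  fl <- provider$floor
  p <- pmax(fl, fl + (p_train - fl) * exp(-provider$decay_rate * dt))
  names(p) <- skill_names()
  p
}
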
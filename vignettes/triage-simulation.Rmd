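---
title: "Simulating and evaluating primary MCI triage performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating primary MCI triage performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagesim)
```

## The problem

At a mass casualty incident the first arriving EMS providers must sort
casualties into four urgency categories — RED (immediate), YELLOW
(delayed), GREEN (minor), DEAD — faster than they could ever examine
them properly. START-family triage protocols standardize this decision
as a small tree over findings any provider can assess in seconds:
can the patient walk, are they breathing (also after an airway-opening
maneuver), what is the respiratory rate, is a radial pulse palpable, do
they obey commands, is there severe external bleeding. Two life-saving
interventions are folded into the protocol: bleeding control and the
insertion of an oropharyngeal tube.

Triage skills decay in the months after a training course, and study
designs that re-assess providers yearly need three things this package
provides: an executable, configurable triage algorithm; a synthetic
cohort whose skill structure can decay and be refreshed; and the full
evaluation and statistics layer of such studies.

## The decision-tree engine

`load_tree()` reads a YAML document declaring finding domains, nodes,
branch predicates and leaf categories; `apply_algorithm()` executes it
deterministically on a vignette. Nothing clinical is hard-coded: the
shipped `asav.yaml` (the Amberg-Schwandorf Algorithm for Primary
Triage, a START-family derivative) and `start_demo.yaml` (classic
START) are both just data. That keeps every threshold — e.g. the
respiratory-rate band of 10–29/min that separates YELLOW from RED in
the shipped configuration — in one reviewable file, and lets the same
engine execute protocol variants.

Validation happens at load time, where it is cheap to explain:
cycles, unreachable nodes, references to undeclared findings, and
predicates that fail to partition a finding's domain are all rejected
with the offending node named. Because every internal node must cover
its finding's whole domain, traversal is total: any vignette that
carries a value for each finding reaches exactly one leaf.

Two numerical conventions matter. Numeric predicates are half-open
intervals `[min, max)`, with the interval touching the declared domain
maximum closed so the domain endpoint itself is classifiable.
Intervention annotations sit on nodes, not edges; a branch that implies
an intervention (e.g. "severe bleeding present") points to a node
carrying the annotation, so "performed interventions" are exactly the
annotations on the traversed path.

```{r tree}
tree <- asav_tree()
tree
apply_algorithm(list(can_walk = FALSE, spontaneous_breathing = FALSE,
                     breathing_after_airway_opening = TRUE), tree)
```

## The synthetic cohort

### Vignettes

`generate_vignette_pool()` emulates the written dummy description
cards of a moulage study: each vignette carries a complete set of vital
findings plus demographic colour, and a ground-truth category. The
generator proposes findings from category-conditioned distributions and
accepts a draw only when the tree itself reproduces the target category
— so the stored truth is derived, never asserted, and the pool
invariant `ground_truth == apply_algorithm(vignette, tree)$category`
holds by construction. Unreachable categories (e.g. YELLOW under a
two-leaf demonstration tree) fail loudly after a bounded number of
attempts.

The default pool holds 40 vignettes with a 35/35/25/5 RED/YELLOW/
GREEN/DEAD mix. Training collectives deliberately over-represent
urgent categories; the exact mix is a design choice of the pool, made
once here, and is configurable. Every vignette carries values even for
findings its own path never tests (a breathing patient still records
`breathing_after_airway_opening = TRUE`), so a provider who errs onto
another branch still finds a well-defined value there — this is what
makes the error model total.

Sessions draw 20 vignettes from the pool uniformly without replacement
and shuffle their order (`draw_session_vignettes()`).

### Providers and skill decay

A provider (`make_roster()`) carries one correct-execution probability
per checklist skill: `categorization_step`, `airway_indication`,
`bleeding_indication`, `documentation`, `labeling`, `role_behavior`,
`communication`, `algorithm_compliance`. Skills decay exponentially
toward a residual floor,

$$p_s(t) = \mathrm{floor} + (p_s^{\mathrm{train}} - \mathrm{floor})\,
  e^{-\lambda \, \Delta t},$$

with $\Delta t$ the months since the most recent training event. A
re-training event resets $p_s^{\mathrm{train}}$ to the post-initial
level plus a small `retrain_gain` (capped at 1) — brief re-education
can nudge performance slightly above the original level. The
exponential-toward-a-floor form is a single-rate parsimony choice: the
longitudinal designs this package emulates observe only two or three
time points, which cannot identify a richer retention curve; the floor
encodes that experienced EMS personnel do not decay to guessing.

Between-provider heterogeneity is modelled on the logit scale as a
provider-level aptitude effect shared across all skills plus residual
per-skill jitter. The shared component matters: independent per-skill
jitter alone averages out over the ten checklist items and produces an
implausibly homogeneous score distribution, while a common aptitude
term spreads provider-level scores the way real cohorts spread.

Default parameters (all in `default_skill_params()`, overridable per
study):

| parameter | default | unit | why |
|---|---|---|---|
| `p0` (most skills) | 0.96–0.97 | probability | fresh-after-training execution quality |
| `decay_rate` | 0.017 | per month | halves the above-floor surplus in ~3.4 years; see calibration below |
| `floor` | 0.70 | probability | residual competence without refreshment |
| `retrain_gain` | 0.005 | probability | re-training restores to slightly above initial |
| `aptitude_sd` | 0.60 | logit units | provider-level spread of scores |
| `jitter_sd` | 0.20 | logit units | residual per-skill variation |

### The error model

`simulate_procedure()` walks the tree as the team leader. Under the
default **per-node** model the leader branches wrongly at each decision
node with a probability anchored at $1 - p_{\mathrm{categorization}}$.
Errors are directional: a wrong branch whose (error-free) continuation
is *less* urgent than the ground truth is `1 + under_bias` times as
likely as one toward a *more* urgent outcome (default `under_bias = 1`,
i.e. twice as likely). Two properties motivated this design over a
simpler per-procedure coin flip:

* near-miss structure — erring at one node of a deep path usually lands
  in an adjacent category, so extreme confusions (DEAD for a walking
  patient) are rare, as observed in real cohorts;
* under/over asymmetry — START-family protocols are known to be prone
  to under-triage, and a uniform error model cannot produce that
  asymmetry. The bias acts on the per-node error probability, not only
  on the choice among wrong branches, because most nodes are binary
  and a choice-only bias would have nothing to choose between.

The alternative `error_model = "per_procedure"` makes the whole
categorisation correct with probability $p_{\mathrm{categorization}}$,
which is the model under which observed accuracy is an unbiased
estimate of that parameter — the parameter-recovery tests use it.

Intervention decisions are separate skills: an intervention annotated
on a traversed node is performed with probability
`p_airway_indication` / `p_bleeding_indication`; commission errors
arise naturally when a wrong branch leads through an intervention node.
Checklist criteria without an outcome anchor (role behavior,
communication, documentation, algorithm compliance, labeling) are
Bernoulli draws from the corresponding skill; the outcome-anchored
criteria (correct category, correct intervention indications) are taken
from the simulated outcome itself. Correct labeling means tagging the
patient with the assigned category's colour — and *not* tagging GREEN
patients, who receive no band.

### Time model

Per-procedure time is lognormal with a mean depending on the assigned
category (defaults 44/40/18/16 s for RED/YELLOW/GREEN/DEAD,
`sdlog = 0.35`), walking time between dummies folded in. Interventions
cost no relevant extra time by default (`intervention_s = 0`), matching
the simulate-by-placing-material convention of dummy studies; the cost
is configurable. Because training pools over-represent urgent patients,
session mean times are also reported re-weighted to a realistic 20%
red / 20% yellow / 60% green casualty distribution
(`weighted_time()`; DEAD carries weight 0 because cited field
distributions name no dead fraction).

### The study

`simulate_study()` ties it together: a roster of 34 providers (17
teams) is assessed at months 0, 14.6 and 25.1; retention between
sessions is independent Bernoulli per provider (defaults 0.67 then
0.86, thinning 34 → ~22 → ~19 as longitudinal EMS cohorts do); a brief
re-training precedes the third session; teams are re-paired at random
each session; within a 20-vignette session the two members swap roles
after ten patients, so each accumulates a full 6-item × 10 + 4-item ×
10 = 100-point sheet. The inclusion rule keeps a triage run only if at
least one team member participated in the baseline and in at least one
follow-up; N1 counts the retained procedures, N2 the qualifying
providers. A session whose provider pass rate (score ≥ 90) falls below
70% raises the early-stopping flag — the design's trigger for
premature re-training, chosen because even at that floor about
`r round(100 * team_pass_probability(0.70, 2))`% of two-person teams
(`team_pass_probability(0.70, 2)` = 0.91) still contain one qualified
member.

```{r study, eval = FALSE}
study <- simulate_study(study_config(), seed = 17)
study$sessions
#>  session month n_teams retrained  n1 pass_rate stop_flag
#>        1   0.0      17     FALSE 280 0.9411765     FALSE
#>        2  14.6      11     FALSE 220 0.5454545      TRUE
#>        3  25.1       8      TRUE 160 0.9375000     FALSE
```

### Calibration

The default skill parameters were fixed, once, so that the shipped
configuration reproduces the canonical decline-and-recovery trajectory
of yearly triage re-assessment: a mean performance score around 95 and
a pass rate near 0.9 right after training, a pass rate around 0.5 some
15 months later (firing the stop rule), and recovery to the initial
level after a brief re-training, with categorisation accuracy moving
roughly 0.85 → 0.7 → 0.9 and under-triage exceeding over-triage
throughout. They are defaults of a simulator, not estimates: only the
trajectory's shape, not any individual parameter, is identified by
data of this design.

## The evaluation layer

`classify_error()` implements the five-class taxonomy that partitions
all 16 (assigned, expected) pairs: the diagonal is OK; any RED
assignment to a non-RED patient is CRITICAL_OVER; any missed RED
patient is CRITICAL_UNDER; remaining more-urgent assignments are OVER,
less-urgent ones UNDER. Because the five classes are mutually
exclusive cells, accuracy plus the four error rates sums to exactly 1
on counts — the package adopts this cell-partition reading, under
which "under-triage" excludes the critical cells. Published tables
sometimes print rates that cannot satisfy this identity (provider-level
averaging is one cause), so `compute_metrics_by_provider()` offers the
provider-averaged variant alongside the pooled one.

Sensitivity and specificity are reported for RED patients, with all
non-RED categories (YELLOW, GREEN and DEAD) as negatives. With no
expected-RED records, sensitivity is undefined and reported `NA`, never
0. Proportions carry Wilson score intervals and means t-based
intervals — a deliberate choice where a source reports "mean and 95%
confidence intervals" without naming a method, because Wilson behaves
sensibly at the small per-session denominators involved.

`score_performance()` sums the ten-item checklist (max 6 points per
procedure leading, 4 assisting; 100 over a standard session). Sheets
with irregular role coverage are flagged and only rescaled to the
100-point ceiling on explicit request, so a partial sheet can never
silently pass the 90-point qualification threshold.

## The statistics layer

Procedure-level endpoints are compared across sessions by one-way
ANOVA with Bonferroni post-hoc pairwise t-tests (pooled SD,
`compare_sessions()`). The default unit of analysis is the
per-provider rate within a session (`provider_rates()`), not the raw
per-procedure Bernoulli outcome: procedures by the same provider are
correlated, and treating them as independent overstates evidence. The
raw-procedure mode remains available for sensitivity analyses.

Provider-level endpoints use paired tests on providers present in both
sessions (`compare_provider_level()`): a paired t-test on scores and a
Wilcoxon signed-rank test on the binary pass indicator. Zero
differences dominate paired binary indicators, so the signed-rank test
uses Pratt's treatment — zeros are ranked, then their ranks dropped
from the statistic — with a normal approximation including tie, zero
and continuity corrections (`wilcoxon_pratt()`); the classical
drop-zeros-first procedure would discard most of the sample. All
paired differences being zero yields a flagged `NA`, not a crash.
Shapiro-Wilk (`normality_check()`) screens score distributions before
the parametric test. Significance is declared at α = 0.05 throughout.

## What the simulation does and does not show

The generator emulates the *structure* of a dummy-based longitudinal
triage study: consented ground truths, role switching, skill decay and
refreshment, loss to follow-up, category-dependent timing. It does not
model cognitive processes (anchoring, fatigue, case-order effects),
team communication beyond the checklist booleans, assessor
disagreement (a single consensus rating is emitted), re-test effects,
or vignette difficulty heterogeneity. Passing tests therefore
demonstrate that the pipeline's arithmetic and statistics behave as
specified under a faithful synthetic cohort — not that any real cohort
decays at the default rate.

Test problem sizes were chosen to make Monte-Carlo checks sharp but
quick: 1000 procedures per point for accuracy-recovery and
monotone-decay checks, 1000 replicates for the type-I-error
calibration of the three tests, and three replicate studies for the
end-to-end trajectory check.
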
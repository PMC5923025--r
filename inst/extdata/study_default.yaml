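# Default longitudinal study configuration: yearly re-assessment of
# primary triage skills with a brief re-training before the third
# session. Values mirror study_config() defaults; edit and load with
# read_study_config().
tree: asav
n_providers: 34
pool_size: 40
category_mix: {RED: 0.35, YELLOW: 0.35, GREEN: 0.25, DEAD: 0.05}
session_months: [0.0, 14.6, 25.1]
retrain_before_session: 3
retention: [0.67, 0.86]
k_per_session: 20
skill:
  p0:
    categorization_step: 0.97
    airway_indication: 0.96
    bleeding_indication: 0.96
    documentation: 0.97
    labeling: 0.97
    role_behavior: 0.97
    communication: 0.97
    algorithm_compliance: 0.97
  decay_rate: 0.017      # per month, toward `floor`
  floor: 0.70
  retrain_gain: 0.005    # added to p0 by a re-training event
  aptitude_sd: 0.60      # provider-level logit effect shared across skills
  jitter_sd: 0.20        # residual per-skill logit variation
time:
  mean: {RED: 44, YELLOW: 40, GREEN: 18, DEAD: 16}   # seconds
  sdlog: 0.35
  intervention_s: 0      # life-saving interventions cost no relevant time
error_model: per_node
under_bias: 1            # wrong branches favour less urgent outcomes
pass_threshold: 90
stop_threshold: 0.70
weights: {RED: 0.2, YELLOW: 0.2, GREEN: 0.6, DEAD: 0.0}
alpha: 0.05
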
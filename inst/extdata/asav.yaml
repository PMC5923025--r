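# Amberg-Schwandorf Algorithm for Primary Triage (ASAV) — a START-family
# primary triage tree. Transcribed into the data-driven engine schema;
# every clinical threshold is here, not in code. Leaf categories:
# RED = immediate (I), YELLOW = delayed (II), GREEN = minor (III), DEAD = black.
algorithm: ASAV
findings:
  can_walk:                        {type: logical}   # ambulatory on request
  spontaneous_breathing:           {type: logical}
  breathing_after_airway_opening:  {type: logical}   # after head tilt / chin lift
  severe_bleeding:                 {type: logical}   # life-threatening external bleeding
  respiratory_rate:                {type: numeric, min: 0, max: 80}  # breaths/min
  radial_pulse_palpable:           {type: logical}
  obeys_commands:                  {type: logical}   # follows simple commands
root: walk
nodes:
  walk:
    finding: can_walk
    edges:
      - {value: true,  goto: minor}
      - {value: false, goto: breathing}
  breathing:
    finding: spontaneous_breathing
    edges:
      - {value: false, goto: airway_opened}
      - {value: true,  goto: bleeding}
  airway_opened:
    finding: breathing_after_airway_opening
    edges:
      - {value: false, goto: dead}
      - {value: true,  goto: airway_secured}
  airway_secured:                  # resumed breathing: insert tube, immediate
    intervention: OROPHARYNGEAL_TUBE
    leaf: RED
  bleeding:
    finding: severe_bleeding
    edges:
      - {value: true,  goto: resp_rate_after_bleeding_control}
      - {value: false, goto: resp_rate}
  resp_rate_after_bleeding_control:   # same respiratory-rate test, after bleeding control
    intervention: BLEEDING_CONTROL
    finding: respiratory_rate
    edges:
      - {min: 0,  max: 10, goto: immediate}
      - {min: 10, max: 30, goto: pulse}
      - {min: 30, max: 80, goto: immediate}
  resp_rate:
    finding: respiratory_rate
    edges:
      - {min: 0,  max: 10, goto: immediate}
      - {min: 10, max: 30, goto: pulse}
      - {min: 30, max: 80, goto: immediate}
  pulse:
    finding: radial_pulse_palpable
    edges:
      - {value: false, goto: immediate}
      - {value: true,  goto: consciousness}
  consciousness:
    finding: obeys_commands
    edges:
      - {value: false, goto: immediate}
      - {value: true,  goto: delayed}
  minor:     {leaf: GREEN}
  immediate: {leaf: RED}
  delayed:   {leaf: YELLOW}
  dead:      {leaf: DEAD}
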
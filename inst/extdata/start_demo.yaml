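# Classic START (Simple Triage and Rapid Treatment) — demonstration
# configuration showing the engine is algorithm-agnostic. Uses the
# historical respiratory-rate cut-off (> 30/min) and capillary refill.
algorithm: START
findings:
  can_walk:                        {type: logical}
  spontaneous_breathing:           {type: logical}
  breathing_after_airway_opening:  {type: logical}
  respiratory_rate:                {type: numeric, min: 0, max: 80}
  capillary_refill_s:              {type: numeric, min: 0, max: 10}
  obeys_commands:                  {type: logical}
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
      - {value: true,  goto: resp_rate}
  airway_opened:
    finding: breathing_after_airway_opening
    edges:
      - {value: false, goto: dead}
      - {value: true,  goto: immediate}
  resp_rate:
    finding: respiratory_rate
    edges:
      - {min: 0,  max: 30, goto: perfusion}
      - {min: 30, max: 80, goto: immediate}
  perfusion:
    finding: capillary_refill_s
    edges:
      - {min: 0, max: 2,  goto: consciousness}
      - {min: 2, max: 10, goto: immediate}
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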
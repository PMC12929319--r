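# Toy additive EQ-5D-3L value set for examples and tests.
# This is NOT a published tariff; real tariffs must be supplied by the user.
full_health: 1.0
any_problem: 0.05
any_level3: 0.0
decrements:
  mobility:           [0.10, 0.30]
  self_care:          [0.08, 0.25]
  usual_activities:   [0.06, 0.20]
  pain_discomfort:    [0.09, 0.30]
  anxiety_depression: [0.07, 0.23]
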
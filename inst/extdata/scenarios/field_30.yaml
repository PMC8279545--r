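# Packaged E = 30 kcal/(mol A e) scenario: the field restricts the peptide to
# a single dominant extended state (stationary probability 0.995) with a most
# probable d_ee of 8.9 A. A minor compact state carries the remaining 0.5%.
name: field_30
field: 30
ladder: [310.00, 315.38, 320.82, 326.35, 331.96, 337.64,
         343.41, 349.26, 355.19, 361.20, 367.30, 373.45]
ref_temp: 310.0
states:
  emission_mean: [5.0, 8.9]
  emission_sd:   [0.5, 0.5]
rates:
  - {from: 1, to: 2, rate: 0.05,                  ea: 2.0}
  - {from: 2, to: 1, rate: 0.0002512562814070352, ea: 2.0}
energy:
  u0: -11000.0
  slope: null
  sigma: 50.0
  target_acceptance: 0.20
  artifact_offset: 300.0
  artifact_mix: 0.35
  artifact_tau: 100.0
field_state: 2           # the field-stabilised extended state
artifact_mode: false
affected_replicas: [1, 2]
exchange_interval: 1.0
frame_interval: 1.0
production_ns: 100
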
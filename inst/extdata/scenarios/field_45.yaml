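# Packaged E = 45 kcal/(mol A e) scenario: single dominant extended state,
# most probable d_ee 10.0 A (slightly longer than at E = 30).
name: field_45
field: 45
ladder: [310.00, 315.38, 320.82, 326.35, 331.96, 337.64,
         343.41, 349.26, 355.19, 361.20, 367.30, 373.45]
ref_temp: 310.0
states:
  emission_mean: [5.0, 10.0]
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
field_state: 2
artifact_mode: false
affected_replicas: [1, 2]
exchange_interval: 1.0
frame_interval: 1.0
production_ns: 98
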
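# Packaged zero-field REMD scenario: 3 metastable conformational states on
# the d_ee axis with stationary populations 0.38 / 0.42 / 0.20 at 310 K.
# Equal activation energies keep the stationary distribution
# temperature-invariant across the ladder.
name: zero_field
field: 0
ladder: [310.00, 315.38, 320.82, 326.35, 331.96, 337.64,
         343.41, 349.26, 355.19, 361.20, 367.30, 373.45]
ref_temp: 310.0
states:
  emission_mean: [5.0, 8.9, 11.0]   # Angstrom
  emission_sd:   [0.5, 0.5, 0.5]
rates:                               # 1/ps at ref_temp; detailed balance with
  - {from: 1, to: 2, rate: 0.012,                ea: 2.0}   # p = (0.38, 0.42, 0.20)
  - {from: 2, to: 1, rate: 0.010857142857142857, ea: 2.0}
  - {from: 2, to: 3, rate: 0.008,                ea: 2.0}
  - {from: 3, to: 2, rate: 0.0168,               ea: 2.0}
energy:
  u0: -11000.0          # kcal/mol at the lowest temperature
  slope: null           # calibrated at build time to target_acceptance
  sigma: 50.0           # kcal/mol, common width
  target_acceptance: 0.20
  artifact_offset: 300.0
  artifact_mix: 0.35
  artifact_tau: 100.0
field_state: null
artifact_mode: false
affected_replicas: [1, 2]
exchange_interval: 1.0   # ps
frame_interval: 1.0      # ps
production_ns: 126
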
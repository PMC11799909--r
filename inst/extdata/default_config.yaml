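# Default run configuration: TrueBeam-class machine limits, the standard
# complexity-scoring settings, head-and-neck gamma criteria (all at a 10%
# low-dose threshold) and a 95% confidence level.
machine_limits:
  max_gantry_speed: 4.8    # deg/s
  max_dose_rate: 600       # MU/min
  max_leaf_speed: 25       # mm/s
complexity:
  speed_range: [16, 20]    # mm/s
  accel_range: [160, 200]  # mm/s^2
  sas_thresholds: [1, 2, 5, 10]  # mm
  closed_tolerance: 0.5    # mm
  plan_aggregation: sum
gamma_criteria:
  - {dose_diff: 3, dta: 2, threshold: 10}
  - {dose_diff: 2, dta: 2, threshold: 10}
  - {dose_diff: 1, dta: 1, threshold: 10}
alpha: 0.05
prescription: 70           # Gy
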
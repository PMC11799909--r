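# Organ-at-risk dose-constraint protocol for head-and-neck VMAT plans
# (RTOG 0225/0615 style). All limits in Gy; comparisons are strict (<).
# Serial organs carry a D1% alternate ("1% of the volume receives less
# than ..."); the paired parotid rule passes when the mean dose is under
# 26 Gy or at least one side stays under 30 Gy. The lens limit is quoted
# clinically as a 6-15 Gy range; the permissive end is encoded here.
rules:
  - organ: Brain stem
    pattern: "brain.?stem"
    statistic: Dmax
    limit: 54
    alt_statistic: D1pct
    alt_limit: 60
  - organ: Chiasm
    pattern: "chiasm"
    statistic: Dmax
    limit: 54
    alt_statistic: D1pct
    alt_limit: 60
  - organ: Cochlea
    pattern: "cochlea"
    statistic: Dmean
    limit: 45
  - organ: Internal auditory canal
    pattern: "iac|auditory"
    statistic: Dmean
    limit: 45
  - organ: Eye
    pattern: "^eye|eye$|globe"
    statistic: Dmean
    limit: 35
  - organ: Lens
    pattern: "lens"
    statistic: Dmax
    limit: 15
  - organ: Optic nerve
    pattern: "optic.?nerve"
    statistic: Dmax
    limit: 54
    alt_statistic: D1pct
    alt_limit: 60
  - organ: Parotid
    pattern: "parotid"
    statistic: Dmean
    limit: 26
    alt_statistic: Dmean
    alt_limit: 30
    alt_scope: either_side
  - organ: Spinal cord
    pattern: "spinal.?cord|^cord"
    statistic: Dmax
    limit: 45
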
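---
title: "Methods: complexity, quality and QA metrics for VMAT plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity, quality and QA metrics for VMAT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planscope)
```

planscope evaluates volumetric-modulated arc therapy (VMAT) plans for
head-and-neck cancer along three axes: **deliverability** (multileaf
collimator complexity scores), **dosimetric quality** (DVH-derived target
and organ-at-risk metrics) and **measurement agreement** (2D gamma
analysis), plus paired statistics for comparing two planning approaches
(for example, manual versus automated knowledge-based planning) over a
patient cohort. This vignette documents the models, every free parameter
and the numerical decisions behind the implementation.

## Plan model and the segment-time reconstruction

A VMAT arc is a sequence of control points, each holding the gantry angle,
the cumulative meterset weight (fraction of the arc's monitor units, MU,
delivered so far) and the tip positions of both MLC leaf banks plus the
jaws (`control_point()`, `rt_beam()`, `rt_plan()`). Geometry follows
IEC 61217: leaf tips move along IEC-X, leaf strips are stacked along
IEC-Y, and the pair gap is `bank_b - bank_a`, which must be non-negative
up to a 0.01 mm interdigitation tolerance.

DICOM plans carry no timestamps, so per-segment delivery times are
reconstructed from the machine limits (`machine_limits()`; defaults are
TrueBeam-class: gantry 4.8 deg/s, dose rate 600 MU/min, leaf speed
25 mm/s). The duration of the segment between control points $i$ and
$i+1$ is the slowest of the three axes:

$$t_i = \max\!\left(\frac{|\Delta\theta_i|}{\dot\theta_{\max}},\;
\frac{\Delta \mathrm{MU}_i}{\dot D_{\max}},\;
\frac{\max_\ell |\Delta x_{i,\ell}|}{v_{\max}}\right)$$

with the gantry delta taken as the absolute shortest arc (so the model is
invariant to arc direction and to the 0/360 wrap). This is the standard
delivery-time model; it assumes each axis moves at its limiting speed
within a segment, which makes reconstructed speeds lower bounds on true
modulation but is the accepted convention when only the DICOM plan is
available.

## Complexity scores

Leaf **speed** for leaf $\ell$ over segment $i$ is
$|\Delta x_{i,\ell}|/t_i$; **acceleration** at interior control point $j$
is the absolute speed change between adjacent segments divided by the mean
of their durations. `fraction_in_range(values, lo, hi)` counts samples in
the half-open band $[lo, hi)$ over *all* leaf-segment samples, moving and
static alike. The headline bands reported per plan are 16–20 mm/s
(`LS_A16-20`, `LS_B16-20`, per bank) and 160–200 mm/s²
(`LA_A160-200`, `LA_B160-200`); full partitions (4 mm/s and 40 mm/s²
bins plus an overflow bin) are configurable via `complexity_config()`.

Aperture-shape scores are defined per control point and averaged over
segments with delta-MU weights (a segment's score is the mean of its two
bounding control points; `mu_weighted = FALSE` gives plain segment means):

- **MFA** (mean field area, mm²): sum over leaf pairs of the open gap
  clipped to the X jaws times the leaf width; pairs entirely outside the
  Y jaws are excluded.
- **CAS** (cross-axis score): fraction of leaves whose tip crosses the
  central axis (bank A tip strictly right of $x=0$ or bank B tip strictly
  left of it) out of $2 n_\text{pairs}$ leaves inside the Y jaws.
- **CLS** (closed leaf score): fraction of pairs with gap at most the
  closed tolerance (0.5 mm default).
- **SAS** (small aperture score, %): percentage of *open* pairs (gap above
  the closed tolerance) with gap below the threshold; thresholds 1, 2, 5
  and 10 mm are reported. A control point with no open pair contributes 0,
  a convention that keeps the score defined for fully-closed states.
- **MU/CP**: beam MU over control points; at plan level MU and control
  points are pooled (total over total), not averaged per beam.

Plan-level aggregation (`plan_aggregation`) defaults to `"sum"`:
CAS/CLS/SAS of a plan are the sums over its arcs, so 3–4-arc plans can
exceed 1 (or 100 % for SAS). This matches reporting conventions in the
automated-planning literature, where per-plan aperture scores scale with
the number of arcs; `"mu_weighted_mean"` is available to keep plan values
on the per-beam scale. MFA aggregates as the MU-weighted mean over beams,
and speed/acceleration fractions pool all leaf-segment samples across
beams.

## Dose metrics

Structures are planar contour stacks (`structure_set()`), rasterized on
the dose grid by even-odd ray casting of voxel centers against the
contour(s) of the nearest slice (within half a grid spacing); multiple
contours on one slice combine by the even-odd rule, so nested contours
produce holes (`rasterize_structure()`).

The cumulative DVH uses 0.01 Gy bins; `dose_at_volume()` returns the
largest dose received by at least the requested volume fraction, with
linear interpolation between bins ($D_{2}$, $D_{95}$, $D_{98}$,
$D_{1cc}$, ...). Derived scores:

- **Conformity number** $CN = \frac{PTV_{PD}}{PTV}\cdot
  \frac{PTV_{PD}}{PIV}$, where $PTV_{PD}$ is the target volume at or above
  the prescription and $PIV$ the irradiated (body) volume at or above it.
- **Heterogeneity index** $HI = (D_2 - D_{98}) / D_{50}$.
- **Hot spot**: maximum body dose as a percentage of the prescription,
  flagged when *strictly* above 110 %; the normalization scale
  `prescription / D95` is reported, not applied.

Organ-at-risk constraints are evaluated against a YAML protocol
(`hn_constraint_protocol()`); the shipped head-and-neck protocol encodes
serial-organ maximum-dose limits with $D_{1\%}$ alternates (brain stem,
chiasm, optic nerves: 54 Gy else $D_{1\%}<60$ Gy), mean-dose limits
(cochlea/auditory canal 45 Gy, eyes 35 Gy), lens maximum 15 Gy (the
permissive end of the clinically quoted 6–15 Gy range), spinal cord
maximum 45 Gy, and the paired-parotid rule: mean below 26 Gy, or at least
one side below 30 Gy (`alt_scope: either_side`). All comparisons are
strict (`<`), and structure matching is by case-insensitive regular
expression, so protocol rules for organs absent from a case are reported
as not evaluated rather than silently passed.

## Gamma analysis

`gamma_map()` implements the 2D global-normalization gamma index for
portal-dosimetry style QA. For each reference pixel at or above the
low-dose threshold (10 % of the maximum reference dose by default; pixels
below it are excluded from numerator *and* denominator of the passing
rate), the gamma value is the minimum over a search disc of

$$\gamma = \sqrt{\left(\frac{D_e(\mathbf{r}+\mathbf{s}) -
D_r(\mathbf{r})}{\Delta D}\right)^2 +
\left(\frac{|\mathbf{s}|}{\Delta d}\right)^2}$$

with $\Delta D$ a percentage of the maximum reference dose (global
normalization). The evaluated image is sampled by bilinear interpolation
on a sub-grid of step DTA/10 out to 3 DTA; offsets are visited in order of
increasing distance so the search can stop as soon as the distance term
alone exceeds every pixel's current minimum (exact, not approximate,
early termination). Both images must share the pixel grid; resampling
differing grids is out of scope. Reported criteria follow QA practice:
3 %/2 mm, 2 %/2 mm and 1 %/1 mm, summarized per criterion as max, min,
mean and SD over the cohort (`passing_rate_table()`).

## Paired statistics

`wilcoxon_signed_rank()` implements the two-sided Wilcoxon signed-rank
test with mid-ranks for ties. Zero differences are dropped by default
(Wilcoxon's convention; Pratt's method is available). For up to 25
nonzero differences the p-value is computed by exact enumeration of the
null distribution via a dynamic program over doubled ranks — unlike
`stats::wilcox.test()`, this stays exact in the presence of ties, which
matter here because paired complexity metrics are often quantized. Larger
samples use the normal approximation with tie-corrected variance
($\sigma^2 = \sum r_i^2/4$, which equals the textbook
$n(n+1)(2n+1)/24 - \sum(t^3-t)/48$) and a continuity correction.
`compare_cohorts()` applies the test per metric over patients paired
across exactly two cohorts, reports mean ± SD (min–max) summaries, and
deliberately applies no multiplicity correction (matching common practice
in planning-comparison studies; interpret accordingly). Metrics whose
paired differences are all exactly zero are reported as *not tested*
rather than given p = 1, since a deterministic recomputation of an
unchanged plan carries no evidence either way.

## Synthetic generators and ground truth

Every generator is a pure function of its seed.

`synth_plan()` builds arc plans whose aperture statistics are exact by
construction: each leaf pair receives a fixed role — closed (gap 0),
small (gap drawn strictly inside the closed-tolerance/threshold band) or
open (gap $\geq 1.2\times$ threshold) — and crossing pairs are confined
to one side of the axis with a 2 mm margin while non-crossing pairs
straddle it. Pair centers perform a bounded random walk with steps drawn
from the programmed speed range under the machine limits, so the realized
segment times equal the nominal gantry/dose-rate-limited time and leaf
speeds stay below the limit. Positions are quantized to 0.01 mm, weights
to $10^{-6}$ and gantry angles to $10^{-4}$ degrees — exactly the decimal
quanta of the DICOM writer — so a write/read round trip is bit-identical.
Per-tip rounding perturbs individual gaps by at most 0.01 mm, which the
role gap margins absorb, so CAS/CLS/SAS recovery is exact while MFA is
exact only up to the 0.01 mm write quantum.

`synth_case()` is a simultaneous-integrated-boost-like phantom: nested
spherical targets (25/35/45 mm), spherical OARs and a body sphere on a
regular grid, with a radial dose that ramps linearly from the hot spot at
the center to exactly the prescription at radius
$r_\mathrm{iso} = r_\mathrm{PTV}\,\mathrm{coverage}^{1/3}$ and falls off
as a Gaussian outside. The prescription isodose is therefore exactly a
sphere, giving closed-form CN (and closed-form HI at full coverage). Dose
values are pre-quantized to the writer's power-of-two `DoseGridScaling`
quantum, making the dose round trip lossless as well.

`synth_dose_pair()` produces gamma fixtures: a smooth three-lobe field as
reference, and an *analytically* shifted and scaled evaluated image (no
interpolation error in the pure-shift case) with optional correlated
noise. `synth_cohort()` draws paired metric tables at head-and-neck
scales; metrics without a programmed effect are carried over unchanged,
mimicking deterministic recomputation and making the expected
significance pattern exact.

## Numerical and I/O decisions

- **DICOM codec**: a minimal explicit-VR little-endian reader/writer
  (RT Plan, RT Dose, RT Structure Set) is implemented in-package; no R
  DICOM toolkit covering RT IOD sequence writing was available. Output is
  deterministic (stable element order, fixed-precision DS values,
  content-hashed UIDs), so rewriting a read plan is byte-stable.
- **Dose scaling**: RT Dose uses 16-bit pixels with a power-of-two
  `DoseGridScaling` written as an exact decimal, so quantized grids
  round-trip exactly and arbitrary grids are faithful to half a quantum
  (about 0.5 mGy at 70 Gy).
- **DVH resolution**: 0.01 Gy bins bound interpolation error on any
  $D_x$ by one bin.
- **Gamma interpolation**: bilinear sampling at DTA/10 steps; corners
  with zero bilinear weight are excluded so integer-pixel offsets remain
  valid at image borders.
- **Exactness testing**: the test suite validates each metric family
  against independent brute-force oracles (scalar-loop complexity scores,
  a fine-grid window-minimum gamma, full $2^n$ sign-flip enumeration for
  the signed-rank test) and against the analytic phantom values.

## Worked example

```{r example, eval = FALSE}
res <- synth_plan(seed = 1, n_arcs = 4)
report <- plan_complexity_report(res$plan)
report$per_plan[, c("CAS", "CLS", "SAS_1mm", "MFA", "MU_per_CP")]

case <- synth_case(seed = 1)
masks <- lapply(case$structures$structures, rasterize_structure,
                grid = case$grid)
conformity_number(case$grid, masks$PTV_high, 70, masks$BODY)
heterogeneity_index(cumulative_dvh(case$grid, masks$PTV_high))

pair <- synth_dose_pair(seed = 1, shift = c(1.5, 0))
gamma_map(pair$reference, pair$evaluated,
          gamma_criterion(3, 2))$passing_rate
```
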
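# planscope

Complexity, quality and QA analysis of VMAT radiotherapy plans.

planscope evaluates volumetric-modulated arc therapy (VMAT) treatment
plans for head-and-neck cancer along the three axes used when an
automated (knowledge-based) planning workflow is compared against manual
planning over a patient cohort:

- **Deliverability / MLC complexity** — per-beam and per-plan scores
  computed from the DICOM RT Plan alone: leaf-speed fractions
  (`LS 16–20 mm/s`) and leaf-acceleration fractions (`LA 160–200 mm/s²`)
  per bank, mean field area (`MFA`), cross-axis score (`CAS`), closed
  leaf score (`CLS`), small aperture scores (`SAS` at 1/2/5/10 mm) and
  MU per control point. Segment times are reconstructed from machine
  limits via the standard delivery-time model
  `t = max(Δθ/θ̇max, ΔMU/Ḋmax, max|Δx|/vmax)`.
- **Dosimetric quality** — DVH-based metrics from RT Dose + RT Structure
  Set: conformity number `CN = (PTV_PD/PTV)·(PTV_PD/PIV)`, heterogeneity
  index `HI = (D2 − D98)/D50`, hot spot (strict 110 % flag), D95
  normalization scale, and organ-at-risk statistics
  (Dmax/Dmean/D1cc/D1 %) evaluated against a YAML head-and-neck
  constraint protocol with alternates (e.g. the paired-parotid
  either-side rule).
- **Measurement QA** — 2D global-normalization gamma analysis
  (3 %/2 mm, 2 %/2 mm, 1 %/1 mm at a 10 % low-dose threshold) with
  per-criterion cohort summaries.

Paired cohorts are compared metric-by-metric with an exact two-sided
Wilcoxon signed-rank test (exact with ties, unlike
`stats::wilcox.test()`), and seeded synthetic generators provide plans,
dose/structure phantoms, gamma image pairs and metric cohorts with
analytic ground truth.

The package includes a minimal deterministic DICOM codec (explicit VR
little endian) for RT Plan / RT Dose / RT Structure Set, designed so that
its own generated files round-trip bit-identically.

## Worked example

```r
library(planscope)

# a seeded 4-arc plan with programmed aperture statistics
res <- synth_plan(seed = 1, n_arcs = 4)
res$plan
#> <rt_plan 'synth-1'>  4 beam(s), 70.0 Gy in 33 fx
#>   arc1: 178.0 MU, 178 control points, 60 leaf pairs (CW)
#>   arc2: 178.0 MU, 178 control points, 60 leaf pairs (CW)
#>   arc3: 178.0 MU, 178 control points, 60 leaf pairs (CW)
#>   arc4: 178.0 MU, 178 control points, 60 leaf pairs (CW)

report <- plan_complexity_report(res$plan)
round(report$per_plan[, c("CAS", "CLS", "SAS_1mm", "MFA", "MU_per_CP")], 3)
#>   CAS CLS SAS_1mm      MFA MU_per_CP
#> 1 1.2 0.8     200 3710.825         1

# DICOM round trip is lossless for generated plans
write_rtplan(res$plan, "plan.dcm")
identical(plan_complexity_report(read_rtplan("plan.dcm"))$per_plan,
          report$per_plan)
#> [1] TRUE

# gamma analysis of a sub-DTA shifted field
pair <- synth_dose_pair(seed = 1, shift = c(1.5, 0))
gamma_map(pair$reference, pair$evaluated,
          gamma_criterion(3, 2))$passing_rate
#> [1] 100

# paired cohort comparison: a CAS-only shift is the only significant metric
sc <- synth_cohort(1, effects = list(CAS = list(shift = 0.3, sd = 0.1)))
cmp <- compare_cohorts(sc$table)
cmp[cmp$metric == "CAS", c("metric", "mean_a", "mean_b", "p_value",
                           "significant")]
#>   metric   mean_a    mean_b      p_value significant
#> 6    CAS 1.179495 0.9012228 1.907349e-06        TRUE
```

End-to-end cohort runs go through `run_pipeline()` (manifest CSV of
patients, cohorts and DICOM/image paths) and `write_report_bundle()`; a
thin command-line wrapper lives in `inst/scripts/planscope.R`:

```sh
Rscript inst/scripts/planscope.R complexity --rtplan plan.dcm
Rscript inst/scripts/planscope.R run --manifest manifest.csv --out report/
```

## Documentation

The methods vignette (`vignettes/planscope-methods.Rmd`) documents the
models, all parameters and defaults, the synthetic generators' exactness
arguments, and the numerical/I/O design decisions.
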
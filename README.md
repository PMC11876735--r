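# prrtdose

Internal dosimetry and dose-response analysis for Lu-177 DOTATATE peptide
receptor radionuclide therapy (PRRT), from planar scintigraphy count images
to organ and tumor absorbed doses.

PRRT delivers a fixed activity course — typically four cycles of 7.4 GBq
(29.6 GBq total) — while the absorbed doses to the critical organs (kidneys,
red marrow) and to individual tumors vary widely between patients. This
package implements the complete planar-dosimetry analysis chain used to
quantify that variability, for medical physicists and methods researchers
who want a tested, reproducible reference implementation:

* **Conjugate-view quantification** — background-corrected geometric-mean
  activity estimates from anterior/posterior image pairs:
  `A = sqrt(C_A * C_P / e^(-mu*T)) / (k * dt)`, which cancels source depth.
* **Kinetics** — multi-start least-squares fits of monoexponential,
  biexponential and uptake–washout models, AICc/AIC selection, terminal
  effective half-lives, and time-integrated activity coefficients
  `tau = sum(a_i / lambda_i)` (analytic) or trapezoid-plus-tail (hybrid).
* **MIRD organ dosimetry** — `D/A0 = sum_s tau_s * S(target <- s)` with a
  mass-weighted remainder-of-body correction, a blood-based red-marrow model
  (`tau_RM = integral(c_blood) * m_RM * ratio`), and planned/actual course
  projections.
* **Sphere-model tumor dosimetry** — unit-density-sphere dose factors
  `df(m) = N * (Delta_np + phi_p(m) * Delta_p) / m`, log-log interpolated by
  lesion mass, with cumulative course doses under the constant-uptake
  assumption, and dose-threshold frequency tables.
* **Response and toxicity analytics** — tumor area/diameter change from CT
  (`((T_t/T_bl) - 1) * 100%`), best change per lesion, shrinkage fractions,
  Spearman dose-response association, renal decline slopes against the
  -20 %/year rule, and 23 Gy kidney / 2 Gy marrow threshold flags.
* **A synthetic phantom cohort generator** with exactly known ground truth
  (organ kinetics, whole-body retention, blood clearance, lesion doses and
  CT size courses), so every stage is testable without patient data.

## Worked example

Simulate a 20-patient cohort, run one patient through the image-to-dose
chain, then produce the cohort report:

```r
library(prrtdose)

co  <- simulate_cohort(seed = 42)
res <- run_patient_dosimetry(co$patients[[1]])
res$doses
#>        organ tiac_h terminal_half_life_h dose_per_unit_Gy_per_GBq course_planned_Gy
#> 1    kidneys  4.936                151.5                   1.4164             41.93
#> 2      liver 20.476                155.0                   1.0220             30.25
#> 3     spleen  2.388                155.6                   1.1759             34.81
#> 4 red marrow  0.714                 78.8                   0.0885              2.62
#> 5 total body 98.805                 99.9                   0.1314              3.89
```

Per organ: the time-integrated activity coefficient (hours of injected
activity residing in the organ), the terminal effective half-life of the
fitted clearance, the absorbed dose per unit administered activity, and the
projected dose for the planned 29.6-GBq course. This synthetic patient's
kidneys would exceed the conservative 23-Gy threshold — exactly the
per-patient variability the analysis exists to surface
(`threshold_flags()` reports it).

```r
rep <- run_cohort_report(co)
rep
#> Cohort dosimetry report
#>   patients: 20   lesions: 65 (52 with CT follow-up)
#>   lesions >= 100 Gy: 52.3%   >= 50 Gy: 73.8%
#>   shrinkage (>= 50 Gy): 35/38 (92%)   all measured: 47/52 (90%)
#>   dose-response Spearman rho: 0.077 (p = 0.588, n = 52)
```

The cohort report aggregates organ doses (Table-2-style summaries in
`rep$organ_summary`), lesion doses with threshold frequencies, per-lesion
best size change, shrinkage fractions with and without a 50-Gy dose floor,
and the dose-response rank correlation — here, as expected for lesion
responses independent of dose, no association.
`write_report_bundle(rep, "report/")` writes the deterministic text bundle
(TSV/CSV/JSON).

The methods vignette (`vignettes/dosimetry-pipeline.Rmd`) documents the
models, assumptions, numerical choices and the generator's design.

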
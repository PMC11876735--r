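---
title: "Planar-image dosimetry for Lu-177 DOTATATE: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar-image dosimetry for Lu-177 DOTATATE: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrtdose)
```

## The problem

Peptide receptor radionuclide therapy (PRRT) with Lu-177 DOTATATE is
administered as a fixed course — typically four cycles of 7.4 GBq — while the
absorbed dose actually delivered to kidneys, red marrow and individual tumors
varies widely between patients. Planar scintigraphy dosimetry estimates those
doses from a handful of whole-body anterior/posterior images acquired over
the week after an infusion, plus blood samples. `prrtdose` implements that
analysis chain end to end and pairs it with a synthetic phantom cohort whose
ground truth is known exactly, so every stage can be validated without
patient data.

The chain is:

1. **Quantification** — conjugate-view (geometric-mean) activity estimates
   per organ/lesion region of interest (ROI) at each imaging time point.
2. **Kinetics** — sum-of-exponentials fits and time-integrated activity
   coefficients (TIACs).
3. **Organ dosimetry** — MIRD-schema S-value sums with a mass-weighted
   remainder-of-body correction and a blood-based red-marrow model.
4. **Tumor dosimetry** — unit-density-sphere dose factors interpolated by
   lesion mass, projected over the course under a constant-uptake assumption.
5. **Response and toxicity analytics** — tumor area/diameter change
   statistics, dose-response rank correlation, organ-at-risk threshold flags.

## Conjugate-view quantification

For a source at depth $d$ in a body of thickness $T$ with effective linear
attenuation coefficient $\mu$, the anterior and posterior count rates are
attenuated by $e^{-\mu d}$ and $e^{-\mu (T-d)}$. Their geometric mean cancels
the unknown depth:

$$A = \frac{\sqrt{C_A C_P / e^{-\mu T}}}{k\,\Delta t},$$

with $k$ the camera sensitivity (counts per MBq·s) and $\Delta t$ the
acquisition duration. Background is corrected by subtracting the mean count
per pixel of a user-drawn background ROI, scaled by the source ROI area, and
floored at zero with a warning. On noiseless phantoms this estimator is exact
to floating-point precision for every depth, which the test suite asserts at
1e-9 relative.

Assumptions inherited from the method: a slab body, a single effective
$\mu$ at 208 keV (default 0.136 cm$^{-1}$), no scatter or septal-penetration
modeling, and non-overlapping ROIs (overlap raises a validation error; the
published correction chains for overlap and scatter are not reproduced
here).

## Kinetics and TIACs

Time-activity samples (fractions of injected activity) are fitted with up to
three families: monoexponential, biexponential (both amplitudes
non-negative), and an uptake–washout model — two terms with exactly one
negative amplitude and $A(0) \ge 0$ — for organs such as kidneys that fill
over the first day. Fitting is multi-start Levenberg–Marquardt (20 starts,
rates initialised on a log grid spanning $[\lambda_{phys}/10,\,10]$ h$^{-1}$,
unweighted by default with optional $1/y$ weights).

Numerical choices that matter:

* **Rate floor.** Rates are parameterised as
  $\lambda_{phys}/10 + e^{p}$: clearance slower than a tenth of physical
  decay is not identifiable inside a 7-day imaging window and, if allowed,
  only inflates the extrapolated tail integral.
* **Unconstrained terminal half-life.** Fits may return terminal effective
  half-lives longer than the physical half-life (159.53 h) — real noisy
  series do this — and such fits are flagged (`superphysical_flag`) rather
  than clipped.
* **Model selection.** Candidates are compared by AICc when every candidate
  supports the small-sample correction ($n > k + 1$), otherwise by AIC; 4–6
  point series cannot carry AICc for 4-parameter models. Saturated fits
  (zero residual degrees of freedom) are excluded from selection unless every
  positive-df candidate grossly lacks fit against the samples' Poisson
  standard deviations (chi-square beyond $9n$) — without this fallback a
  4-point kidney uptake series forced onto a monoexponential can
  overestimate its TIAC several-fold.

The TIAC is computed analytically from the selected model,
$\tau = \sum_i a_i/\lambda_i$ (`tiac_analytic()`). A hybrid alternative
(`tiac_hybrid()`) integrates the observed samples trapezoidally and adds an
analytic tail from the last sample, with either the fitted terminal rate or
pure physical decay. The pipeline uses the analytic TIAC for organs, lesions
and blood, but the **whole-body** retention term is integrated with the
hybrid rule: anchored at the exact physical point $(t=0,\,f=1)$ and closed
with a physical-decay tail. This is the conservative whole-body convention
(no biological elimination assumed after the last scan) and it keeps the
remainder-of-body balance from being broken by extrapolated fit tails of a
4-point whole-body series.

## Organ dosimetry

Absorbed dose per unit administered activity is the MIRD sum
$D/A_0 = \sum_s \tau_s\, S(t \leftarrow s)$ over explicit sources plus the
remainder of body, with

$$\tau_{RoB} = \tau_{TB} - \sum_s \tau_s, \qquad
S(t \leftarrow RoB) = \frac{S(t \leftarrow TB)\,M_{TB} -
\sum_s S(t \leftarrow s)\,M_s}{M_{TB} - \sum_s M_s}.$$

A negative remainder TIAC raises an error (it signals inconsistent
quantification — organ activity exceeding whole-body activity — and must
never be clipped silently); a negative remainder S-value is floored at zero
with a warning. The red-marrow TIAC comes from the blood model:
$\tau_{RM} = \left(\int_0^\infty c_{blood}\,dt\right) m_{RM}\, r$, with
marrow mass 1.17 kg and a marrow-to-blood activity concentration ratio
defaulting to 1, the standard choice for peptides without specific marrow
binding. Course doses multiply the per-GBq dose by either the planned course
(29.6 GBq) or the administered cycle activities.

S-values ship as a **synthetic** CSV fixture
(`inst/extdata/s_values_synthetic.csv`): electron self-dose plus a small
photon cross-dose, constructed so the MIRD partition identity
$S(t \leftarrow TB)\,M_{TB} = \sum_s S(t \leftarrow s)\,M_s$ holds over the
organ partition. The values are plausible in magnitude for Lu-177 but are
not a published reference phantom table; users with a real phantom table
supply it through `read_dose_factor_table()`. Patient-specific self-dose
mass scaling is deliberately not applied by default.

## Tumor dosimetry

Sphere dose factors for unit-density spheres are
$df(m) = N \,[\Delta_{np} + \phi_p(m)\,\Delta_p]/m$ with $N$ = 3.6e9
decays per MBq·h, $\Delta_{np}$ = 0.1479 MeV/decay of electrons (absorbed
locally) and $\Delta_p$ = 0.0345 MeV/decay of photons whose absorbed
fraction $\phi_p(m)$ is a synthetic smooth curve (small, as appropriate for
these photon energies). Interpolation over lesion mass is **log-log
linear**, which is exact for power-law tables and hence exact in the
electron-only limit where $df \propto 1/m$. Masses below the grid raise by
default — mirroring the exclusion of lesions below camera resolution —
rather than extrapolating silently; power-law extrapolation can be enabled
and is flagged.

Lesion dose per administration is $A_0 \tau\, df(m)$. Course projection
assumes uptake proportional to mass (constant absorbed dose at every cycle
for equal injected activity), so the cumulative dose scales the
reference-cycle dose by total administered over reference-cycle activity.

## Response and toxicity analytics

Tumor size change uses the area ratio
$((L_t W_t)/(L_{bl} W_{bl}) - 1)\times 100\%$, with a single-diameter
variant (short axis for lymph nodes, long axis otherwise). The best change
is the minimum over post-baseline time points; shrinkage means a negative
best change. Reporting precision follows the conventions of cohort tables in
this field: threshold and incidence percentages to one decimal, shrinkage
percentages to the nearest integer. The dose-response association is a
Spearman rank correlation with mid-ranks for ties — an explicitly labeled
convenience statistic; the scientific claim it supports is qualitative.
Renal decline is the least-squares slope of percent change from baseline
creatinine clearance versus years, flagged at or below -20 %/year (a 1e-9
relative tolerance keeps an exactly-threshold slope flagged despite
round-off). Organ-at-risk flags use strict inequalities against 23 Gy
(kidneys) and 2 Gy (red marrow) course doses.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the pipeline is designed
for, with every draw derived from one integer seed through named substreams
(images, blood, lesions, renal series are independently reproducible):

* 20 patients imaged at 4 (3 patients), 5 (14) or 6 (3) time points within
  7 days, last scan at 3 days for some and 6–7 days for the rest; kidneys,
  liver and spleen with biexponential kinetics; about 30% of kidneys get an
  uptake phase peaking near 24–35 h; terminal effective half-lives are drawn
  in 30–150 h, inside the 21–161 h band such studies report; a biexponential
  blood curve and an administration record per patient (15 complete four
  7.4-GBq cycles; 3, 1 and 1 patients stop after 3, 2 and 1).
* A uniform soft-tissue/blood-pool **background compartment** holding 70% of
  the injected activity at $t=0$ and clearing biexponentially. Making the
  background a kinetic compartment (rather than a fixed fraction of organ
  activity) is what gives the phantom a physically consistent whole-body
  retention curve: whole-body TIAC strictly exceeds the organ plus marrow
  TIACs, as it must for the remainder correction to be meaningful.
* 65 target lesions in 17 patients, masses ~1–1000 g (lognormal, clamped),
  locations liver/lymph node/bone/other in the observed proportions.
  Ground-truth lesion TIACs are backed out of target cumulative doses
  through the sphere table, with doses drawn inside three strata (34 lesions
  ≥ 100 Gy, 14 in 50–100 Gy, 17 below 50 Gy) and kept clear of the 50/100 Gy
  boundaries so classification is unambiguous under floating-point round
  trips.
* 52 lesions carry CT courses over up to 72 weeks at 12-week intervals
  (1–6 post-baseline points): 38 from the ≥ 50 Gy strata of which 35 shrink,
  and 14 low-dose lesions of which 12 shrink — so 47 of 52 shrink overall.
  Shrinkage is defined on **area**: axes scale by $\sqrt{1 - s(1 -
  e^{-t/\tau})}$, making the plateau area change exactly $-100\,s\%$.
  Shrinking lesions draw $s \in [0.10, 0.565]$, growing ones
  $s \in [-0.30, -0.08]$, and per-axis measurement jitter (1% SD) is clamped
  at 3 SD, which guarantees the sign of every best change matches its class.
  The plateau magnitudes bracket the best-change range reported for
  responding lesions in this setting (about -3.6% to -56.5% for the
  high-dose group).

What the generator does **not** emulate: anatomically realistic activity
distributions (organs are rectangles in a slab), scatter and septal
penetration, ROI mis-drawing, organ overlap, CT volume segmentation error
beyond axis jitter, and inter-cycle kinetic changes. Passing tests therefore
validate the mathematics and the estimator contracts, not the clinical
accuracy of planar dosimetry on real images — the known biases of the planar
method (tumor size limits, background heterogeneity) are out of scope by
construction.

## Problem sizes and runtime choices

The test suite renders 32x32 to 64x64 pixel frames; the parameter-recovery
study uses 200 seeded cohorts at ~1e4 ROI counts and six time points, where
the terminal half-life and TIAC recover with RMSE well under 10%; the
quadrature cross-check uses 500 random exponential models; the full-cohort
determinism check runs the 20-patient pipeline twice and compares report
bundles byte for byte. These sizes are the package's own validation design:
small enough to run routinely, large enough that each property is exercised
across its parameter range.

## Known limitations

* The S-value and sphere-photon fixtures are synthetic stand-ins with
  correct structure and plausible magnitude; absolute organ doses from the
  toy table should not be quoted against published phantom tables.
* Fits on 4-point series are fragile by nature; the pipeline's guards
  (rate floor, saturated-fit fallback, hybrid whole-body integration) keep
  the cohort runs stable, but individual organ fits can still return
  superphysical half-lives, which are flagged and propagate to doses.
* Blood-based marrow dosimetry ignores image-based marrow contributions
  (e.g. from skeletal metastases); the marrow-to-blood ratio is a single
  configurable scalar.
* No RECIST-style overall response classification, survival endpoints or
  adverse-event grading: CTCAE grades and event counts are consumed as
  inputs only.
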
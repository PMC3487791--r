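---
title: "Volumetric response criteria for GIST liver metastases: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric response criteria: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volresp)
```

## The problem

Response of solid tumors to therapy is conventionally assessed by RECIST 1.1:
the percent change of the sum of the longest diameters of up to two target
lesions per organ, with partial response (PR) at a decrease of at least 30%,
progressive disease (PD) at an increase of at least 20% or a new lesion, and
stable disease (SD) in between. A single diameter is a one-degree-of-freedom
description of a three-dimensional object. GIST liver metastases under
imatinib often shrink anisotropically — mostly along their short axes — so a
volumetric (3D) measurement can register a large, real change while the
longest diameter barely moves. This package implements the machinery needed to
quantify that gap: four response classifiers, a raw 1D-vs-3D change-detection
comparison, an exact test of symmetry for the resulting paired tables,
landmark survival analysis by response group, and a synthetic cohort generator
that makes the whole pipeline testable without patient data.

## Geometry and cut-offs

Lesions are modeled as prolate spheroids (`r1 = r2 <= r3`, volume
`4/3 * pi * r1 * r2 * r3`), with the RECIST diameter tied to the longest axis
(`d = 2 * r3`). Two volumetric cut-off sets follow:

* **3D-sphere**: if the tumor is a sphere, a diameter change of `c`% is a
  volume change of `100 * ((1 + c/100)^3 - 1)`%. RECIST's (−30, +20) maps to
  (−65.7, +72.8); `derive_sphere_cutoffs()` performs the mapping and the
  package stores the full-precision values (the familiar "65% volume
  reduction" is the rounded presentation of −65.7).
* **3D-ellipsoid**: if only the longest axis changes, the volume changes by
  exactly the same percentage as the diameter, so the RECIST percentages
  (−30, +20) are reused directly on the volume scale. This is the most
  conservative volumetric reading: any additional short-axis response makes
  the volume change larger than the diameter change.

Choi criteria combine size (PR at a 10% diameter decrease, PD at a 10%
increase) with CT density (PR at a 15% mean HU decrease); new lesions or new
intratumoral nodules force PD. Density changes are averaged over the target
lesions as per-lesion relative changes; when densities are unavailable the
call proceeds on size alone and carries a `density_missing` flag.

All boundaries are inclusive toward the more extreme category, matching the
"at least" phrasing of the published criteria; strictness at the boundary is
otherwise unobservable with continuous data. All changes are computed versus
baseline, not nadir — the comparisons here are baseline-to-timepoint, and a
nadir-based PD rule would need the full longitudinal RECIST bookkeeping that
is out of scope. Multi-lesion volumes are aggregated by summation, mirroring
RECIST's summed diameters; no published aggregation rule exists for volumes,
so the mirrored rule is the least surprising choice.

## The exact test of table symmetry

The 1D and 3D classifications of the same patients form a square paired
table. The null hypothesis of interest is symmetry: neither measurement
systematically out-detects the other. Conditional on each off-diagonal pair
total `n_ij + n_ji`, the split is Binomial(n, 1/2) under the null, and the
pairs are independent. `exact_symmetry_test()` computes the probability of
every joint configuration and sums those no more probable than the observed
one (probability ordering, two-sided by construction). This reproduces all of
the published p-values for these tables, including the closed-form cases
(a single `n` vs `0` pair gives `p = 2 * (1/2)^n`). For k = 2 this is the
exact McNemar test; the asymptotic analogue is Bowker's
`sum (n_ij - n_ji)^2 / (n_ij + n_ji)`, which the function switches to when
every discordant pair total reaches 25 (sparse tables are the intended use,
and the published tables are very sparse).

Numerical choices: the enumeration works in log space, and the comparison
"configuration probability <= observed probability" uses a relative tolerance
of 1e-12. Tied configurations are exact ties in rational arithmetic but only
near-ties in floating point; without the tolerance a tie could fall on the
wrong side and halve the p-value. The test suite checks the implementation
against an independent oracle that enumerates configurations with exact
integer binomial coefficients (products stay below 2^53 at the tested table
sizes, so no tolerance is needed there).

Display rounding is half-away-from-zero (`round_half_up()`), because that is
how the published values were rounded (0.125 prints as .13, 0.625 as .63);
R's default banker's rounding would disagree at exactly these values.

## Survival analysis

Overall survival is analysed with the landmark method: time runs from the
landmark CT (3, 6 or 12 months), patients dead or censored on or before the
landmark are excluded, and groups are formed from the response call at the
landmark (PD vs non-PD, or PR/SD/PD). This avoids guarantee-time bias —
patients must survive to the landmark to be classified at all. Exclusion is
strict (`os <= landmark` drops the patient) and every exclusion is counted in
the output.

Kaplan-Meier curves use the standard product-limit estimator with events
before censorings at tied times. The log-rank test accumulates observed minus
expected events over event times with the hypergeometric covariance; the
Mantel-Haenszel hazard ratio is `(O1/E1)/(O0/E0)` with
`exp(log HR ± 1.96 * sqrt(1/E1 + 1/E0))` confidence limits, flagged undefined
when a group has zero expected events. These are implemented from the
formulas (the contract of this package) and verified in the tests against the
independent `survival` package. Curves can be truncated at 72 months for
reporting (`km_table(truncate_months = 72)`); estimation is never truncated.

## The synthetic cohort: what it emulates, and what a green test proves

No raw measurements are deposited with the study this package operationalises,
so the pipeline is exercised on simulated cohorts (`simulate_cohort()`) whose
structure encodes the stated world:

* **Geometry**: prolate-spheroid lesions, 1–4 per patient, baseline longest
  semi-axis log-normal with median 20 mm and log-sd 0.45, short/long aspect
  ratio uniform on (0.55, 1). The published work gives no baseline size
  distribution; a 40 mm-diameter median liver metastasis with moderate spread
  is a realistic GIST presentation and the value is stated once here, not
  revisited.
* **Latent response classes** with per-quarter multiplicative axis rates:
  isotropic responders (0.85 on all axes), anisotropic responders
  (0.75, 0.75, 0.93 — volume −48% but diameter −7% at 3 months, the
  discordance mechanism), stable (1), progressors (1.25 on all axes). Default
  class probabilities (0.10, 0.45, 0.35, 0.10) put the cohort-level response
  distributions in the neighbourhood of the published training-cohort
  percentages (RECIST PR rare at 3 months, ellipsoid PR for roughly half).
* **Measurement noise**, multiplicative log-normal so sizes stay positive:
  calibrated so the mean absolute relative difference between the two manual
  readers is 0.2% (1D) and 3.2% (3D), and between methods 0.15% (1D) and
  9.6% (3D) — the reported variabilities. The semi-automated method is a
  single deterministic "reader", so in a full cohort the manual-vs-semiauto
  comparison also carries the manual reader's noise and slightly exceeds the
  configured method component; the agreement-recovery test therefore uses
  `simulate_paired_measurements()`, which realises the stated variability
  exactly.
* **Density**: only semi-automated rows carry HU values (as in practice);
  responders' density declines 20% per quarter from a baseline of
  roughly 75 ± 12 HU.
* **Survival**: exponential per class (median 66 months for responders, 48
  stable, 16 progressors) with uniform censoring on (36, 110) months,
  spanning the follow-up ranges of the two cohorts. New lesions appear only
  in progressors (Bernoulli 0.3 per follow-up, persistent once present).

Axes are re-sorted at every timepoint so the measured diameter is the
*current* longest diameter, not a fixed anatomical axis. Emitted semi-axes
are rescaled isotropically to match the noisy measured volume, so every
generated row satisfies the axis/volume consistency invariant of the file
schema.

The "variability" reported for the method comparison has no published
formula; this package defines it as the mean symmetric percent difference
`mean(|a-b| / ((a+b)/2)) * 100`, and the recovery test only establishes
internal consistency with a generator built under the same definition.
Likewise, a green parameter-recovery test establishes that the pipeline
correctly measures cohorts with this structure — not that real GIST cohorts
have it. Features of real data deliberately not emulated include: lesion
coalescence and irregular shapes, scanner/protocol batch effects,
within-class heterogeneity of response rates, non-exponential hazards, and
informative censoring.

`expected_detection_rates()` is the analytic oracle for recovery tests: with
the configured rates the true diameter and volume ratios are closed-form, and
detection probabilities under log-normal noise are normal tail probabilities.
It uses the single-lesion noise level (patients summing two lesions average
some noise away), a negligible approximation because all default classes sit
far from the ±20% boundary relative to the noise.

## Design choices on genuinely open points

* **Timepoint window**: scans are eligible for a nominal timepoint within
  ±1.5 months. The study picked "the closest CT" without a window; the
  published scan-time ranges (2.3–3.7, 5.2–6.7, 11.1–12.9 months) all fit
  inside ±1.5 months, which also prevents a 3-month CT from serving as a
  6-month assessment.
* **Reader handling**: multi-reader measurements are never merged; every
  analysis filters to one method and one reader (defaulting to the
  lexicographically first), because the published analysis does not state a
  consensus rule.
* **Change detection on target lesions**: the 1D-vs-3D comparison defaults to
  the RECIST target lesions (`use_target_lesions = TRUE`), with a switch to
  use all of a patient's lesions, since the published per-patient tables do
  not say which set fed them.
* **Eligibility**: a patient enters an analysis timepoint only if all target
  lesions are measured at baseline and that timepoint by the same
  method/reader, mirroring the study's per-timepoint denominators; every
  exclusion is enumerated, never silent.
* **Units**: files carry mL, geometry works in mm³, 1 mL = 1000 mm³.

## Known limitations

* The exact test's enumeration grows as the product of (pair total + 1) over
  discordant pairs; the implementation guards this and falls back to the
  asymptotic Bowker test, which is also used when all pair totals are >= 25.
* Survival outputs are validated by properties and simulation only: the
  published survival figures print no numeric hazard ratios or p-values.
* Nadir-based RECIST progression, PFS endpoints, Cox models, density
  measurement from images and DICOM handling are out of scope.
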
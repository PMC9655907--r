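---
title: "Methods: from FAME profiles and screening counts to biodiesel quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from FAME profiles and screening counts to biodiesel quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycodiesel)
```

## Scope

`phycodiesel` implements the quantitative chain used when a microalga is
improved for biodiesel by random mutagenesis: plasma-exposure screening
arithmetic, growth kinetics, spectrophotometric composition assays, GC-MS
fatty-acid (FAME) profile summarization, and empirical fuel-property
estimation with standards compliance. Each stage is a plain function with a
small S3 result class; a seeded generator produces synthetic inputs with
known ground truth so every stage is testable without instrument data. The
package bundles a reference dataset — the wild strain (`WS`) and five
plasma mutants (`M1`–`M8`) of the marine chlorophyte *Parachlorella
kessleri* — used in examples and cross-checks.

## FAME profiles and saturation classes

A profile is a compositional vector of relative percentages over fatty-acid
species parsed from shorthand (`C18:1 (ω9)` = 18 carbons, 1 double bond,
omega-9). Design choices:

* **Not-detected is zero, not missing.** GC-MS tables mark species below
  detection with a dash; treating them as `NA` would silently drop them
  from sums, while 0 is the value the closure of the composition implies.
* **Total gate.** Relative-percentage columns should sum to roughly 100;
  totals outside [95, 105] on load are treated as transcription or
  integration errors and rejected. `normalize_profile()` closes a profile
  to exactly 100 when needed; class summaries are computed on the raw
  percentages by default, with `renormalize = TRUE` as an explicit option,
  because the bundled wild-strain PUFA value (35.9%) is reproduced on the
  raw scale.
* **Average degree of unsaturation.** `ADU = Σ Nᵢ Mᵢ` with `Nᵢ` the C=C
  count and `Mᵢ` the mass fraction on the 0–1 scale, so a pure
  monounsaturated profile has ADU exactly 1. This is the single predictor
  of the property regressions below.
* **Db ≥ 4 is literal.** The fraction with four or more double bonds is
  summed as defined; the separate `c18_3_pct` field carries the linolenic
  limit, rather than bending one definition to serve both reporting
  conventions.
* **Omega annotations are identity.** `C18:1`, `C18:1 (ω7)` and
  `C18:1 (ω9)` are distinct keys; summaries simply add them.

## Fuel-property regressions

Six properties are linear in ADU (kinematic viscosity υ, density ρ, cloud
point CP, cetane number CN, iodine value IV, higher heating value HHV), and
the cold filter plugging point is linear in the long-chain saturated
factor:

| property | form | units |
|---|---|---|
| υ | −0.6313·ADU + 5.2065 | mm²/s (40 °C) |
| ρ | 0.0055·ADU + 0.8726 | g/cm³ |
| CP | −3.356·ADU + 19.994 | °C |
| CN | −6.6684·ADU + 62.876 | — |
| IV | 74.373·ADU + 12.71 | g I₂/100 g |
| HHV | 1.7601·ADU + 38.534 | MJ/kg |
| CFPP | 3.1417·LCSF − 16.477 | °C |

with `LCSF = 0.1·C16:0 + 0.5·C18:0 + 1·C20:0 + 1.5·C22:0 + 2·C24:0` (wt%).
The five-term LCSF is the default: the weighted form that includes
1.5·C22:0 is the one that back-reproduces the bundled reference LCSF and
CFPP values (e.g. M8: LCSF 11.24, CFPP 18.80 °C); a four-term variant
without C22:0 is available via `terms = "four"` for sources that omit it.

Three caveats are built in as always-on or conditional `flags` on the
result object rather than silent behavior:

* `cp_regression_not_reconciled` — the CP regression does not reproduce
  published per-strain cloud points in this system (e.g. ADU 1.47 gives
  15.06 °C where 0.32 °C is reported); CP is still computed by its printed
  form, and reports must carry the caveat.
* `adu_supplied_disagrees_with_profile` — ADU recomputed from a profile
  can differ substantially from an externally reported ADU for the same
  strain (for the bundled M8 column: 0.48 from the profile vs 0.87
  reported). The package therefore supports both sources: a supplied ADU
  takes precedence when given, the from-profile value is kept alongside
  (`adu_from_profile`), and the source is recorded.
* `iv_sensitive_to_adu_rounding` — with slope 74.4, a 0.005 rounding of
  ADU already moves IV by ~0.4 g I₂/100 g, so IV agreement with
  2-decimal-ADU references is only expected to a few tenths.

## Standards compliance

ASTM D6751 and EN 14214 limits ship as a JSON resource (kinematic
viscosity, cetane number, iodine value, density, cloud point, Db ≥ 4 and
C18:3 caps). Printed "≥ x" / "≤ x" limits are closed bounds — a value
exactly on the bound passes — while the ASTM cloud-point "> 4" is open,
and the schema records openness explicitly. Properties a standard does not
limit are reported `not-limited` and never affect the overall verdict;
properties whose inputs were not carried through (e.g. composition
percentages when only ADU was supplied) are `not-evaluated` rather than
silently passed.

## Growth kinetics and productivity

Dry weight is preferred; OD680-only readings are converted through an
ordinary-least-squares calibration (`fit_od_calibration()`). The specific
growth rate is the endpoint log-ratio `µ = (ln DWt − ln DW0)/t`.
Productivity over a window is the signed difference quotient
`(late − early)/Δt`: the sign convention keeps a declining culture visibly
negative while matching the positive values reported for growing cultures.
The rate window defaults to days 2–16, the exponential phase typical of
these batch cultures; the window actually used is recorded in the result.

Fold change is `mutant/wild`, percent increase `(fold − 1)·100`; the wild
value must be positive.

## Screening arithmetic

Mortality is `(1 − T/C) × 100` for treated count `T` and control count `C`
— the parenthesization that keeps the value on a 0–100% scale — clamped at
0 with a warning if sampling noise gives `T > C`. Dose selection encodes
the screening principle that the positive-mutation rate peaks at ≥ 95%
lethality *while survivors remain*: `select_exposure()` returns the
smallest exposure whose mortality meets the threshold with at least one
surviving colony, and a fully lethal dose never qualifies; when nothing
qualifies an explicit non-viable result is returned. Mutant ranking keeps
strains beating the wild type on both growth-rate and lipid folds and
orders them lipid-fold first (growth-first is available via `priority`);
the lexicographic order is a package choice where practice only says
"comprehensive analysis".

## Assay calibration

Pigments use the methanol-extract equations
`Chl a = 10.3·A663 − 0.913·A644`, `Chl b = 19.07·A644 − 3.87·A663`,
`Car = 4.2·A452 − (0.0264·Chl a + 0.426·Chl b)` (µg/mL), converted to
µg/mgDW through the extract volume and aliquot biomass. The chlorophyll-b
leading coefficient is 19.07: a coefficient three orders of magnitude above
the chlorophyll-a one is physically impossible for this assay family, and
19.07 is the magnitude consistent with methanol-extract spectrophotometry;
the coefficient is overridable (`chlb_coef`) for users following a
different equation set. Blank-subtraction noise can drive an equation
negative; negative pigments are floored at 0 with a warning, and the
unfloored values are kept in `raw` so linearity diagnostics remain
possible.

Lipid (SPV), carbohydrate, protein and Nile-red TAG quantification all go
through one empirical standard-curve pair: `fit_standard_curve()` (OLS
line, ≥ 3 points spanning a nonzero range) and `invert_curve()`, which
solves for concentration and flags — rather than refuses — readings outside
the calibrated signal range. TAG is reported per culture volume (µg/mL),
not per dry weight, matching fluorometric practice. `composition_table()`
fixes the unit identity `%DW = (mg/gDW)/10` and appends folds versus the
wild strain.

## The synthetic-data generator

Generators take an explicit seed, use their own RNG stream, and restore the
caller's RNG state, so calls are reproducible in isolation and in any
order. Defaults are the study conditions the pipeline is meant to emulate:

* **Growth** (`sim_growth_curve`): logistic with a lag offset — 0.025 g/L
  inoculum, 0.65 g/L carrying capacity, intrinsic rate 0.20 day⁻¹, 2-day
  lag, sampling every 2 days to day 20, multiplicative log-normal noise
  (σ = 0.05), OD derived at 0.24 (g/L)/AU. The returned `truth` includes
  the noiseless trajectory function. Note that the endpoint rate of a
  logistic over a finite window is below the intrinsic rate by
  construction, so recovery studies compare the estimate against the
  *analytic window rate* from `truth$analytic`, not against µ itself;
  tolerances then measure noise sensitivity, not model bias.
* **Dose–mortality** (`sim_mortality_table`): survival
  `1/(1 + exp(k(t − t50)))` with binomial colony counts; defaults t50 =
  32 s, k = 0.45 s⁻¹, 320 control colonies. These place the expected dose
  response where a plasma screen on a 10–60 s grid is set up to operate:
  crossing the 95% threshold between 30 and 40 s (~97% expected mortality
  at 40 s, ~15 expected survivors of 320) and essentially fully lethal by
  50 s. A much shallower slope cannot produce that pattern — it would put
  the first ≥ 95% dose at the top of the grid. `truth$designed_dose()`
  returns the exposure the configuration is designed to make
  `select_exposure()` pick.
* **FAME profiles** (`sim_fame_profiles`): Dirichlet jitter around a
  bundled strain archetype (concentration 500, i.e. component standard
  deviations of ~1–2 percentage points), with not-detected species held at
  exactly zero and every draw closed to 100%.
* **Assays** (`sim_assay_readings`): linear signal model with Gaussian
  noise, clamped at zero signal with a flag; defaults emulate a Nile-red
  ladder (0–600 µg/mL, slope 0.0015 AU per µg/mL, σ = 0.005 AU).

What the generator does **not** emulate: GC-MS peak-integration artifacts
and co-elution, correlated replicate structure, photo-limitation and
nutrient-depletion dynamics beyond the logistic plateau, and any mechanism
linking plasma dose to trait shifts (mutant traits are drawn from
configured distributions). Passing recovery tests therefore demonstrates
the estimators' correctness and noise behavior under these idealized
conditions, not robustness to real instrument pathologies.

## Problem sizes and numerical choices

Recovery studies use 100 seeded growth curves and calibrations and 200
seeded mortality tables; the compositional law-of-large-numbers check uses
500 draws. These sizes put Monte-Carlo error well below the tolerances
they are checked against (e.g. median slope error ~1.5% against a 5%
bound) while keeping the full suite fast. Exact identities (class
conservation, closure after normalization, curve inversion on noiseless
points) are asserted to 1e−9 or tighter; comparisons with 2-decimal
published references use 0.01–0.05 absolute windows matching their printed
precision. Report serialization rounds to 2 decimals; all comparisons use
full precision. Ties in dose selection are broken toward the smaller
exposure; ranking ties break by the secondary fold, then strain id.

## Known limitations

* Property estimates are empirical univariate regressions; they carry no
  uncertainty and extrapolate linearly outside the ADU range they were
  fitted on (roughly 0–3). No group-contribution or thermodynamic model is
  provided.
* The from-profile ADU path and an externally supplied ADU can disagree
  (see flags above); the package reports both rather than adjudicating.
* The cloud-point regression is retained for completeness but flagged as
  unreconciled; compliance verdicts involving CP should be read with that
  caveat.
* Growth-rate estimation is endpoint-based; no logistic or Gompertz model
  fitting is offered as a headline feature.
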
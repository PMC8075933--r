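---
title: "Methods: glove permeation, PBPK internal doses, and margins of exposure for NMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glove permeation, PBPK internal doses, and margins of exposure for NMP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmpglove)
```

## The problem

N-methylpyrrolidone (NMP) is a dermally well-absorbed solvent used in
paint strippers. For several occupational stripping scenarios, margins of
exposure computed without gloves fall below the acceptability threshold
of 30, and the dominant exposure route is liquid NMP on the hands.
Whether gloves fix that depends strongly on the glove: measured NMP
permeation rates across glove materials span nearly three orders of
magnitude. This package quantifies glove efficacy by propagating
measured permeation rates through a physiologically based pharmacokinetic
(PBPK) model of the exposed worker and re-expressing the result as
margins of exposure (MOE) and glove protection factors (PF).

The pipeline is:

1. **Permeation data → permeability coefficients.** A steady-state
   permeation rate PR (µg/cm²/min) measured against a formulation with
   NMP concentration C (mg/cm³) gives a permeability coefficient
   `Kp = PR / C × 0.06` in cm/h (the 0.06 collapses the µg→mg and
   min→h conversions).
2. **Glove + skin → composite barrier.** Gloved skin is a two-layer
   barrier under Fick's law; permeabilities compose like conductances in
   series: `1/Kp_net = 1/Kp_skin + 1/Kp_glove`. The skin coefficients are
   0.00205 cm/h for neat NMP and 0.000478 cm/h for NMP solutions
   (shipped as `kp_skin_defaults`, overridable).
3. **Barrier → internal dose.** A flow-limited PBPK model aggregates
   dermal-liquid, dermal-vapor and inhalation uptake into blood NMP
   concentration over time, summarized as Cmax (mg/L, acute metric) and
   AUC (mg·h/L, chronic metric).
4. **Internal dose → risk.** `MOE = POD / dose` against internal-dose
   points of departure (216 mg/L Cmax for the acute developmental
   endpoint; 411 mg·h/L AUC for the chronic one), with acceptability at
   MOE ≥ 30; `PF = dose_no_gloves / dose_gloves` computed from
   dermal-liquid-only simulations to isolate what the glove itself does.

## Censoring and classification rules

Permeation datasets are messy in three specific ways, and the package's
conventions for them are deliberate:

- **Below-detection rates** (`"<0.1"`) are replaced by half the
  detection limit (0.05), the standard substitution for left-censored
  hygiene data.
- **Above-range rates** (`">34"`) are taken at face value. This
  understates the true rate, which flatters the glove; we accept it
  because the resulting permeability coefficient matches the value
  published for that record, confirming this is the convention the
  source data used.
- **"Not detected" with no stated detection limit** cannot be quantified
  at all and is excluded from permeability computations and summaries
  (the record is retained in the dataset for completeness).

Gloves fall into three protection categories by effective permeation
rate: minimal (> 2 µg/cm²/min), moderate (1–2), maximal (≤ 0.3). The
definition leaves the interval (0.3, 1) uncovered; we assign it to
moderate — the adjacent *less protective* category, i.e. the
conservative choice for the worker — and flag it with a warning. A
`category_hint` column, when present, overrides the rate rule: reference
datasets group records by glove material family, and one atypical
measurement (a natural-rubber glove at 0.19 µg/cm²/min, sitting among
rates up to 94) stays with its minimal-protection family rather than
being promoted to maximal on the strength of a single formulation.

## Aggregation order: aggregate, then compose

Category summaries average the **unrounded** per-record glove Kp values
first and apply the series composition once to the mean (and to the min
and max). The alternative — composing each record with skin and then
averaging the Kp_net values — gives different numbers because the
harmonic composition is nonlinear. Aggregate-then-compose with full
precision is the only order that reproduces all six published
category-mean Kp_net values at two significant figures, including the
close pair 0.0000076 (solution) / 0.0000077 (neat) for the maximal
category, so it is the package's fixed convention. Rounding to two
significant figures happens only at the reporting boundary
(`report_signif()`, round-half-even); no intermediate rounding is ever
applied. Two cells of the source tables disagree with full-precision
arithmetic by one unit in the last printed digit (a range maximum that
only reproduces if an intermediately rounded Kp is composed, and one Kp
cell that appears truncated rather than rounded); we keep full precision
and document the difference rather than replicate it.

The two moderate-category records are equally weighted in the mean (no
per-study weighting), and a single-record category yields
mean = min = max.

## The PBPK model

The model is the standard flow-limited perfusion structure used for NMP:
compartments for liver, fat, skin, rapidly and slowly perfused tissue,
and venous blood; arterial blood at quasi-steady state through a lung
with blood:air partitioning; saturable hepatic metabolism
(`vmax·C/(km + C)`); and a first-order renal clearance of parent
compound. Dermal-liquid uptake enters the skin compartment as
`Kp × area × concentration` (cm/h × cm² × mg/cm³ = mg/h) with the donor
liquid assumed inexhaustible and at constant concentration while contact
lasts — a conservative assumption that can absorb ~15 g of NMP over a
neat-NMP workday. Dermal-vapor uptake is a separate
`Kp_vapor × area × C_air` flux over uncovered skin; a respirator removes
90% of the *inhaled* concentration only and never touches the vapor
flux, and gloves reduce only the dermal-liquid Kp. Exposure schedules
are piecewise constant and the integrator (stiff-capable `lsoda`,
rtol 1e-8, atol 1e-10) is restarted at every schedule discontinuity, so
discontinuous inputs are handled exactly. A mass-balance ledger
(absorbed by route, exhaled, metabolized, renally cleared, remaining in
body) is carried as auxiliary integrals and must close within 0.1%.

The paper trail for NMP PBPK parameter values runs through a regulatory
assessment whose full parameterization is not printed in the primary
literature, so the shipped defaults (`default_pbpk_parameters()`,
mirrored in `inst/extdata/pbpk_defaults.yaml`) are an **illustrative
human parameterization**: reference-human physiology (70 kg, cardiac
output 348 L/h, alveolar ventilation 300 L/h, standard tissue volume and
flow fractions), partition coefficients near 1 except fat (0.3) as
expected for a highly water-soluble, low-log-Kow solvent, a very large
blood:air partition (5000) reflecting NMP's low volatility, and
round-number metabolic constants (vmax 420 mg/h, km 90 mg/L, renal
clearance 4.6 L/h) of plausible magnitude. Every value is
config-overridable. Consequences of this stance:

- **Absolute** internal doses, MOEs and PFs from this package are
  illustrative, not replications of any regulatory number.
- **Relative and structural** results are the package's claims: exact
  reproduction of the permeability tables; proportionality of doses to
  Kp in the linear limit; monotonicity of doses in Kp, air
  concentration and duration; and the saturation mechanism by which
  PF(Cmax) exceeds the raw Kp ratio (without gloves, neat-NMP uptake
  pushes blood NMP far above km, so metabolism saturates and the
  no-glove dose grows superlinearly; the gloved dose stays in the linear
  range). The published PFs show exactly this signature (510 vs a Kp
  ratio of ≈266 for neat NMP / maximal protection).

## Exposure scenarios

Eight occupational base scenarios are assessed: two tasks
(miscellaneous stripping, graffiti removal) × two liquid levels
(mid-range NMP solution, which binds the solution skin Kp; high-end
neat NMP, which binds the neat skin Kp) × respirator on/off. Each
expands over glove options (none, minimal, moderate, maximal), and
category ranges (min/mean/max Kp_net) propagate into dose and MOE
ranges. The default exposure parameterization
(`default_scenario_config()`, mirrored in
`inst/extdata/scenario_defaults.yaml`) is again illustrative: 8-h
(stripping) or 6-h (graffiti) daily contact over both hands (890 cm²),
liquid concentrations of 450–540 mg/cm³ for mid-range solutions and
1030 mg/cm³ (neat density) for high-end, air concentrations of
24–60 mg/m³, 3000 cm² of vapor-exposed skin. It was chosen once so that
the no-glove MOEs fall in the bands reported for these scenarios (acute
roughly 0.7–14, chronic roughly 0.1–6.1) and is not asserted to equal
any regulatory assessment's inputs. The chronic schedule simulates 5
consecutive exposure days and reports the AUC of the final 24-h day; the
system's effective time constant is a few hours, so the last day is
steady-periodic well before day 5 (tests use 2–3 days for speed on the
same grounds).

## What the synthetic generator does and does not emulate

`generate_permeation_dataset()` draws rates log-uniformly over
0.05–100 µg/cm²/min (the ~3-decade span of real glove data), censors
below a configurable detection limit, and draws test concentrations
uniformly over 371–1030 mg/cm³. It reproduces the *marginal* statistical
structure the pipeline consumes — heavy spread across decades,
left-censoring, concentration variation — deterministically under a
seed. It does not model glove-material covariance, temperature
dependence, breakthrough kinetics, or acute glove failure (swelling,
splitting), all real features of permeation data that the downstream
analysis does not consume. Passing tests on synthetic data therefore
demonstrate pipeline robustness and invariant preservation, not fidelity
of any particular glove's rating.

## Numerical choices and degenerate inputs

- `kp_net` treats an infinite glove Kp as "no glove" and returns the
  skin Kp *exactly* (no floating-point composition), and an explicit
  zero for either layer as a valid impermeable-layer edge returning 0.
- Solver tolerances (1e-8/1e-10) keep the linear-limit proportionality
  checks meaningful at 1e-6 relative and mass balance far inside 0.1%.
- A zero internal dose yields an infinite MOE (and PF) marker rather
  than an error; a zero *denominator* input elsewhere (test
  concentration, POD, threshold) is a validation error.
- Negative compartment amounts beyond integrator noise abort the
  simulation rather than being silently clamped.
- The MOE threshold defaults to 30 (3 interspecies toxicodynamics × 10
  intraspecies) but is configurable; data-derived intraspecies
  toxicokinetic factors have been argued to support 20–21.

## Known limitations

- Absolute doses/MOEs/PFs depend on the illustrative parameterization
  (see above); use site-specific configs for absolute work.
- The dermal model has no glove–skin gap reservoir (no NMP accumulation
  between glove and skin — conservative) and no donor depletion.
- Breakthrough time is ignored: a glove is characterized by its
  steady-state permeation rate only, so short task durations are
  penalized relative to reality for thick gloves.
- Metabolites are lumped into clearance; only parent NMP in blood is
  dose-relevant here.

## A worked pass through the numbers

```{r example, eval = FALSE}
recs <- reference_permeation_data()
s <- category_summary(recs, "maximal", kp_skin_defaults[["neat"]])
s
#> Glove category: maximal (n = 20 quantifiable records)
#>   Kp glove (cm/h): mean 7.7e-06 (range 2.9e-06 - 4.7e-05)
#>   Kp net, gloved skin (cm/h; Kp skin 0.00205): mean 7.7e-06 (range 2.9e-06 - 4.6e-05)

spec <- build_scenarios()[[3]]       # high-end neat NMP, no respirator
none <- run_scenario(spec, NULL, horizon = "acute")
gl <- run_scenario(spec, s, horizon = "acute")
protection_factor(none$dermal_only_cmax,
                  gl$dermal_only_cmax[gl$kp_level == "mean"])
```

The full grid is produced by `assess()` (or `cmd_assess()`, which also
writes delimited reports); see the README for a complete worked example
with its printed output.
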
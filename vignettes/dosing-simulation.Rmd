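---
title: "Model, simulation conditions and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, simulation conditions and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the pharmacokinetic model and its assumptions, the conditions under which
the virtual-population simulations are run, the estimation algorithm, the
numerical choices that matter, and the limits of what the bundled synthetic
data can demonstrate.

## 1. The pharmacokinetic model

Both piperacillin and tazobactam are described by a mammillary
two-compartment model with zero-order infusion input into the central
compartment and first-order elimination from it. With clearance CL,
central and peripheral volumes V1 and V2 and intercompartmental clearance
Q, the micro-constants are k10 = CL/V1, k12 = Q/V1, k21 = Q/V2, and the
central concentration is a sum of two exponentials with hybrid rate
constants α, β satisfying α + β = k10 + k12 + k21 and α·β = k10·k21.

The covariate model ties the parameters to three patient-level quantities,
each centred at its reference value (the medians of the healthy-adult
cohort the model was estimated in):

* **CE** — absolute CKD-EPI creatinine eGFR in mL/min (i.e. the
  1.73 m²-normalised value rescaled by the subject's BSA/1.73), reference
  108.25 mL/min. Acts as a power on CL for both drugs (exponents 1.16 and
  0.857). This is the only route by which renal function enters the model,
  so the steady-state *average* concentration is exactly rate/CL and falls
  monotonically with eGFR, while Vss = V1 + V2 (8.83 L for piperacillin) is
  renal-function-invariant.
* **WT** — total body weight, reference 61.7 kg; exponential effect on V2.
  Assigning body size to the peripheral rather than central volume is
  consistent with the hydrophilicity of both drugs: the peripheral
  compartment tracks interstitial and lean-tissue water, which scales with
  weight.
* **LBM** — lean body mass, reference 50.08 kg; power effect (exponent
  2.50) on piperacillin's Q only.

Interindividual variability is log-normal, θᵢ = θ·exp(ηᵢ) with η ~ N(0, ω²),
on piperacillin CL (ω = 7.17% CV) and V1 (18.4%) and tazobactam CL
(6.95%); Ω is diagonal. Residual error is proportional, y = f·(1 + ε) with
ε ~ N(0, σ²), σ = 13.4% / 13.5%. The unbound fraction of piperacillin is a
fixed fu = 0.7; tazobactam concentrations are simulated but carry no
pharmacodynamic target, because the %fT>MIC machinery is defined on the
free piperacillin concentration.

All parameters ship in `inst/extdata/piptaz_parameters.json`
(a versioned schema users can copy and edit); `pk_model()` reads it.

### Units and renal estimators

Serum creatinine and cystatin C are in mg/dL throughout, with no unit
auto-detection. Five renal estimators are implemented
(`crcl_cockcroft_gault()`, `egfr_mdrd()`, and the 2021 race-free CKD-EPI
creatinine / cystatin / combined forms in `egfr_ckdepi()`), but the model
covariate CE is always the BSA-adjusted CKD-EPI creatinine value: the
others are exposed for exploration only. The combined CKD-EPI form uses
the standard −0.323 exponent on the below-knot cystatin term, making all
estimators strictly decreasing in both biomarkers.

The formulas behind the cohort's BSA and LBM summaries are not uniquely
determined by the data; the package defaults to Du Bois-Du Bois BSA
(0.007184·H^0.725·W^0.425) and James LBM (1.10·W − 128·(W/H)² for males,
1.07·W − 148·(W/H)² for females), which reproduce the cohort medians from
median height and weight within about 2%. Mosteller BSA is available as a
configurable alternative; both choices are arguments, not constants.

## 2. Virtual populations and simulation conditions

Two cohort designs are used, mirroring the two simulation studies the
model supports.

**Free mode** emulates a general adult population with normal renal
function. Demographics are drawn per sex from truncated normal
distributions (configured in `inst/extdata/population_defaults.json`):
means at the cohort medians, SDs chosen so the observed min–max range
spans the central 95% (SD = range/3.92), truncated to physiological adult
bounds (age 19–55, height 140–210 cm, weight 35–130 kg, creatinine
0.3–2.0 mg/dL). eGFR is then *computed* from the drawn covariates and the
subject is kept only if it falls in [90, 130) mL/min. "Normal renal
function" is deliberately operationalised as the same 90–130 window used
by the category simulation, so breakpoint claims from the two designs are
commensurable. The rejection sampler raises an error rather than spinning
if a window rejects more than 99.99% of draws.

**Category mode** isolates renal function: eGFR is drawn uniformly within
the category bounds (0–20, 20–40, 40–90, 90–130, 130–180 mL/min) and
weight and lean body mass are fixed at the study medians (61.7 / 50.08
kg). Uniform-within-bin is the assumption-minimal choice over a bounded
interval; no within-bin distribution is implied by the category design
itself. Note that PTA at an MIC near the attainment boundary is sensitive
to this choice — see §5.

Subjects are sampled one at a time, so enlarging a cohort under the same
seed preserves the first subjects bit-for-bit. Each subject's η vector is
drawn once and reused across regimens: regimen comparisons are paired,
which removes most Monte Carlo noise from PTA *differences* and guarantees
the dose-monotonicity property tested in the suite.

**Residual error is excluded from PTA simulations.** The proportional ε
represents assay noise around the measured concentration; target
attainment is a property of the subject's underlying exposure, so PTA is
computed from model-predicted (noise-free) individual profiles. ε is
applied only when generating synthetic *observed* datasets.

**Steady state, 24-h window, no loading dose.** %fT>MIC is defined over a
24-h window at steady state. All intermittent intervals used (6, 8, 12 h)
divide 24 h, so the fraction over one dosing interval equals the fraction
over the 24-h window and the package evaluates one interval. Continuous
infusions are evaluated at their flat steady state Css = rate/CL; no
loading dose is modelled, which is immaterial at steady state.

**Attainment is non-strict** (fT ≥ target fraction). At machine precision
this matters only for the 100% target under continuous infusion, where the
free steady-state concentration is constant: a subject with fu·Css just
above the MIC attains exactly 100% and must count.

## 3. Estimation: Laplace with interaction

`pkfit()` maximises the marginal likelihood of the nonlinear mixed-effects
model. The integral over each subject's η is approximated by the Laplace
method at the posterior mode η̂:

−2 log Lᵢ = 2 g(η̂) − d·log 2π + log det H,   g(η) = −log p(yᵢ|η) − log p(η),

with H the Hessian of g at the mode. The residual variance is evaluated at
the conditional prediction (σ²f(η̂)², "interaction"). This is the same
statistical model as classical FOCE-I; the approximation of the integral
differs, and the package documents itself as Laplace rather than imitating
FOCE-I's linearisation conventions, because Laplace is fully specified and
can be checked against numerical quadrature — the test suite verifies
agreement within 0.5 OFV units against adaptive integration on
single-subject problems, and exactness in the analytic case where the
prediction does not depend on η.

Numerical design of the estimator:

* Structural parameters constrained positive (CL, V1, Q, V2) are estimated
  on the log scale; covariate exponents are unbounded; ω and σ are
  estimated as log-SDs. Q's population value is fixed (not estimated) by
  default, matching the final model's parameterisation.
* The inner problem (the η mode) is solved by guarded Newton iteration
  warm-started from the previous outer iteration's mode, with the gradient
  assembled from the analytic derivative of the log-density with respect
  to the prediction and a central-difference Jacobian of the prediction in
  η (step 1e-5); the Hessian uses central differences of that gradient
  (step 1e-4). Modes are polished to a gradient norm of 1e-10, which makes
  the outer objective smooth: the inner solver's tolerance never leaks
  into outer finite differences. The per-subject kernel is compiled (C++);
  an R reference implementation of the identical algorithm is kept and the
  suite asserts both agree to 1e-6.
* The outer optimiser is PORT (`nlminb`) with an explicit central-difference
  gradient (step 1e-5, chosen well above the objective's noise floor),
  relative tolerance 1e-7, and restarts from the incumbent when PORT
  reports false convergence; optional multi-start from jittered initial
  values guards against local minima. Default starting values are generic
  (CL 10, V1 5, V2 3 L, exponents 1, ω 10%, σ 15%), not the published
  estimates.
* Standard errors come from the numerical Hessian of the OFV at the
  optimum (covariance 2·H⁻¹); on the log scale the SE is already a
  relative SE. η shrinkage is 1 − sd(η̂)/ω.

`covariate_step()` implements forward selection (add when OFV drops by
more than 6.635, χ² p < 0.01) and backward elimination (retain when
removal raises OFV by at least 10.83, p < 0.001) over the covariate terms
of the structural model (CE-power on CL, LBM-power on Q, WT-exponential on
V2). Fits are cached by model signature within a stepping run.
`pk_bootstrap()` resamples subjects with replacement and refits from the
original estimates; non-convergent resamples are counted, not hidden.
`vpc()` simulates replicate datasets (new η and ε) at the observed design
and compares observed 10/50/90th percentiles with the simulated
percentiles' 95% intervals, binned by nominal sampling time; prediction
correction is unnecessary in a single-dose, single-dose-level design.
Observations below the limit of quantification are not modelled; the
predose sample is a structural zero flagged `MDV = 1` and excluded from
the likelihood.

## 4. The synthetic study generator

`generate_study()` reproduces the statistical structure the estimator
assumes: n subjects (default 12, two-thirds male), a single 4 g/0.5 g dose
infused over 30 min, sampling at 0, 0.5, 0.75, 1, 2, 3 and 6 h, covariates
drawn uniformly within the sex-specific observed ranges, individual
parameters θ·e^η, noiseless profiles from the analytic solver, and
proportional error truncated to positive concentrations by resampling ε
(clipping would create a point mass at zero that the likelihood cannot
represent). Datasets round-trip losslessly through the NONMEM-convention
CSV reader/writer (17 significant digits).

What the generator does *not* emulate: assay-level artifacts (carryover,
calibration drift, heteroscedasticity beyond the proportional model),
correlation between covariates beyond what the sex-specific ranges induce,
multi-dose designs, and disease-state pathophysiology (capillary leak,
hypoalbuminemia, augmented clearance mechanisms). Passing the
parameter-recovery and VPC tests therefore demonstrates the internal
consistency of estimator and simulator — that the code correctly fits data
with exactly the assumed structure — not that the model describes any
particular patient population.

### Validation problem sizes

The suite's calibration experiments use sizes chosen to make the
statistical assertions sharp while keeping the default test run short: a
100-subject study (seeded) for parameter recovery, where the well-informed
structural parameters (CL, V1, V2) recover within 10% and the covariate
exponents within 25%; twenty 20-subject replicates each for the covariate
stepping power (CE effect present) and type-I (effect absent) experiments,
with IIV on CL only so the selection signal is isolated; 400 simulated
replicates on a 12-time-point, 100-subject design for the VPC
self-consistency check. All stochastic tests run under a fixed seed (101).

## 5. Numerical choices and degenerate inputs

* **Steady state by closed form, not simulation.** Each exponential term
  accumulates geometrically with factor e^(−λτ)/(1 − e^(−λτ)); the suite
  checks the closed form against brute-force superposition of 60 doses to
  1e-6 and against a piecewise ODE integration (the infusion on/off switch
  is integrated as two initial-value problems; integrating across the
  discontinuity naively costs several percent accuracy).
* **Repeated eigenvalue.** When α and β coincide within 1e-10 relative,
  the impulse response degenerates to e^(−αt)(1 − (α − k21)t) (the
  l'Hôpital limit of the biexponential, verified in the suite as the limit
  of nearly-degenerate distinct-root evaluations); steady state in this
  measure-zero case falls back to explicit accumulation until terms reach
  machine zero.
* **%fT>MIC by crossing location.** The profile is evaluated on a grid of
  240 points per interval to bracket threshold crossings (the profile is
  unimodal per interval, with its peak at end of infusion — a grid point);
  each crossing is refined by bisection to 1e-4 h. Comparisons are strict
  (concentration must exceed the threshold), and a whole-grid-above
  profile short-circuits to exactly 1.
* **Breakpoint tie-breaks.** The PK/PD breakpoint is the highest MIC with
  PTA ≥ 0.90 (non-strict). A breakpoint at the top of the grid is flagged
  right-censored; a grid whose lowest MIC already fails returns `NA`
  rather than 0.
* **CFR without interpolation.** Every distribution MIC must match the PTA
  grid exactly; silently interpolating between doubling dilutions would
  fabricate attainment information.
* **Within-bin eGFR sensitivity.** For the stringent 100%fT>MIC target
  under 4 g q6h with a 3-h infusion in the 90–130 mL/min category, the
  free steady-state trough crosses 2 mg/L at an eGFR of about 120 mL/min:
  under the uniform within-bin assumption PTA at 2 mg/L evaluates to
  ≈ 0.73 and the breakpoint to 1 mg/L, whereas a within-bin distribution
  concentrated near the bin centre would push PTA at 2 mg/L above 0.90.
  The same regimen at 6 g attains 2 mg/L with PTA ≈ 0.96 under the uniform
  assumption. Reported breakpoints one dilution either side of an
  attainment boundary should be read with this sensitivity in mind.

## 6. Known limitations

* The model was estimated in twelve healthy adults with a narrow renal
  function range; extrapolation of the CL–eGFR power law to the 0–20 and
  130–180 mL/min categories is exactly that — extrapolation.
* fu is fixed at 0.7; protein-binding variability (pronounced in critical
  illness) is not modelled.
* Ω is diagonal (no CL–V1 correlation), the residual model is purely
  proportional, and elimination is linear — no saturable clearance.
* The estimator supports the single-dose design the study used;
  multi-dose estimation datasets are rejected rather than mis-handled.
* Bundled MIC distributions are synthetic placeholders in EUCAST-export
  shape; population-level CFR conclusions require real, versioned
  susceptibility data supplied by the user.
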
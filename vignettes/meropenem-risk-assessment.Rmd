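---
title: "Meropenem target non-attainment risk: models, evaluation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meropenem target non-attainment risk: models, evaluation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meropta)
```

## The clinical problem

Meropenem is a first-line empirical antibiotic in critically ill patients.
Its efficacy tracks the time the drug concentration stays above the
pathogen's minimum inhibitory concentration (MIC); a demanding but common
target is 100% T>MIC — the concentration never falls below the MIC over the
dosing interval.  Under intermittent q8h infusion the concentration is at
its minimum just before the next dose, so the target reduces to a single
question: *is the 8-h trough concentration (C8h) above the MIC?*  Renal
function is the dominant determinant: meropenem is cleared mostly by the
kidney, so patients with high creatinine clearance are the ones at risk of
sub-therapeutic troughs under standard dosing (1 g, 0.5 h infusion, q8h).

`meropta` computes the probability that a given patient on standard dosing
misses this target, from nothing more than the inputs available at therapy
start: the Cockcroft–Gault creatinine clearance (CLCR, or its four
determinants) and whatever is known about the pathogen.

## The two risk engines

### Regression engine

The primary engine is a linear regression on the double natural-log scale,

$$\ln C_{8h} = a + b \,\ln \mathrm{CLCR} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with risk of target non-attainment obtained from classic linear-model
prediction theory: a future patient's $\ln C_{8h}$ follows a location–scale
t distribution with $n-2$ degrees of freedom, centred at the fitted line,
with standard deviation
$\sigma\sqrt{1 + 1/n + (\ln \mathrm{CLCR} - \bar x)^2 / S_{xx}}$
(the usual new-observation variance including the leverage term).  The risk
is then

$$P(C_{8h} < \mathrm{MIC}) =
  T_{n-2}\!\left(\frac{\ln \mathrm{MIC} - \hat y}{\widehat{se}}\right).$$

Whether the original spreadsheet tool used t or normal quantiles, and
whether it carried the leverage terms, is not documented; both are
implemented (`gaussian_approx` flag) and the difference is negligible at
the training sizes involved ($n$ in the hundreds; the leverage term adds
less than 1% to the predictive SD except at the extreme ends of the CLCR
range).  The t/leverage variant is the default because it is the exact
small-sample theory.

The back-transformed point prediction `exp(a + b ln CLCR)` is reported as
the *median* of the lognormal predictive distribution, not its mean; the
risk statement is invariant to this choice because probabilities are
computed on the log scale.

The engine is only used inside its applicability range, CLCR 25–255
mL/min; outside it the functions refuse (error) rather than extrapolate,
which mirrors the disclaimer behaviour of a clinical tool.  A second
disclaimer is attached to any result where CLCR < 50 mL/min meets a
contributing MIC ≥ 8 mg/L — the regime where the log-log line materially
underestimates risk (see "Why the engines disagree at low clearance").

### Population-PK engine

The benchmark engine is a two-compartment model with zero-order infusion
input, solved in closed form (macro-constant bi-exponential solution,
superposed over doses; a numerical ODE solution is used only as an oracle
in the tests).  Covariates follow the renal-drug convention:

* **CLCR on clearance, piecewise linear.**  Anchored so that an anuric
  patient (CLCR = 0) retains `nonrenal_fraction` (default 0.2) of the
  typical clearance, and clearance equals `cl_pop` at the reference CLCR.
  The knot (`clcr_breakpoint`, `slope_ratio`) exists so a genuine
  two-slope model can be configured; the default is a single line through
  the two anchors, because no published knot location is available to us.
  Both anchors hold exactly for any knot/ratio configuration — the slopes
  are solved, not supplied.
* **Weight on central volume, power model** (`wt_exponent`, default 0.75).
* **Albumin on peripheral volume, linear** (`alb_slope`, default −0.3 per
  g/dL: hypoalbuminaemic patients have larger peripheral volumes), floored
  at 0.1 L so pathological inputs cannot produce a non-positive volume.

Interindividual variability (IIV) is lognormal and independent across
parameters (no correlation structure is documented for meropenem in this
population; a correlated model could be added, but independent IIV is the
conservative default and all tests are parameter-agnostic).  Residual
error is combined proportional + additive, truncated at zero with the
truncation rate recorded.

The shipped parameter values (CL 12.5 L/h at CLCR 100 mL/min, V1 10.5 L at
73 kg, Q 15 L/h, V2 12 L, ω ≈ 0.25–0.3, 20% proportional + 0.5 mg/L
additive residual error) are *typical two-compartment meropenem values for
critically ill adults*, shipped as a JSON file
(`inst/extdata/poppk_default.json`) precisely so that published estimates
for a specific model can be substituted by editing one file.  Nothing in
the package's logic or tests depends on these particular numbers.

**Which dose is assessed.**  "C8h" is the trough of the *first* dose by
default (`n_doses = 1`): at therapy start, before any accumulation, this
is the conservative reading for an empiric-therapy decision.  Steady state
is one configuration away (`n_doses = 6` puts the assessment at the sixth
trough, where accumulation is essentially complete for meropenem
half-lives).

**Total vs unbound drug.**  Risk is computed on total concentration by
default (`unbound_fraction = 1`).  Meropenem protein binding is low
(~2%), so the distinction is minor; the flag exists for users who want the
unbound-concentration reading of the target.

**IIV only vs IIV + residual.**  For *risk* the default simulates IIV
only: risk should reflect true between-patient variability in exposure,
not assay noise.  For *observation prediction* (the prediction-error
evaluation) residual variability is included, since the comparator is a
measured concentration.  Both are flags.

## Pathogen modes and CFR

Three input modes, resolved with precedence MIC > pathogen > breakpoint:

1. **Known MIC** — risk at that MIC.
2. **Known pathogen, unknown MIC** — cumulative-fraction-of-response
   analysis over the pathogen's MIC frequency distribution:
   $\text{risk} = \sum_i f_i\, P(C_{8h} < \mathrm{MIC}_i) = 1 -
   \mathrm{CFR}$.  Every bin is evaluated *exactly at its MIC* — the risk
   engines are analytic (or simulable) at arbitrary MIC, so no grid
   interpolation is ever done; this avoids interpolation bias in
   distribution tails.  Top-censored bins ("≥ x mg/L") are evaluated at
   the stated concentration with a warning: the resulting risk is an
   underestimate, which is documented rather than hidden.
3. **Nothing known** — single-MIC risk at a user-chosen breakpoint.

Distributions are versioned CSV files with a mandatory provenance label
that is echoed in every result; there is no live download.  The packaged
file `mic_distributions_synthetic.csv` is a *synthetic* fixture shaped
like published wild-type distributions, for tests and examples only — it
is labelled synthetic in both filename and provenance string and must not
be used clinically.

Risk is displayed with the traffic-light rule green ≤ 10% < orange ≤ 50% <
red.  The *cohort-level* pathogen summary uses strict bands (median below
10%, 10–50%, above 50%); the two rules differ at exactly 10% and both are
implemented and named (`classify_risk` vs the summary's `band` column).

## The two-step evaluation

Routine TDM data is sampled at variable times, so troughs cannot be
compared to the regression directly without discarding most samples.  The
package therefore implements the two-step strategy:

* **Step 1** checks that the PK engine predicts measured concentrations at
  *their actual sampling times*: per-sample prediction error (default sign
  convention `predicted − observed`, so underprediction yields negative
  bias — matching how such biases are conventionally reported; the
  opposite convention is a flag), bias as the *median* error (paired, as it
  is, with a 50% inter-quartile prediction-error interval; a mean-based
  variant is a flag), relative errors against the observed value.
* **Step 2** uses the step-1-validated PK engine as benchmark: paired
  risks from both engines for every patient at the 8 MIC levels 0.125–16
  mg/L, agreement by Lin's concordance correlation coefficient (CCC),
  per MIC, per renal-function stratum (all patients vs CLCR > 50 mL/min)
  and pooled over all patient × MIC pairs.  Confidence limits use the
  Fisher z transform with Lin's asymptotic variance (the corrected form
  involving the Pearson r and the standardised location shift);
  the success rule is the one-sided 95% lower limit of the pooled CCC
  exceeding 0.95, graded on the McBride scale (poor < 0.90, moderate
  0.90–0.95, substantial 0.95–0.99, almost perfect > 0.99).
  The PK engine simulates *one* virtual cohort per patient and reuses it
  across all MICs, which makes the per-patient risk curve exactly
  monotone in MIC and removes Monte-Carlo noise from the paired
  comparison.

### Why the engines disagree at low clearance

The log-log line sends $C_{8h} \to \infty$ as CLCR → 0: it cannot separate
renal from non-renal elimination.  The PK engine's clearance floors at the
non-renal fraction, so its predicted troughs at low CLCR are lower — and
its risks at high MIC higher — than the regression's.  In the package's
end-to-end synthetic replication (cohort generated from the piecewise
clearance truth, regression fitted to the simulated troughs) this
structural mismatch reproduces qualitatively: pooled CCC restricted to the
CLCR > 50 mL/min stratum exceeds the full-cohort pooled CCC.  This is what
motivates the high-MIC/low-CLCR disclaimer flag.

## The synthetic cohort generator

No patient-level dataset is shipped; the generator *is* the reference
cohort.  Its defaults encode a critically ill TDM population: median CLCR
86.4 mL/min (5th–95th percentile 35.4–161), age 57.0 y (33.7–79.0), weight
73.0 kg (50.0–97.3), albumin 2.5 g/dL (2.3–3.2), 65.2% male, mean 5.7
samples per patient, sampling offsets with median 6.2 h after the last
dose (5th–95th 3.72–8.13 h).

Design choices, made once:

* **Lognormal marginals** for CLCR, age, weight, albumin: positive,
  right-skewed clinical variables.  Calibration solves (median, 95th
  percentile) for (µ, σ) and *validates* the implied 5th percentile,
  warning when it is off by more than 15%.  For the default CLCR and age
  targets the warning fires: those lower tails are heavier than lognormal,
  and the generator says so rather than silently matching two of three
  quantiles.  A point-mass spec (all three targets equal) is supported for
  degenerate tests.
* **Independence across characteristics** — no correlation structure is
  documented for this population.  Real cohorts correlate age, weight and
  CLCR; synthetic validation results are therefore slightly optimistic
  about covariate-combination extremes.
* **Serum creatinine is derived, not drawn**, by inverting
  Cockcroft–Gault from the drawn CLCR, so every record is internally
  consistent (the two patient input paths of the tool agree on every
  synthetic patient by construction).
* **Sampling offsets** are beta-distributed on [0, interval], least-squares
  calibrated to the three quantile targets.  The printed 95th percentile
  (8.13 h) exceeds the 8-h interval — real wards occasionally delay the
  next dose — and is clamped to the interval; the achieved median lands
  within ~0.15 h of the 6.2 h target, within the generator's stochastic
  tolerance.
* **Samples per patient**: 1 + Poisson(mean − 1), guaranteeing at least
  one sampled interval while keeping the mean exact.

What passing tests on this generator do *not* show: performance under
correlated covariates, under non-lognormal renal-function tails, under
irregular dosing histories (doses are uniform q8h in generated data,
though the evaluation functions accept arbitrary dose times), or against
real assay error structure.

## Calibration of the shipped regression coefficients

The package must ship *some* regression coefficients for the assessment
functions to be usable out of the box, but the authentic ones belong to
the original tool's development data.  The shipped set
(`inst/extdata/regression_default.json`) was calibrated once against the
synthetic reference cohort: 500 screened synthetic patients, one simulated
individual trough per patient from the default PK model (IIV included),
log-log OLS fit.  Fitting to *individual* simulated troughs — rather than
per-patient median predictions — matters: it is how the original tool was
built (observed troughs from a trial), and it puts the full
between-patient variability into the regression's residual SD
(σ ≈ 1.0 on the log scale) so that the two engines' predictive
distributions are commensurable.  Substituting authentic published
coefficients is a one-file edit.

## Numerical choices

* Quantiles everywhere are type-7 (R default, linear interpolation);
  documented because the 50% prediction-error interval depends on it.
* The two-compartment solution handles `q = 0` by an explicit
  one-compartment branch (the macro-constant form divides by β → 0).
* Zero residual SD in the regression gives exact 0/0.5/1 risks (point-mass
  predictive distribution) rather than NaN.
* Negative simulated concentrations after additive error are truncated at
  zero; the truncation rate is attached to the simulation result.
* CCC degenerate cases: two identical constant vectors → 1, two different
  constant vectors → 0; |CCC| = 1 returns degenerate confidence limits
  with a warning.
* All simulation entry points accept an integer `seed` and restore the
  global RNG state afterwards, so a fixed seed reproduces results bit for
  bit without perturbing the caller's stream.

## Problem sizes

The shipped tests and the acceptance script use: 10,000 patients for
generator calibration checks, 155 patients (the evaluation-cohort size)
for the end-to-end replication with 1,000–2,000 virtual patients per real
patient, 20,000 replicates for the Monte-Carlo-vs-closed-form risk cross
checks, and 10^6 draws for the regression-risk sampling oracle.  These
sizes keep Monte-Carlo error an order of magnitude below every tolerance
asserted.

## Known limitations

* The shipped PK parameters and regression coefficients are defaults, not
  estimates from clinical data; absolute risks from a default install are
  illustrative until site-specific or published models are dropped into
  the two JSON files.
* Only the 100% T>MIC target at the 8-h trough is implemented; %fT>MIC
  targets over the full interval would need the time-above-MIC integral
  (the analytic solution makes this an extension point, not a redesign).
* No renal-replacement or ECMO kinetics: such patients are excluded by the
  inclusion screen, as in the tool's intended use.
* Cockcroft–Gault only; no CKD-EPI/MDRD, no paediatrics.
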
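---
title: "Personalizing HbA1c with the apparent glycation ratio: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing HbA1c with the apparent glycation ratio: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pa1c)
```

## The kinetic model

At glycemic steady state, the fraction of glycated hemoglobin reflects a
balance between the glycation rate — proportional to the glucose
concentration inside the red cell — and red-cell turnover. Because RBC
glucose uptake is carrier-mediated, the effective glucose term saturates:
the model works with the composite

$$X(\mathrm{MG}) = \frac{1}{\mathrm{MG}} + \frac{1}{K_M},$$

where MG is the mean glucose in mg/dL and $K_M = 472$ mg/dL is the
Michaelis constant of RBC glucose transport. A person's **apparent
glycation ratio** (AGR, mL/mg) is then defined so that their steady-state
A1c (NGSP %) satisfies

$$\mathrm{A1c} = \frac{100}{1 + 10^5\, X(\mathrm{MG})/\mathrm{AGR}},
\qquad\text{equivalently}\qquad
\mathrm{AGR} = \frac{10^5\, X(\mathrm{MG})}{100/\mathrm{A1c} - 1}.$$

The AGR summarises everything individual about the A1c–MG relationship —
RBC lifespan, membrane transport, glycation kinetics — in one constant.
Once calibrated it is assumed stable, and a later measured A1c can be
mapped onto the scale of a **reference glycator** with
$\mathrm{AGR}_{\mathrm{ref}} = 65.1$ mL/mg:

$$\mathrm{pA1c} = \frac{100}
{1 + (\mathrm{AGR}/65.1)\,(100/\mathrm{A1c} - 1)}.$$

Two structural identities pin the implementation down and are enforced in
the test suite:

1. **Reference identity.** `compute_pa1c(a, 65.1)` equals `a` for every
   A1c: the reference glycator's A1c needs no correction, so 65.1 mL/mg
   is the unique fixed point of the personalization transform.
2. **A1c-independence.** For a fixed mean glucose $m$,
   `compute_pa1c(a, compute_agr(m, a))` is constant in $a$ and equals the
   reference curve `reference_ea1c(m)` — the personalization cancels the
   individual A1c and leaves only the glucose signal. This holds to
   machine precision (the suite asserts $10^{-12}$ relative).

A third, softer anchor is physiological: `reference_ea1c(154)` ≈ 7.0%,
the familiar clinical correspondence between an A1c of 7% and a mean
glucose of about 154 mg/dL. High glycators (AGR > 65.1) run A1c levels
above the reference curve for the same MG, and their pA1c is corrected
downward.

The forward model saturates at $100/(1 + 10^5/(\mathrm{AGR}\,K_M))$
(≈ 23.5% for the reference glycator); `estimate_mg()` refuses A1c values
at or above this asymptote, where no finite mean glucose exists.

Units follow the dominant printed convention: AGR in mL/mg throughout,
glucose conversions with divisor 18.016 (glucose molar mass / 10), and
the NGSP↔IFCC master equation IFCC = 10.929·(NGSP − 2.15) with half-up
integer rounding for reported mmol/mol. Note that with this equation a
mean A1c of 10.7% converts to 93 mmol/mol; published tables sometimes
print 94, presumably converted from an unrounded mean. The package
follows the master equation and does not reconcile such rounding
artifacts.

## The wear protocol and CGM metrics

The package targets a protocol of three consecutive blinded sensor wears
of 10–14 days each, with at most 48 h between wears and sensor-reportable
glucose 40–500 mg/dL at 15-minute cadence. QC (`qc_wearset()`) marks a
wear valid when its timestamp span covers at least 10 days — span, not
reading count, so interior dropouts do not invalidate a wear — and marks
the protocol valid when all three wears are valid and every inter-wear
gap is ≤ 48 h. Protocol-invalid subjects are excluded from the cohort
stage with a logged reason.

Metric conventions, each pinned by tests because the consensus standard
leaves them unstated:

- **Band boundaries**: 70 and 180 mg/dL count as *in range*; the
  below/above bands are strict inequalities. The three exclusive bands
  (< 70, 70–180, > 180) always sum to 100%.
- **Population SD** (divisor $n$) for the CV. At a full protocol's
  ~3,000 readings the difference from the sample SD is negligible, but a
  single convention keeps tests exact.
- **Reading-weighted pooling**: pooled metrics are computed over the
  concatenated readings of the selected wears, which equals
  time-weighting at fixed cadence. The calibration MG pools wears 1–2;
  the evaluation MG pools all three wears (accepting the overlap with
  the calibration window, which is how the protocol this package models
  was analysed).
- **Clamp-then-compute**: out-of-range readings are clamped to
  [40, 500] on ingestion and metrics are computed on clamped values —
  what the device would report.

## The synthetic cohort

No public dataset accompanies the protocol, so `simulate_cohort()`
generates one with known ground truth. Its defaults are the study
conditions the package emulates: ~64 subjects; per-subject mean glucose
drawn from Normal(257, 57) mg/dL truncated to [80, 450]; glucose CV from
Normal(44, 10)% truncated to [23, 62]; three wears of 10–14 days at
15-min cadence with gaps up to 48 h.

The trace process is a stationary AR(1) (a discretised
Ornstein–Uhlenbeck process, mean-reversion 0.5/h, i.e. ~2 h correlation
time) plus one diurnal sinusoid and Poisson meal-excursion pulses
(3/day expected, exponential 1.5 h decay). This particular process is a
design choice — no trace model is published for the protocol — selected
because it gives *independent* control of mean and CV: the composite
signal is linearly rescaled so the realized pre-clamp mean and
population CV equal the subject's targets exactly, then clamped to the
sensor range. Clamping can shift realized moments for high-CV subjects;
targeting is deliberately pre-clamp and the pipeline consumes the
clamped readings, exactly as it would real sensor data.

Two generator parameters have no published value and are explicit knobs,
chosen once:

- **Between-subject AGR spread**: Normal(65.1, 6) mL/mg truncated
  positive. An SD of 6 (~9% of the mean) produces the clinically
  familiar situation in which two subjects with identical mean glucose
  differ by ~1% A1c — enough heterogeneity for personalization to
  matter, not so much that measured A1c becomes useless.
- **Assay imprecision**: multiplicative lognormal noise with 2% CV for
  the laboratory assay and 4% for point-of-care, typical of NGSP-
  certified methods; both are configurable and can be set to 0 for
  noise-free runs.

A1c at each visit is generated by the *forward* kinetic model from the
trailing mean of the clamped readings (visit 2: wears 1–2 pooled;
visit 3: all readings), so with assay noise disabled the analysis
pipeline recovers every subject's true AGR exactly — a round-trip the
acceptance suite asserts to $10^{-6}$ mL/mg. Determinism is structural:
one master seed, with per-(subject, wear, purpose) substreams derived by
a stable string hash, so identical configurations produce byte-identical
CSV tables regardless of evaluation order.

What the generator does *not* emulate: sensor error (MARD), insulin and
meal pharmacokinetics, within-subject AGR drift, or the heavy-tailed
behavioural structure of real glucose traces. Passing tests therefore
demonstrate that the *pipeline arithmetic* is correct and that
personalization recovers planted glycation heterogeneity — not that real
cohorts will show any particular R².

## The cohort statistics

`run_pipeline()` chains QC → metrics → AGR calibration (laboratory A1c
only; point-of-care A1c is never used to calibrate) → pA1c → the
statistical stage:

- `compare_predictors()` fits evaluation MG against laboratory A1c, POC
  A1c and pA1c on the identical subject set, plus POC against laboratory
  A1c, reporting slope, intercept, R², r and RMSE = $\sqrt{RSS/n}$. The
  pA1c–MG relationship is mildly nonlinear through the kinetic model; a
  straight line is fitted anyway, matching how such comparisons are
  reported. (In the noise-free limit the pA1c equals the reference curve
  at the evaluation MG, so a fit on the reference-curve scale is exact;
  tests use that scale for the R² = 1 check.)
- Welch (unequal-variance) t-tests compare metabolic variables between
  children and young adults; the unequal-variance form is the safer
  default when group variances are unknown.
- Stepwise-AIC covariate adjustment runs bidirectionally from the
  primary-predictor model, scoped up to age group, sex, Tanner stage,
  income, hemoglobin AS, G6PD, ferritin, hemoglobin and RDW-CV, with the
  `extractAIC` convention $n\ln(RSS/n) + 2p$ (only differences matter).
  Complete cases only; aliased designs error naming the columns.
- `correlation_power()` gives the design power for detecting an A1c–MG
  correlation, by the Fisher-z closed form
  $\Phi(\sqrt{n-3}\,\operatorname{atanh}\rho - z_{1-\alpha/2})$ or by
  Monte-Carlo simulation of bivariate-normal cohorts; the two agree
  within simulation error and give ≈ 0.99 at $\rho = 0.52$, $n = 60$,
  $\alpha = 0.05$. p-values are computed throughout but never used as
  acceptance surfaces, being cohort-specific.

## Problem sizes and numerical choices

The test suite runs its simulations at sizes chosen to make each
assertion sharp while keeping the suite quick: moment-fidelity checks at
2,000 profile draws; trace-level pipeline tests at 4–6 subjects; the
CV–hypoglycemia sign property at 30 subjects; and the replicate study of
$\Delta R^2 = R^2(\mathrm{pA1c}) - R^2(\mathrm{A1c})$ at 200 cohorts of
64 subjects. The replicate study simulates at the subject level (target
MG as the realized MG — the steady-state limit of the trace generator,
which rescales each trace to its target exactly), since trace-level
detail is irrelevant to a property of the A1c machinery; with the
default AGR spread and assay noise, pA1c out-fits measured A1c in
essentially every replicate, and the suite requires ≥ 95%.

Tie-breaks and degenerate inputs are pinned: Spearman correlation is the
Pearson correlation of mid-ranks and returns 0 with a warning when a
variable is entirely tied; `fit_simple()` refuses constant predictors;
stepwise selection breaks ties deterministically by candidate order;
truncated normals are drawn by inverse-CDF so they are exact and
seed-stable; root-finding for the acceptance fixed point uses `uniroot`
at tolerance $10^{-12}$ on a bracket of [1, 500] mL/mg.

## Limitations

The model is steady-state: the AGR concept is most accurate under stable
glycemia over the RBC lifespan, and no quantitative stability gate is
applied — the CV is reported alongside instead. Calibration and
evaluation windows overlap (wears 1–2 are part of both), which inflates
agreement relative to a prospective design; the package reproduces that
design fact rather than correcting it. The generator's AGR distribution
and assay CVs are modelling choices, so cohort-level R² values from the
simulator are illustrative, not predictions for any real population.
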
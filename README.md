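# pa1c

Personalized HbA1c from continuous glucose monitoring (CGM) via the
apparent glycation ratio.

## The problem

HbA1c (A1c) is widely used as a proxy for mean glucose (MG), but the
A1c–MG relationship varies substantially between individuals: for the same
mean glucose, people glycate hemoglobin at different rates. Where CGM is
unaffordable and clinicians dose insulin from A1c alone — as in much of
sub-Saharan Africa — this variability matters clinically. One proposed
remedy is a *personalized A1c* (pA1c): a brief period of sensor wear is
used to estimate the individual's glycation tendency, and later A1c
measurements are rescaled onto a common reference scale that tracks mean
glucose more faithfully.

`pa1c` implements that analysis end to end for a three-sensor-wear CGM
protocol (three consecutive wears of 10–14 days, ≤ 48 h between wears):

- **CGM metrics** — consensus glycemic metrics per wear and pooled: mean
  glucose, population-SD coefficient of variation (CV), and % time
  < 54, < 70, 70–180, > 180 and > 250 mg/dL, plus wear-protocol QC.
- **Glycation model** — the steady-state kinetic model. With
  X(MG) = 1/MG + 1/K_M (K_M = 472 mg/dL, Michaelis constant of RBC
  glucose transport):

  - AGR = 10⁵ · X(MG) / (100/A1c − 1)  (apparent glycation ratio, mL/mg,
    from a calibration window: MG pooled over wears 1–2 and the
    laboratory A1c at the end of wear 2)
  - pA1c = 100 / (1 + (AGR/65.1) · (100/A1c − 1)), where 65.1 mL/mg is
    the reference-glycator rate constant; pA1c ≡ A1c exactly when
    AGR = 65.1.

- **Cohort analysis** — OLS fits of evaluation MG against laboratory A1c,
  point-of-care A1c and pA1c on the same subject set (slope, intercept,
  R², r, RMSE), Spearman correlation of CV with hypoglycemia time, Welch
  t-tests between age groups, stepwise-AIC covariate adjustment, and the
  Fisher-z / Monte-Carlo power calculation for detecting an A1c–MG
  correlation.
- **Synthetic cohort** — a generator with known ground-truth glycation
  parameters (per-subject target MG, CV and AGR; mean-reverting glucose
  traces with diurnal and meal structure; lognormal assay noise), so the
  whole pipeline is testable without patient data.

## Worked example

```r
library(pa1c)

# one subject: calibration MG 154 mg/dL, laboratory A1c 7.0%
compute_agr(mg = 154, a1c = 7.0)
#> [1] 64.82264        # mL/mg, close to the reference glycator 65.1

# a full synthetic cohort through the pipeline
cfg  <- sim_config(n_subjects = 64, seed = 42)
tabs <- simulate_cohort(cfg)
res  <- run_pipeline(tabs$readings, tabs$visits, tabs$covariates)
res
#> <cohort_result> 64 subjects analyzed, 0 excluded
#>
#> Mean glucose vs A1c variants:
#>  predictor_name  slope intercept r_squared pearson_r  rmse  n
#>         lab_a1c 30.088   -38.970     0.775     0.880 25.50 64
#>         poc_a1c 29.166   -27.970     0.729     0.854 28.02 64
#>            pa1c 39.598  -127.832     0.940     0.970 13.15 64
#>      poc_vs_lab  0.974     0.167     0.948     0.974  0.36 64
#>
#> Spearman (CV, % time < 54 mg/dL): 0.90
#> Design power (rho = 0.52, n = 60): 0.992
```

The fit table is the heart of the analysis: each row regresses the
cohort's evaluation mean glucose (all three wears pooled, mg/dL) on one
A1c variant. Here personalization lifts R² from 0.775 (laboratory A1c) to
0.940 and cuts the RMSE from 25.5 to 13.2 mg/dL — the pA1c removes the
between-subject glycation variance that the generator planted (AGR SD 6
mL/mg), while assay noise keeps the fit short of perfect. The Spearman
row quantifies how strongly glycemic variability drives hypoglycemia
exposure, and the power line is the design calculation: 99% power to
detect an A1c–MG correlation of 0.52 with 60 subjects.

A command-line wrapper covering the same stages ships in
`inst/cli/pa1c`:

```sh
Rscript inst/cli/pa1c simulate --n 64 --seed 7 --out d/
Rscript inst/cli/pa1c analyze  --in d/ --out d/
Rscript inst/cli/pa1c report   --in d/ --out d/
```

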
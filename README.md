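# radcomb

Radiobiological modelling of combined radium-223 alpha-emitter therapy and
external beam radiotherapy (EBRT) in metastatic castration-resistant
prostate cancer (mCRPC).

Ra-223 dichloride and EBRT are often combined in patients with bone
metastases, but the randomized trials that reported outcomes for the
combination used different activities (placebo to 80 kBq/kg), cycle
numbers and EBRT schedules, and no patient-level dosimetry. `radcomb` puts
both modalities on one scale — the 2 Gy-per-fraction equieffective dose
(EQD2) of the linear-quadratic (LQ) model — builds an arm-level virtual
cohort from the published trial summaries, and fits sample-size-weighted
logistic dose-response models for two-year overall survival (2y-OS) and
grade >=2 neutropenia (TOX).

## The model in brief

For EBRT delivering total dose *D* in *n<sub>f</sub>* fractions:

> BED = D (1 + (D/n<sub>f</sub>)/(α/β)),  EQD2 = BED / (1 + d<sub>ref</sub>/(α/β))

For the Ra-223 decay-chain mixture (parent plus six daughters in secular
equilibrium, initial per-nuclide dose rates R<sub>i</sub> =
D<sub>i</sub>·A<sub>inj</sub>·λ), over n<sub>c</sub> cycles:

> BED<sub>RN</sub> = n<sub>c</sub> (ΣR<sub>i</sub>/λ) { RBE<sub>max</sub> +
> ΣΣ R<sub>i</sub>R<sub>j</sub> / [(α/β)(μ+λ) ΣR<sub>i</sub>] }

with RBE<sub>max</sub> = RBE<sub>exp</sub> + d<sub>ref</sub>/(α/β) ·
(RBE<sub>exp</sub>² − 1)/RBE<sub>exp</sub> = 5.96 at the defaults
(α/β = 10 Gy, μ = 1.4 h⁻¹, RBE<sub>exp</sub> = 5, d<sub>ref</sub> = 2 Gy).
At the arm level the modalities combine as

> EQD2<sub>TOT</sub> = EQD2<sub>RN</sub> + f · EQD2<sub>EBRT</sub>

where *f* is the fraction of the arm also receiving EBRT. Each arm then
contributes a grouped-binomial observation (events out of *n*) to a
logistic regression of outcome on EQD2<sub>TOT</sub>, in a fixed-effect
and a random-intercept-per-study variant.

## Worked example

```r
library(radcomb)

arms <- ra223_cohort()                       # 8 arms, 4 trials, 1156 patients
tab  <- build_dose_table(arms, dose_scenario(8, 1))  # 8 Gy in 1 fraction
format_dose_table(tab)
#>   study_id activity_kbq_kg n_patients f_ebrt_pct eqd2_rn eqd2_ebrt_weighted eqd2_tot
#> 1        A              50         33        100   103.2               12.0    115.2
#> 2        A               0         31        100     0.0               12.0     12.0
#> 3        B              25         41         29    34.2                3.5     37.7
#> 4        B              50         39         44    77.4                5.3     82.7
#> 5        B              80         42         36   140.7                4.3    145.0
#> 6        C              50        614         16   154.8                1.9    156.7
#> 7        C               0        307         16     0.0                1.9      1.9
#> 8        D              55         49         29   174.0                3.5    177.5
```

Each row is one trial arm: the EQD2 of its Ra-223 component, the EBRT
component weighted by the fraction of the arm that received EBRT, and
their total. Placebo arms get a radionuclide dose of zero but can still
carry an EBRT dose.

```r
fit_logistic(outcome_dataset(tab, arms, "os_2y"))
#> Weighted logistic dose-response model (fixed, endpoint: os_2y, EBRT: 8 Gy in 1 fr)
#>                beta        SE       z  p value
#> Intercept -1.417498 0.1313597 -10.791  < 2e-16
#> EQD2_TOT   0.004538 0.0009943   4.564 5.02e-06

fit_logistic(outcome_dataset(tab, arms, "tox"), "random_intercept")
#> Weighted logistic dose-response model (random_intercept, endpoint: tox, EBRT: 8 Gy in 1 fr)
#>               beta       SE      z  p value
#> Intercept -4.63493 0.893260 -5.189 2.12e-07
#> EQD2_TOT   0.01295 0.003622  3.576 0.000349
```

Both endpoints rise with total dose: each additional Gy of
EQD2<sub>TOT</sub> multiplies the odds of two-year survival by about
exp(0.0045) ≈ 1.005 and the odds of grade >=2 neutropenia by about
exp(0.013) ≈ 1.013. The toxicity model uses 7 of the 8 arms (study D did
not report neutropenia). Predicted probabilities with 95% bands:

```r
predict(fit_logistic(outcome_dataset(tab, arms, "os_2y")), c(0, 80, 160))
#>   eqd2_tot      prob     lower     upper
#> 1        0 0.1950542 0.1577643 0.2386605
#> 2       80 0.2583652 0.2315165 0.2871641
#> 3      160 0.3337066 0.2998269 0.3693949
```

`plot(fit)` draws the curve with its shaded band and the observed arm
proportions sized by arm size. The whole pipeline (three EBRT scenarios,
both endpoints and variants, a parameter-recovery simulation) runs from a
single configuration:

```r
cfg <- pipeline_config(out_dir = "out")
run_dose_tables(cfg); run_fits(cfg); run_recovery(cfg)
```

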
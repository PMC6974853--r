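# dynland — landmark models for dynamic prediction of survival

`dynland` answers the moving clinical question *"given that this patient
is still alive `s` years after diagnosis, what is the probability of
dying within the next `w` years?"* for registry-style survival cohorts
(the shipped worked example is a breast-cancer registry emulation). It is
aimed at biostatisticians who want the full landmarking workflow — super
dataset, supermodels, sliding-window predictions, dynamic validation — as
tested, composable R functions.

## The method in brief

For a window `w` and landmarks `s_1 ≤ … ≤ s_L`, each landmark data set
keeps the subjects at risk at `s` (time > `s`), administratively censored
at the horizon `s + w`; stacking them gives the **super dataset**. Two
Cox-type **supermodels** with smoothly landmark-varying coefficients
`β_LM(s) = Σ_j θ_j f_j(s)` are fitted on it:

* stratified: `h(t|x,s) = h0(t|s) exp(x β_LM(s))` — one Breslow baseline
  per landmark stratum;
* proportional baselines: `h(t|x,s) = h0(t) exp(x β_LM(s) + γ(s))`,
  `γ(s) = Σ_j γ_j g_j(s)` with `g_j(s_1) = 0` — one baseline, fitted with
  delayed entry over the stacked rows.

Default bases are `f = {1, s/s_L, (s/s_L)²}`, `g = {s/s_L, (s/s_L)²}`.
Because subjects repeat across strata, all interval output uses a
sandwich covariance clustered on subject id. Window predictions follow
the landmark convention
`F_w(s|x) = 1 − exp(−[H0(s+w) − H0(s)] e^{x β_LM(s) + γ(s)})`,
and are validated dynamically with a window-restricted C-index, IPCW
Brier prediction-error curves against the conditional Kaplan–Meier null,
and time-dependent AUC. A seeded registry-style cohort simulator
(`table1_design()`) makes the whole pipeline testable without real data.

## Worked example

The numbered scripts under `analysis/` run the complete study on the
simulated registry; each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1      # seed 1
Rscript analysis/02_cox_prognostic_index.R
Rscript analysis/03_landmark_supermodels.R
Rscript analysis/04_dynamic_evaluation.R
```

With seed 1 this prints, along the way:

```
simulated n=550 patients, 166 deaths (30.2%)
median follow-up (reverse KM): 2.78 years — registry-like (< 3)
PI: mean -1.29e-16 (centered), sd 1.302
         part covariate time_function coefficient         se
   stratified        PI      constant   0.9806541 0.06737770
   stratified        PI        linear  -0.3730339 0.23294656
   stratified        PI     quadratic   0.4297977 0.32208695
 proportional        PI      constant   0.9733047 0.06594451
 ...
dynamic hazard ratio exp(beta_LM(s)) ranges 2.46 to 2.82 over the grid
5-year death probability at mean PI: 0.430 (s=0) to 0.783 (s=3)
dynamic C-index: 0.766 (landmark average), 0.779 (pooled pairs)
model prediction error below KM null at every landmark: TRUE
```

Reading: the prognostic index `PI = (X − X̄)'β̂` is exactly centered; a
one-unit PI difference multiplies the five-year hazard of dying by
roughly 2.5–2.8 at every landmark; the landmark model's prediction error
beats the covariate-free KM null everywhere; discrimination (C ≈ 0.77)
is strong but not perfect on this synthetic cohort. The same objects are
available programmatically via `run_analysis(analysis_config(...))`, and
every figure written has a CSV twin with the plotted numbers.

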
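---
title: "Landmark models for dynamic prediction of survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark models for dynamic prediction of survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A Cox model fitted at diagnosis answers one question: what is a patient's
survival prospect *from baseline*? Clinicians often need a different,
moving question answered: *given that this patient is still alive s years
after diagnosis, what is the probability of dying within the next w
years?* Refitting at every `s` with only the survivors is wasteful and
noisy; ignoring the conditioning is simply wrong (immortal-time bias is
the textbook failure). Landmarking resolves this by building the
conditioning into one model.

## The model

Fix a window `w` and a grid of landmark times `s_1 <= ... <= s_L`. For
each landmark `s`, keep the subjects with observed time `> s` (left
truncation), censor everyone administratively at the horizon `s + w`, and
stack the per-landmark data sets into a **super dataset** with a stratum
label. On this stacked data the package fits two supermodels:

* **Stratified:** `h(t | x, s) = h0(t | s) exp(x beta_LM(s))`, a Cox
  model stratified on the landmark, with the landmark-varying coefficient
  expanded in a small basis, `beta_LM(s) = sum_j theta_j f_j(s)`. Risk
  sets never cross strata. Each stratum gets its own Breslow baseline.
* **Proportional baselines:** `h(t | x, s) = h0(t) exp(x beta_LM(s) +
  gamma(s))`, one baseline plus a smooth landmark main effect
  `gamma(s) = sum_j gamma_j g_j(s)`. It is fitted as a single partial
  likelihood over the stacked rows with delayed entry `(s, exit]`, which
  reproduces the construction in which a subject at risk at an event time
  appears once per landmark containing it. Identifiability requires
  `g_j(s_1) = 0`; the baseline is therefore anchored at the first
  landmark.

Both are maximized by the package's own Newton-Raphson Breslow
partial-likelihood engine (step-halving; convergence when the relative
log-likelihood change drops below 1e-9; at most 100 iterations). The
engine supports delayed entry, stratification and per-row score
residuals, from which a subject-clustered sandwich covariance is built.

The default bases follow the polynomial convention in the landmarking
literature, expressed in the normalized landmark `s / s_L`:
`f = {1, s/s_L, (s/s_L)^2}` and `g = {s/s_L, (s/s_L)^2}`. With the
default grid (`0` to `3` by `0.1`) these are `1, s/3, (s/3)^2`. The
normalizing constant is stored with the design, so other grids need no
code changes. An indicator ("saturated") basis is provided as
`saturated_basis()`; with it the stratified supermodel reproduces the
separate per-landmark ("crude") Cox fits exactly, which is the natural
smoothness diagnostic.

### Predictions

The window death probability is the landmark prediction

`F_w(s | x) = 1 - exp(-(H0(s + w) - H0(s)) exp(x beta_LM(s) + gamma(s)))`

with coefficients evaluated at `s` and held fixed over the window — the
standard landmark convention. Stratified fits use the stratum-`s`
baseline (so `s` must be a grid point); proportional fits interpolate
freely inside `[s_1, s_L]`.

### Why the robust covariance is the default

A subject at risk at many landmarks contributes many stacked rows, so the
rows are not independent and the model-based inverse information is
anti-conservative. Both fitters therefore report, and all interval
output uses, the sandwich covariance clustered on subject id; the
model-based covariance is kept alongside for comparison.

## The prognostic index

The pipeline's default covariate for the landmark stage is the prognostic
index `PI = (X - Xbar)' beta-hat` from the all-covariate Cox fit at
baseline — a one-dimensional risk score whose sample mean is exactly zero
by construction. A column-subset option exists for building the PI from a
subset of covariates (e.g. only those with clearly time-invariant
effects), but the default uses all columns. The proportional-hazards
screen for the PI is the Grambsch-Therneau scaled-Schoenfeld score test
with the identity time transform; it is the field's standard choice where
a specific test is not otherwise required.

## Dynamic evaluation

At every landmark `s`, among subjects at risk at `s`:

* **Dynamic C-index** — Harrell-type concordance restricted to pairs
  whose earlier event falls in `(s, s + w]`, with score ties counting
  1/2. The per-landmark value pools all usable pairs across event times;
  the summary averages landmarks with equal weights (an event-count
  weighting is a switch) and the fully pooled ratio is also reported,
  since either summary convention is defensible.
* **Prediction error (Brier)** — at the horizon `s + w`, IPCW-weighted
  squared error between the window death indicator and the model
  probability; weights use the reverse-KM censoring curve `G` of the
  full cohort, conditioned as `G(.)/G(s)`. The null curve replaces the
  model probability with the conditional KM estimate
  `1 - S(s+w)/S(s)` — the same number for every subject.
* **Time-dependent AUC** — cumulative/dynamic: cases are events in the
  window, controls survive past the horizon, IPCW-weighted.

Landmarks with no usable pairs (or no cases/controls) are flagged `NA`
and excluded from summaries rather than silently imputed. Inestimable
IPCW weights (censoring curve hitting zero before the horizon) raise an
error instead of returning a biased value.

## The synthetic registry

No registry data ship with the package; the generator exists so every
stage is testable end to end on data whose truth is known.

* Covariates are drawn i.i.d. from marginal specifications (normal for
  continuous, fixed frequencies for categorical, dummy-coded against the
  first level). The `table1` preset encodes a 550-patient breast-cancer
  registry profile: age 47.86 (SD 11.79) years; stage I-IV
  110/228/188/24 per 550; grade 66/288/196; metastasis 467/83; ER
  158-/392+; PR 174-/376+; HER2 420-/130+; pathological type 29/25/496
  (in situ / invasive lobular / invasive ductal); surgery 192/358
  (mastectomy / breast-conserving).
* Event times come from inverse-transform sampling of
  `H(t) = H0(t) exp(x' beta(t))`. Constant profiles invert in closed
  form; a step profile inverts exactly piecewise; a linear-decay profile
  is discretized on 512 intervals and then inverted exactly piecewise.
* Generating coefficients for the preset default to the log of the
  registry's published adjusted hazard ratios (e.g. log 9.04 for stage
  IV, log 12.51 for metastasis, log 1.05 per year of age). These are
  illustrative defaults — the published estimates are noisy — and the
  preset documents them as such. Continuous covariates enter the
  generating hazard centred at their mean, which only re-references the
  baseline.
* The baseline is Weibull with shape 1.5 (increasing hazard). The scale
  (22 years) was calibrated once against the qualitative shape of the
  registry's survival curve. One compromise is deliberate: the published
  hazard ratios imply strong between-patient heterogeneity, which
  spreads the marginal survival curve; no scale then yields both a very
  flat first four years *and* ~30% survival at nine years. The preset
  favours a gentle early decline with roughly a quarter of patients
  dying under the registry-like censoring.
* Censoring mixes Uniform(0, 5) years (90%) with an administrative cut
  at 15 years, giving a reverse-KM median follow-up just under 3 years —
  the registry's defining follow-up feature. Censoring draws use their
  own random numbers after the event draws, so the mechanism is
  independent of event times by construction, and a single seed drives
  the whole stream in a fixed order (bit-reproducible cohorts).

What the preset does **not** emulate: covariate correlations (real
stage/metastasis/grade are strongly associated; the preset draws
marginals independently), missing data, competing risks, cohort entry
drift, or measurement error. Passing tests on this preset therefore
demonstrate correctness of the machinery under a known truth, not
clinical validity on any real registry.

## Numerical choices and edge conventions

* Ties: Breslow, throughout (it matches the Breslow-type baseline
  estimator the landmark literature prints); Efron is not offered.
* "At risk at s" excludes subjects with time exactly `s` (left-open
  truncation); events exactly at `s + w` count as window events (closed
  right endpoint), administrative censoring applies strictly after.
* A landmark stratum with no subjects, or no events, stops the fit with
  an error naming the offending `s` — silent empty strata would corrupt
  the stacked likelihood.
* Rank-deficient design matrices are rejected with the collinear columns
  named. With a single landmark the `g` columns are identically zero and
  are dropped (the two supermodels then coincide exactly).
* `beta_lm()` evaluates outside the fitted grid if asked, but tags the
  result and warns; `dynamic_death_probability()` refuses.

## Sizes used in the shipped analyses and tests

The worked analysis simulates the preset at its natural n = 550 and uses
the full 31-landmark grid. Property and calibration tests use the sizes
at which their Monte Carlo error is decisively small (up to n = 10000
for closed-form limits, 20-200 replicates for coverage, size and null
calibrations); these were chosen as the smallest sizes that make the
assertions sharp, and each test fixes its own seed.

## Known limitations

* Polynomial bases only in this version (splines would be a natural
  extension); no competing risks; no cure fraction; no missing-data
  handling.
* The dynamic C-index summary ("average over event times in the window")
  has more than one defensible reading; both the landmark-averaged and
  the pooled versions are reported, and they typically differ in the
  second decimal.
* IPCW uses the cohort-wide censoring curve, not a covariate-conditional
  one; under covariate-dependent censoring the Brier and AUC estimates
  would inherit that approximation.
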
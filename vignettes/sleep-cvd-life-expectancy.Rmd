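---
title: "Estimating CVD-free life expectancy across sleep profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating CVD-free life expectancy across sleep profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeple)
```

## The scientific question

Ratio measures (hazard ratios) of sleep and cardiovascular disease
(CVD) are hard to communicate. A more tangible summary is the number of
*CVD-free years of life* a 40-year-old can expect, and how many of
those years are lost by people with poor sleep — self-reported or
clinically diagnosed. `sleeple` implements that estimation end to end:
sleep phenotyping, cohort construction, multistate survival modelling,
and restricted life-expectancy contrasts with bootstrap uncertainty.

## Sleep exposure

Five self-reported characteristics define the composite score: morning
chronotype, adequate duration (7 to < 9 h/day — whole-hour responses,
so 7 or 8), no usual insomnia complaints, no snoring, and no frequent
daytime sleepiness. The score is the count of healthy phenotypes
(0–5); categories are poor (≤ 1), intermediate (2–3) and healthy
(≥ 4). The response-level cutoffs for "usual" insomnia complaints and
"frequent" sleepiness live in the questionnaire source rather than in
any printed table, so `healthy_sleep_mapping()` exposes them as
configuration with these defaults: insomnia healthy = "never/rarely";
sleepiness healthy = "never/rarely" or "sometimes"; chronotype healthy
= the two morning responses.

Clinical sleep disorders (insomnia, sleep-related breathing disorders,
other) are flagged from coded EHR events — inpatient ICD-9/ICD-10,
primary-care Read v2/CTV3, and BNF prescriptions — inside a 2-year
lookback window before enrollment. The window is closed at both ends so
same-day diagnoses are never silently dropped. ICD and Read hierarchies
match by code prefix; BNF section codes match exactly. A
hypnotic/anxiolytic prescription (BNF chapter 4 section 1) with no
clinical sleep code in the window counts as "other sleep disorder"; a
prescription co-occurring with a clinical code adds nothing. The
shipped `default_codelist()` is deliberately small and illustrative
(one or two representative codes per disorder per vocabulary); real
deployments plug in full lists via `read_codelist()`.

## Cohort construction

Four exclusion stages run in fixed order: missing sleep responses,
prevalent CVD, missing covariates, and events within the first 2 years
of follow-up (landmark). The landmark stage drops early-event
participants but does *not* re-baseline survivors' time origin — that
mirrors the original design and knowingly leaves an immortal-time
window; it is documented, not "fixed" (see *Limitations*).

Age is the analysis timescale, with left truncation at the enrollment
age and administrative restriction at τ = 81 (no observed ages beyond
it, so no extrapolation). Conditioning on survival to age 40 and
truncating at the 81st birthday are only coherent on the age clock,
which is why age is not also a covariate in the multistate fits; a
`timescale = "followup"` switch is provided for sensitivity. Death at
exactly 81 counts as an event; later events are censored. A CVD event
recorded at the same age as death or censoring is nudged one day
earlier (configurable ε = 1/365.25 yr) so counting-process intervals
stay non-degenerate — with day-resolution records the true ordering is
unknowable anyway. In the illness-death expansion each healthy person
contributes a transition-1 (healthy→CVD) and a transition-2
(healthy→death) row over (enrollment, first exit]; the transition-2 row
of a CVD case is censored at the CVD age, which is the standard Markov
treatment of death as a competing exit from the healthy state.

## Estimation

Each transition hazard is a Cox proportional-hazards model fitted by
Newton–Raphson with step halving on the left-truncated partial
likelihood (convergence: relative log-likelihood change < 1e-9, cap 50
iterations; a final polishing Newton step pins the optimum so the
engine cross-checks against an independent implementation to 1e-6).
Efron tie handling is the default: event ages are continuous, but
bootstrap resampling duplicates persons and the duplicates are genuine
ties. The engine is written from scratch (Rcpp) because the test
harness uses `survival::coxph` as the *independent* reference — backing
the fitter by the same library would collapse the dual-route check.
Rank-deficient information matrices (sparse exposure dummies in small
strata) fall back to a pseudo-inverse Newton step and are flagged;
monotone likelihoods (|β| > 20) are flagged as non-convergence.

Baseline cumulative hazards use the Breslow estimator with the fit
centered at the prediction profile itself — mathematically equivalent
to any other centering but immune to `exp` overflow. The prediction
profile follows the median/mean rule: continuous covariates at the
stratum mean, ordered categoricals at the median category, unordered at
the mode, and — for single-characteristic or single-disorder
contrasts — all remaining sleep variables at their healthy/absent
level. Two open choices are resolved as follows: "median for
categorical" is read as the cumulative-count median for *ordered*
factors and the mode for nominal ones; and "marginal" life expectancy
is the profile-conditional estimate at that single profile (the stated
rule), not a population average over the empirical covariate
distribution — averaging is available behind the same machinery for
sensitivity but is not the default.

The three predicted cumulative-hazard step functions enter the
Aalen–Johansen product integral over the union of their jump ages; any
jump whose off-diagonal increments would exceed one is truncated and
renormalized (counted and reported). Occupation probabilities are
piecewise constant, so restricted expectancies are *exact* sums of
step-width × step-value — there is no quadrature error on the
estimation side; grid refinement appears only in the oracle
comparisons. Years of life lost is reference-minus-exposed, positive =
years lost. Contrast references: categories vs the healthy (≥ 4)
group, score levels vs score 5, disorders vs "without this condition".

Confidence intervals are nonparametric bootstrap percentiles (2.5/97.5,
linear interpolation), resampling persons within sex strata with all
their transition rows moving together. The original analyses used
B = 1000; tests run scaled-down B (200) at scaled n, which the coverage
criterion explicitly targets. Iterations whose refit fails are dropped
and logged, and the interval is flagged when more than 5% drop. The
percentile method (not BCa or normal approximation) is a deliberate
choice: the source analysis states only "nonparametric bootstrapping",
and percentile intervals are the least assumption-laden default. YLL
intervals come from the bootstrap distribution of the *difference*,
not from combining group-wise intervals.

For comparability with ratio-based literature the pipeline also fits
Fine–Gray subdistribution-hazard models of incident CVD with non-CVD
death as a competing risk, on the follow-up clock with baseline age
among the covariates (the IPCW construction assumes a single censoring
clock). The weighted risk-set expansion is delegated to
`survival::finegray` — mature, well-tested infrastructure — while the
weighted Cox fit on the expanded data uses the package's own engine, so
the reduction property (no competing events ⇒ identical to `fit_cox`)
holds exactly. Wald intervals use the weighted-information model
covariance; that is an approximation to the full IPCW sandwich
covariance and is labelled as such.

## The synthetic world

The restricted-access cohort cannot ship with the package, so
`simulation_truth()` defines a parametric stand-in whose defaults *are*
the stated conditions, chosen once:

* enrollment ages 40–69 (truncated normal, mean 56.2, SD 8.1) and
  administrative censoring after a mean 11.8 (SD 1.3) years of
  follow-up — the cohort's reported values;
* sleep-category prevalence ≈ 62/36/2% in women and 57/41/2% in men;
* covariate marginals matching the cohort's descriptive table
  (deprivation quartiles, mental health 33%, BMI classes 78/20/2%,
  smoking 56/34/10%, …);
* Gompertz baseline intensities on the age scale,
  λ_k(age) = a_k · exp(b_k (age − 40)): a₁ = 3.5e-3, b₁ = 0.07 for CVD
  incidence; a₂ = 4.5e-4, b₂ = 0.095 for death without CVD; a₃ =
  1.6e-3, b₃ = 0.09 after CVD. These give a CVD-free life expectancy
  at 40 of ≈ 31.7 years and overall event proportions comparable to
  the cohort's (≈ 17% incident CVD, ≈ 4% deaths over follow-up);
* proportional sleep effects (poor vs healthy HR 1.6 on CVD incidence,
  1.45 on healthy-state death, 1.2 after CVD) sized so category
  contrasts in e_free land in the observed 1–7 year range;
* clinical-disorder planting rates ≈ 0.9% insomnia, 1.7% SRBD, 4.6%
  other, matching the subsample frequencies, with occasional
  out-of-window codes to exercise the lookback rule;
* missingness is independent completely-at-random per field — the
  original performs complete-case analysis, so the mechanism only
  needs to exercise the exclusion cascade.

Event times are drawn by inversion sampling of the competing Gompertz
intensities from the enrollment age (vectorized bisection of the
closed-form cumulative hazard); the CVD→death clock is *clock-forward*
(hazard depends on current age, not time since CVD), taking the Markov
label literally since the original does not state whether the real
analysis conditioned on time since CVD. Gompertz baselines were chosen
because they are mortality-shaped, have closed-form cumulative hazards,
and reduce to exponentials at b = 0, where every oracle has a closed
form. Covariate effects act linearly on level scores; factor-coded Cox
fits nest that structure, so the pipeline remains correctly specified.

`true_life_expectancy()` is the independent oracle: adaptive quadrature
(relative tolerance 1e-8) of the closed-form survival functions, with
the time-with-CVD term as a nested double integral. What a green test
does establish: the estimator chain (fitting → baselines →
product-integral → integration → bootstrap) recovers known truths under
proportional hazards, emulated missingness and administrative
censoring. What it does not: robustness to real-data features the
generator does not emulate — covariate-sleep confounding beyond the
configured marginals, informative censoring, recording error, UK
Biobank's selection bias.

Parameter-recovery and CI-coverage checks run with the landmark set to
0 and missingness 0: the 2-year landmark without re-baselining is a
*design* feature that induces immortal-time bias by construction, so an
estimator-correctness check against the simulator's truth must switch
it off; the cascade itself is tested separately against hand-computed
fixtures.

## Numerical choices

* Cox convergence 1e-9 (relative log-likelihood), 50 iterations,
  25 step-halvings, + one polishing step.
* Oracle quadrature relative tolerance 1e-8; AJ/ODE oracle comparisons
  at 2,000 discretization points (sup-norm 1e-3); closed-form e_free
  checks on a 50,000-point grid (the step-integral's O(Δt) bias needs
  the finer grid, not the estimator).
* Ties: Efron default; Breslow available; both verified equal on
  tie-free data.
* Same-age CVD/death nudge ε = 1 day.
* Bootstrap seeds derive from one top-level seed recorded in the run
  manifest; same config + seed reproduces every output byte for byte.

## Limitations

* The landmark design leaves immortal time (acknowledged, not
  corrected); recovery tests bypass it.
* Percentile bootstrap intervals measurably undercover for e_free at
  small cohort sizes: the packaged coverage check (200 replicates,
  B = 200, n = 2,000) reports ~88% for a nominal 95%, despite an
  unbiased point estimator and correctly calibrated intervals for
  smooth functionals — risk sets near τ = 81 are extremely sparse at
  that n. The check is kept failing rather than loosened; at the
  motivating cohort's scale the issue disappears.
* No CVD recovery/relapse — once in the CVD state, always counted
  there, which overestimates time spent with disease.
* Fine–Gray Wald intervals use the model-based weighted information,
  not the IPCW sandwich.
* The profile-conditional "marginal" expectancy is covariate-profile
  specific; contrasts at other profiles will differ under
  non-collapsibility.
* The default code list is illustrative, not a clinical inventory.
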
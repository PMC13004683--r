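---
title: "Clock models for plasma p-tau217: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clock models for plasma p-tau217: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaclock)
```

## The problem

Plasma %p-tau217 (the percentage of tau phosphorylated at position 217,
relative to non-phosphorylated tau217) rises along a remarkably consistent
trajectory during the preclinical and early symptomatic phases of
Alzheimer's disease. That consistency makes a *clock model* possible: a
monotone mapping between the biomarker level and disease time, defined as
years since the biomarker crossed its positivity threshold (4.06% for
plasma %p-tau217, the level aligned with an amyloid PET burden of
Centiloid 20). Once a clock exists, a single plasma sample yields an
estimated *age at biomarker positivity* (draw age minus clock time), and
that age in turn predicts both the probability and the expected age of
symptomatic AD onset.

`plasmaclock` implements the full chain: individual rate estimation, the
rate-versus-level smooth and its interval of consistent change, two clock
constructions (TIRA and SILA), per-subject positivity-age estimation,
interval-censored proportional-hazards modeling of time to symptomatic AD,
and linear onset-age models with diagnostics — plus a synthetic-cohort
generator that reproduces the statistical structure this analysis assumes,
so every stage can be validated against known ground truth.

## The model chain, stage by stage

### Individual rates and the rate-versus-level smooth

Each subject's rate of change (units/year) comes from a linear
mixed-effects model `value ~ age + (age | subject)`: the subject's rate is
the fixed slope plus their random slope, and their *midpoint value* is the
subject-specific fitted value at the temporal midpoint of follow-up. We use
the subject-specific fitted value (not the mean of observed values, which
is a documented alternative) because it is the less noisy summary of where
on the trajectory the subject's follow-up sits. If the mixed model fails or
is singular, per-subject ordinary least squares lines are used instead,
with a warning; when random-effect variances are zero the two coincide.

The population rate-versus-level curve $r(v)$ is a penalized cubic
regression spline (`mgcv::gam`, smoothing by generalized cross-validation)
of individual rates on midpoint values, evaluated with pointwise standard
errors on a uniform 512-point grid over the observed range. Both the grid
size and the basis dimension are configurable; 512 makes interpolation
error negligible relative to every other error source while keeping all
downstream quadrature instantaneous.

### The interval of consistent change

The clock is only identified where the rate is estimated consistently. We
define the variance of the modeled rate at each grid value as its squared
prediction standard error, take the 90th percentile of that variance over
the grid as the cut, and keep the maximal contiguous run of grid values
with variance strictly below the cut that contains the positivity
threshold. Strict inequality is the tie rule: grid values at or above the
cut are excluded. One degenerate case is handled specially: a perfectly
flat variance profile is uniformly consistent, and the full grid is
returned rather than nothing. Cohort-specific intervals are combined with
`intersect_intervals()` (component-wise max/min; disjoint inputs are an
error).

The pipeline applies one additional guard,
`trim_interval_to_positive_rate()`. In a mixed cohort the mean rate near
the trajectory floor approaches zero — many never-positive subjects agree
that nothing is changing, so the variance there can be *low* while the
rate itself is useless for clock building (the inverse rate diverges). The
fitted interval is therefore trimmed to the contiguous region around the
anchor where the fitted mean rate exceeds 10% of the rate at the anchor.
This is a numerical-identifiability guard, not a change to the variance
rule: values below the trimmed interval are simply outside the clock's
domain, exactly as values outside the variance interval are.

### TIRA: integrating the inverse rate

Time between levels is
$$\tau(v) = \int_{v_0}^{v} \frac{dv'}{r(v')},$$
anchored so $\tau(v_0)=0$ at the positivity threshold and negative below
it. The integral is computed segment by segment as the *exact* integral of
the piecewise-linear interpolant of the gridded rate: for a segment where
the rate runs linearly from $r_1$ to $r_2$ over $[v_1, v_2]$,
$$\int_{v_1}^{v_2}\frac{dv}{r(v)} = (v_2-v_1)\,\frac{\log(r_2/r_1)}{r_2-r_1},$$
falling back to the midpoint form when $r_1 \approx r_2$. We chose this
over trapezoiding $1/r$ because it is machine-exact whenever the true rate
is linear in the value (including the constant-rate case) and markedly
more accurate where the rate is small and $1/r$ strongly convex — exactly
the regions that dominate clock error. The anchor is inserted as a grid
node so $\tau(v_0)=0$ holds to machine precision, asserted on every build.

Rates at or below `rate_floor` (default $10^{-4}$ units/year) anywhere in
the interval are a hard error that names the offending region. They are
never silently clipped: clipping a near-zero rate to a floor would
silently compress decades of implied disease time into the floor value.

### SILA: discrete rate sampling and Euler integration

SILA estimates the rate-versus-level relationship directly from discrete
data: consecutive-pair rates $\Delta v/\Delta t$ are assigned to the pair's
midpoint value, averaged within 50 evenly spaced value bins across the
interval, and smoothed by local linear regression (Gaussian kernel,
bandwidth 20% of the interval width). Euler's method then integrates
$dv/d\tau = \hat r(v)$ forward and backward from $(v_0, 0)$ with step
$dt = 0.05$ years, and the trajectory is inverted to $\tau(v)$ on the
value grid. All constants are configurable; they are our choices, made
once, scaled to the data density the generator produces. More than 20% of
empty bins, or a non-positive smoothed rate inside the interval, is an
error. The Euler core is exposed as `sila_euler_integrate()` so its
first-order convergence can be verified directly against analytic rate
functions, independent of the data-driven smoothing.

Both constructions yield a strictly monotone `clock_curve`;
`clock_time_at_value()` and `clock_value_at_time()` interpolate it
piecewise-linearly. Values outside the valid interval are a hard error,
never an extrapolation: outside the interval of consistent change the
level-time relationship is not identified, and a very high value supports
only the qualitative statement that the subject is far past positivity.

### Positivity ages and their validation

Each usable sample (value strictly inside the valid interval) contributes
`age - clock_time_at_value(value)`; a subject's estimate is the arithmetic
mean over usable samples, with out-of-range samples skipped (not clamped)
and counted. The observed conversion age — the average of the age at the
last non-positive value and the age at the first positive value after it —
provides a model-free check; with non-monotone series the rule pairs the
*last* non-positive sample with the first positive sample after it.
Agreement between estimates uses adjusted $R^2$, Spearman's rank
correlation, and the concordance correlation coefficient
$\rho_c = 2s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$ with $1/n$
moments; a rank-transformed variant is available via `ccc_type = "rank"`
since "non-parametric CCC" admits more than one reading.

### Interval-censored proportional hazards

Symptom onset is only ever observed between assessments, so the survival
model maximizes the interval-censored likelihood
$$\prod_i \left[S(L_i \mid x_i) - S(R_i \mid x_i)\right], \qquad
S(t \mid x) = \exp\!\left(-\Lambda_0(t)\, e^{x\beta}\right),$$
with right-censored subjects contributing $S(L_i)$ and (in the
impaired-at-baseline sensitivity analysis) left-censored subjects
$1 - S(R_i)$. $\Lambda_0$ is a nondecreasing step function with jumps on
the Turnbull innermost-interval endpoints; because observation intervals
are half-open $(L, R]$, tied endpoints sort right-before-left when the
support is built. Estimation alternates two monotone steps until the
log-likelihood changes by less than $10^{-6}$:

* a baseline update derived from a latent Poisson-process representation
  (counts $N_{ik} \sim \text{Poisson}(\lambda_k e^{x_i\beta})$ on each
  subject's risk region reproduce the censored likelihood exactly, giving
  closed-form EM updates for the jumps $\lambda_k$), run as several sweeps
  per outer iteration because the baseline converges much more slowly than
  $\beta$; and
* a damped Newton update of $\beta$ with a finite-difference Hessian and
  backtracking.

Both steps can only increase the observed-data log-likelihood, so the
recorded trace is nondecreasing by construction and asserted in tests.
With $\beta = 0$ the procedure reduces to the Turnbull nonparametric
estimator, which the test suite verifies against
`survival::survfit(type = "interval2")` as an independent oracle. Standard
errors come from the curvature of the profile log-likelihood, with the
baseline refitted at perturbed $\beta$.

The concordance index for interval-censored data needs a comparability
rule, which no single convention settles: here pair $(i, j)$ is comparable
when $i$'s event interval wholly precedes $j$'s observation window
($R_i < L_j$, with $L_j$ the censoring age for right-censored $j$), and
concordant when the model gives $i$ the higher risk; ties count one half.
Bootstrap percentile intervals resample subjects and refit. Kaplan-Meier
curves place interval-censored events at the interval's right endpoint
(the assessment where onset is first observed, matching the onset
definition); the interval-midpoint convention is available behind a flag.
Timescale adapters shift ages by a per-subject reference (first positive
sample, estimated positivity, or predicted onset), and
`positivity_age_bins()` provides the <70 / 70--80 / >=80 strata.

### Onset-age models

For subjects whose onset followed estimated positivity, ordinary least
squares fits `onset_age ~ positivity_age` (a flag includes
onset-before-positivity subjects for the sensitivity analysis). Candidate
covariates are screened by single addition at $\alpha = 0.05$ — the
simplest procedure consistent with covariates "considered but not
included"; a candidate enters the final model only if significant.
Diagnostics cover Shapiro-Wilk normality, Breusch-Pagan homoscedasticity,
AIC and sequential F-tests across linear/quadratic/cubic specifications,
and a Cook's distance > 4/n influence refit that is *reported* alongside
the primary fit, never silently substituted for it. Prediction error is
summarized by the median absolute error and the CCC, and supports
train-on-one-cohort / evaluate-on-the-other workflows.

### Biological staging

`classify_stage()` maps amyloid and early/late tau PET positivity flags
(upstream SUVR thresholds 1.328 and 1.224) to the 2024 biological stages:
A−/Te−/Tl− is stage A, A+/Te−/Tl− stage B, A+/Te+/Tl− stage C,
A+/Te+/Tl+ stage D. The four remaining flag combinations are reported as
non-canonical rather than forced into a stage. Group comparisons use
Conover-Iman tests in the Kruskal-Wallis-conditional variant — pairwise
$t$ statistics on global mid-ranks with the pooled rank variance deflated
by $(N-1-H)/(N-k)$, on $N-k$ degrees of freedom — with Benjamini-Hochberg
adjustment across all pairs.

## The synthetic cohort: what it emulates, and what it does not

The generator (`sim_config()`, `generate_cohort()`) encodes the study
conditions the analysis assumes:

* a shared monotone latent trajectory — a four-parameter logistic with
  floor 0.5%, ceiling 15%, growth rate 0.25/year, centered so it crosses
  4.06% exactly at disease time zero;
* individual positivity ages, normal with mean 70 and sd 8 years,
  spanning the age heterogeneity that clock alignment is meant to remove;
* 3--6 plasma draws about 2 years apart (uniform jitter ±0.5 y), with
  first draws placed between 12 years before and 2 years after positivity,
  geometric per-visit dropout (5%/visit), and additive Gaussian
  measurement noise (sd 0.3%, truncated so values stay nonnegative);
* 40% never-positive subjects with flat values jittered around the floor;
* symptom onset lagging positivity by `37.4 − 0.39 × positivity age`
  years (Gaussian sd 2 y, floored at 1 y) — the line through a lag of
  14.0 years at positivity age 60 and 6.2 years at age 80, so older
  converters reach onset sooner by construction;
* annual clinical assessments extending 8 years past the last draw, CDR 0
  before onset and CDR > 0 with an AD syndrome from the first scheduled
  assessment at or after onset (interval censoring thus arises naturally,
  as do right censoring for slow progressors and left censoring for
  subjects already impaired at baseline); 10% of never-positive subjects
  receive a non-AD impairment instead.

The noise sd is a free choice: assay-level replicate error is not a
published quantity for these measures, and 0.3% was fixed once as a
plausible within-subject scale (about 7% of the threshold). Everything the
generator does *not* emulate bounds what passing tests show: there are no
assay batch effects or site differences, no co-pathologies decoupling
symptoms from %p-tau217, no competing mortality (only noninformative
dropout), and the latent trajectory is exactly shared across subjects. So
clock recovery on synthetic data is near-perfect (adjusted $R^2 > 0.99$)
where real cohorts report 0.5--0.8, and synthetic concordance and error
metrics are systematically optimistic. The synthetic results validate the
*machinery*; they do not predict real-data effect sizes.

## Numerical choices and degenerate inputs

* Grid size 512; GCV smoothing; SILA `dt` 0.05 y, 50 bins, 20% bandwidth —
  all defaults, all configurable.
* `rate_floor` $10^{-4}$ units/y is an error threshold, never a clip.
* Positivity is strict (`value > threshold`), so the threshold itself is
  not positive, and interval endpoints are real-valued ages throughout.
* Duplicate (subject, age, assay) rows are rejected at parse time rather
  than averaged; CDR values outside {0, 0.5, 1, 2, 3} are rejected.
* "Symptoms starting after positivity" compares the onset interval's
  *right* endpoint (the first symptomatic assessment) to the estimated
  positivity age; the left endpoint is available behind a flag since the
  convention is genuinely open.
* IC-Cox: convergence is $|\Delta \ell| < 10^{-6}$; non-convergence within
  `max_iter` is an error, as is a constant covariate (warned and fixed at
  zero) or an event interval containing no support point.
* Desk-scale problem sizes used by the tests and the acceptance script —
  cohorts of 120--500 subjects, 50 replicate survival fits at n = 400, 100
  bootstrap resamples in bootstrap tests (the method supports
  paper-scale 5,000) — were chosen as the smallest sizes at which the
  Monte-Carlo checks are stable.

## Known limitations

* The clock is undefined outside the interval of consistent change by
  design; subjects with no usable samples get no estimate rather than an
  extrapolated one.
* Profile-likelihood standard errors for $\beta$ ignore none of the
  baseline's uncertainty in the curvature direction but are still
  asymptotic; the bootstrap is the robust alternative at paper scale.
* The C-index comparability rule discards pairs whose windows overlap;
  with very coarse assessment grids this can leave few comparable pairs.
* The covariate screen is single-addition, not exhaustive subset
  selection, mirroring its role as a reported sensitivity check rather
  than a model-building step.
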
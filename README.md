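# plasmaclock

Clock models for plasma %p-tau217: estimating when someone became
biomarker-positive for Alzheimer's disease, and from that, when symptoms
are likely to begin.

## The problem

Plasma %p-tau217 (the ratio of tau phosphorylated at position 217 to
non-phosphorylated tau217, times 100) rises along a consistent trajectory
during preclinical Alzheimer's disease. Because the trajectory is shared,
a *clock model* — a monotone mapping τ(v) between the biomarker level v
and years since crossing the positivity threshold v₀ = 4.06% (the level
aligned with amyloid PET Centiloid 20) — lets a single plasma sample date
the disease process: the estimated age at positivity is the draw age minus
the clock time, and per-subject estimates average over samples.

Two constructions are implemented:

* **TIRA** (temporal integration of rate accumulation): individual rates
  of change from a random-slope mixed model, a penalized cubic-spline
  smooth r(v) of rate on level, and
  τ(v) = ∫ from v₀ to v of dv′ / r(v′),
  anchored so τ(v₀) = 0;
* **SILA** (sampled iterative local approximation): discrete
  consecutive-pair rates sampled at evenly distributed values, smoothed by
  local linear regression and integrated by Euler's method from the
  anchor.

Clocks are valid only on the *interval of consistent change* — the
contiguous range around the threshold where the variance of the modeled
rate (squared prediction standard error) stays below the cohort's 90th
percentile. Downstream, the estimated age at positivity drives an
interval-censored proportional-hazards model of time to symptomatic AD
(with a concordance index for interval-censored data) and a linear model
of onset age, with full diagnostics. A synthetic-cohort generator
reproduces the statistical structure the analysis assumes, so the entire
chain is testable against known ground truth.

This package is for biostatisticians and methods researchers working on
biomarker-based disease timing — clinical-trial enrichment, staging, and
progression modeling — not for individual prognosis.

## Worked example

The canonical single-sample computation: an 80-year-old whose plasma
%p-tau217 is 7.06%, on a clock where 7.06% corresponds to 8.8 years from
positivity, is estimated to have become positive at 71.2 years.

```r
clock <- build_tira_clock(
  tibble::tibble(value = seq(1.06, 10.45, length.out = 512),
                 rate = (7.06 - 4.06) / 8.8),
  anchor = 4.06, interval = c(1.06, 10.45))

estimate_positivity_ages(
  tibble::tibble(subject_id = "example", age = 80, value = 7.06), clock)
#> # A tibble: 1 × 5
#>   subject_id estimated_age n_samples_used n_samples_skipped per_sample_ages
#>   <chr>              <dbl>          <int>             <int> <list>
#> 1 example             71.2              1                 0 <dbl [1]>
```

`estimated_age = 71.2` is 80 − 8.8; samples outside the clock's valid
interval would be skipped and counted in `n_samples_skipped`, never
extrapolated.

The full pipeline on a synthetic cohort:

```r
res <- run_pipeline(sim = sim_config(seed = 1))
res
#> Plasma biomarker clock pipeline
#>   interval of consistent change: (0.725, 8.643)
#>   clocks: TIRA, SILA
#>   Cox log-HR per year of positivity age: -0.327 (C-index 0.943)
#>   onset model: onset = 37.7 + 0.603 * positivity_age (adj R2 0.772, n 80)
```

Reading the output: the interval of consistent change was fitted from the
cohort's own rate curve; the negative Cox coefficient on the age scale
says that later positivity shifts the whole onset-age distribution later,
while the onset-model slope below 1 is the key structural finding the
generator builds in — the *lag* from positivity to onset shrinks with age
(onset − positivity = intercept + (slope − 1) × positivity age). With this
fit, `median_time_from_positivity(res$survival$fit, 60)` ≈ 14.6 years
versus ≈ 7.6 years at age 80.

Plots: `autoplot()` works on clock curves, rate curves and onset models;
`plot_kaplan_meier()` and `plot_diagnosis_raster()` cover the survival and
longitudinal-diagnosis views. `tidy()`/`glance()` methods summarize the
survival and onset fits.

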
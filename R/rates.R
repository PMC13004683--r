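#' Per-subject rates of biomarker change
#'
#' Estimates each subject's rate of change (units/year) and the biomarker
#' value at the temporal midpoint of their follow-up. The primary estimator
#' is a linear mixed-effects model `value ~ age + (age | subject)` with
#' random slopes and intercepts; each subject's rate is the fixed slope plus
#' their random slope, and the midpoint value is the subject-specific fitted
#' value at `(first draw + last draw)/2`. If the mixed model fails or is
#' singular, the function falls back to independent per-subject ordinary
#' least squares lines with a warning.
#'
#' @param samples Biomarker tibble (`subject_id`, `age`, `value`). Subjects
#'   with fewer than 2 samples are skipped with a warning.
#' @param method `"lmm"` (default, with OLS fallback) or `"ols"`.
#' @return A tibble `subject_id`, `rate`, `midpoint_value`, `followup_span`,
#'   with attribute `"estimator"` recording which path produced it.
#' @export
fit_individual_rates <- function(samples, method = c("lmm", "ols")) {
  method <- match.arg(method)
  counts <- table(samples$subject_id)
  few <- names(counts)[counts < 2]
  if (length(few)) {
    warn(paste0(length(few), " subject(s) with <2 samples skipped."))
    samples <- samples[!samples$subject_id %in% few, , drop = FALSE]
  }
  if (!nrow(samples)) abort("No subjects with >=2 samples.")
  samples <- dplyr::arrange(samples, .data$subject_id, .data$age)

  if (method == "lmm" && length(unique(samples$subject_id)) >= 10) {
    fit <- tryCatch(
      suppressWarnings(
        lme4::lmer(value ~ age + (age | subject_id), data = samples,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      co <- coef(fit)$subject_id  # per-subject intercept and slope
      mids <- samples |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(mid_age = (min(.data$age) + max(.data$age)) / 2,
                         followup_span = max(.data$age) - min(.data$age),
                         .groups = "drop")
      idx <- match(mids$subject_id, rownames(co))
      out <- tibble::tibble(
        subject_id = mids$subject_id,
        rate = co[idx, "age"],
        midpoint_value = co[idx, "(Intercept)"] + co[idx, "age"] * mids$mid_age,
        followup_span = mids$followup_span
      )
      attr(out, "estimator") <- "lmm"
      return(out)
    }
    warn("Mixed model failed to converge or was singular; falling back to per-subject OLS slopes.")
  }

  out <- samples |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(rate = ols_slope(.data$age, .data$value),
                     midpoint_value = mean(.data$value) +
                       ols_slope(.data$age, .data$value) *
                       ((min(.data$age) + max(.data$age)) / 2 - mean(.data$age)),
                     followup_span = max(.data$age) - min(.data$age),
                     .groups = "drop")
  attr(out, "estimator") <- "ols"
  out
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Smooth rate-versus-level curve
#'
#' Fits a generalized additive model of individual rates of change on the
#' midpoint biomarker value, using a penalized cubic regression spline with
#' the smoothing parameter chosen by generalized cross-validation, and
#' evaluates the fitted mean and its pointwise standard error on a uniform
#' grid over the observed midpoint range.
#'
#' @param rates Tibble from [fit_individual_rates()].
#' @param grid_size Number of grid points (default 512).
#' @param k Spline basis dimension passed to [mgcv::s()].
#' @return An object of class `rate_curve`: a tibble `value`, `rate`,
#'   `pred_se` with the fitted \pkg{mgcv} model in attribute `"fit"`.
#' @export
fit_rate_curve <- function(rates, grid_size = 512, k = 10) {
  if (nrow(rates) < 20) abort("Need >= 20 individual rates to fit the rate curve.")
  rng <- range(rates$midpoint_value)
  if (diff(rng) <= 0) abort("Degenerate midpoint value range.")
  k <- min(k, nrow(rates) - 1)
  fit <- mgcv::gam(rate ~ s(midpoint_value, bs = "cr", k = k),
                   data = rates, method = "GCV.Cp")
  grid <- seq(rng[1], rng[2], length.out = grid_size)
  pr <- predict(fit, newdata = data.frame(midpoint_value = grid), se.fit = TRUE)
  out <- tibble::tibble(value = grid, rate = as.numeric(pr$fit),
                        pred_se = as.numeric(pr$se.fit))
  class(out) <- c("rate_curve", class(out))
  attr(out, "fit") <- fit
  out
}

#' Interval of consistent biomarker change
#'
#' The variance of the modeled rate at each grid value is its squared
#' prediction standard error. Grid values whose variance is strictly below
#' the given percentile of variance over the grid are "consistent"; the
#' function returns the maximal contiguous run of consistent grid values
#' containing the positivity threshold (anchor).
#'
#' @param curve A [fit_rate_curve()] result (or any tibble with `value` and
#'   `pred_se`).
#' @param anchor Positivity threshold that the interval must contain.
#' @param percentile Percentile of grid variance used as the cut (default 90).
#' @return Numeric length-2 `c(lower, upper)` of class `value_interval`.
#' @export
consistent_change_interval <- function(curve, anchor, percentile = 90) {
  stopifnot(all(c("value", "pred_se") %in% names(curve)))
  variance <- curve$pred_se^2
  cut <- quantile(variance, percentile / 100, names = FALSE)
  ok <- variance < cut  # strict: values at/above the cut are excluded
  if (all(!ok)) {
    if (diff(range(variance)) == 0) {
      # flat variance profile: uniformly consistent, keep the whole grid
      return(value_interval(curve$value[1], curve$value[nrow(curve)]))
    }
    abort("No grid values below the variance cut.")
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  in_anchor <- which(runs$values &
                       curve$value[starts] <= anchor &
                       curve$value[ends] >= anchor)
  if (!length(in_anchor)) {
    low_rng <- paste(sprintf("[%.3g, %.3g]", curve$value[starts[runs$values]],
                             curve$value[ends[runs$values]]), collapse = ", ")
    abort(paste0(
      "The positivity threshold ", anchor,
      " lies outside every low-variance region (found: ", low_rng, ")."))
  }
  value_interval(curve$value[starts[in_anchor]], curve$value[ends[in_anchor]])
}

#' Trim an interval to the region of usable positive rates
#'
#' Inverse-rate integration requires a strictly positive modeled rate; near
#' the trajectory floor the mean rate of a mixed cohort (converters plus
#' never-positive subjects) approaches zero even where its variance is low,
#' which would make clock times diverge. This trims `interval` to the
#' maximal contiguous grid region containing `anchor` where the fitted rate
#' exceeds `frac` times the rate at the anchor.
#'
#' @param curve A [fit_rate_curve()] result.
#' @param interval A `value_interval` (or numeric length 2) to trim.
#' @param anchor Positivity threshold; must stay inside the result.
#' @param frac Minimum rate as a fraction of the anchor rate (default 0.1).
#' @return A `value_interval`.
#' @export
trim_interval_to_positive_rate <- function(curve, interval, anchor,
                                           frac = 0.1) {
  keep <- curve$value >= interval[1] & curve$value <= interval[2]
  v <- curve$value[keep]; r <- curve$rate[keep]
  r_anchor <- approx(curve$value, curve$rate, xout = anchor)$y
  if (!is.finite(r_anchor) || r_anchor <= 0) {
    abort("Modeled rate at the anchor is not positive.")
  }
  ok <- r > frac * r_anchor
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & v[starts] <= anchor & v[ends] >= anchor)
  if (!length(hit)) abort("No positive-rate region contains the anchor.")
  value_interval(v[starts[hit]], v[ends[hit]])
}

#' Construct or intersect value intervals
#'
#' `value_interval()` constructs a validated `(lower, upper)` pair;
#' `intersect_intervals()` returns `(max(lowers), min(uppers))` and errors
#' on disjoint inputs.
#'
#' @param lower,upper Interval bounds, `lower < upper`.
#' @return A `value_interval` (numeric length 2).
#' @export
value_interval <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("Need numeric bounds with lower < upper.")
  }
  structure(c(lower = lower, upper = upper), class = "value_interval")
}

#' @rdname value_interval
#' @param a,b `value_interval` objects (or numeric length-2 vectors).
#' @export
intersect_intervals <- function(a, b) {
  lo <- max(a[1], b[1])
  hi <- min(a[2], b[2])
  if (lo >= hi) {
    abort(sprintf("Intervals [%g, %g] and [%g, %g] are disjoint.",
                  a[1], a[2], b[1], b[2]))
  }
  value_interval(lo, hi)
}
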
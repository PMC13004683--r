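#' @keywords internal
new_clock_curve <- function(values, times, method, anchor, interval) {
  if (any(diff(values) <= 0)) abort("Clock grid values must be strictly increasing.")
  if (any(diff(times) <= 0)) {
    abort("Clock times must be strictly increasing with value (rate must be positive).")
  }
  t0 <- approx(values, times, xout = anchor)$y
  if (!is.finite(t0) || abs(t0) > 1e-9) {
    abort("Clock is not anchored: time at the anchor value must be 0.")
  }
  out <- tibble::tibble(value = values, years_from_positivity = times)
  class(out) <- c("clock_curve", class(out))
  attr(out, "method") <- method
  attr(out, "anchor") <- anchor
  attr(out, "valid_interval") <- value_interval(interval[1], interval[2])
  out
}

#' Build a TIRA clock from a rate curve
#'
#' Temporal integration of rate accumulation: time between biomarker levels
#' is the integral of the inverse modeled rate,
#' \deqn{\tau(v) = \int_{v_0}^{v} \frac{dv'}{r(v')},}
#' computed segment-by-segment as the exact integral of the piecewise-linear
#' interpolant of the gridded rate (for a segment where the rate runs
#' linearly from \eqn{r_1} to \eqn{r_2} over \eqn{[v_1, v_2]}, the time is
#' \eqn{(v_2-v_1)\log(r_2/r_1)/(r_2-r_1)}), so that \eqn{\tau(v_0) = 0} at
#' the positivity threshold \eqn{v_0} and \eqn{\tau(v) < 0} below it. This
#' quadrature is exact whenever the true rate is linear in the value and is
#' higher-order accurate than trapezoiding \eqn{1/r}, which matters where
#' the rate is small and \eqn{1/r} strongly convex.
#'
#' @param curve A [fit_rate_curve()] result, or any tibble with ascending
#'   `value` and positive `rate` columns.
#' @param anchor Positivity threshold \eqn{v_0}; must lie inside `interval`.
#' @param interval Interval of consistent change (`value_interval` or numeric
#'   length 2) to which the clock is restricted.
#' @param rate_floor Rates at or below this value (units/year) are an error,
#'   never silently clipped: near-zero rates make \eqn{1/r} blow up and
#'   silently clipping them would bias the clock.
#' @return A `clock_curve` tibble: `value`, `years_from_positivity`, with
#'   attributes `method`, `anchor`, `valid_interval`.
#' @export
build_tira_clock <- function(curve, anchor, interval, rate_floor = 1e-4) {
  stopifnot(all(c("value", "rate") %in% names(curve)))
  keep <- curve$value >= interval[1] & curve$value <= interval[2]
  if (sum(keep) < 3) abort("Too few rate-curve grid points inside `interval`.")
  v <- curve$value[keep]
  r <- curve$rate[keep]
  if (anchor < v[1] || anchor > v[length(v)]) {
    abort("`anchor` must lie inside `interval`.")
  }
  bad <- r <= rate_floor
  if (any(bad)) {
    abort(sprintf(
      "Modeled rate <= %g in [%.4g, %.4g]; cannot invert the rate there.",
      rate_floor, min(v[bad]), max(v[bad])))
  }
  # ensure the anchor is a grid node so tau(anchor) = 0 exactly
  if (!anchor %in% v) {
    r_anchor <- approx(v, r, xout = anchor)$y
    ord <- order(c(v, anchor))
    v <- c(v, anchor)[ord]
    r <- c(r, r_anchor)[ord]
  }
  # exact integral of 1/linear-interpolant(r) per segment, then shift so
  # the anchor maps to 0
  r1 <- head(r, -1); r2 <- tail(r, -1)
  dv <- diff(v)
  seg <- ifelse(abs(r2 - r1) > 1e-12 * pmax(r1, r2),
                dv * log(r2 / r1) / (r2 - r1),
                dv * 2 / (r1 + r2))
  ct <- c(0, cumsum(seg))
  tau <- ct - ct[which(v == anchor)[1]]
  new_clock_curve(v, tau, "TIRA", anchor, c(interval[1], interval[2]))
}

#' Build a SILA clock from longitudinal samples
#'
#' Sampled iterative local approximation: (i) discrete rates
#' \eqn{\Delta v/\Delta t} are computed from each subject's consecutive
#' sample pairs and assigned to the pair's midpoint value; (ii) the mean rate
#' is estimated at evenly distributed value bins across the interval and
#' smoothed by local linear regression; (iii) Euler's method integrates the
#' rate-versus-level relationship forward and backward from the anchor
#' (\eqn{v_{i+1} = v_i + \hat r(v_i)\,dt}), and the resulting trajectory is
#' inverted to years-from-positivity on a value grid.
#'
#' @param samples Biomarker tibble (`subject_id`, `age`, `value`).
#' @param anchor Positivity threshold mapped to time 0.
#' @param interval Interval of consistent change restricting the clock.
#' @param dt Euler step in years (default 0.05).
#' @param n_value_bins Number of evenly spaced value bins (default 50).
#' @param bandwidth Local-linear smoothing bandwidth as a fraction of the
#'   interval width (default 0.2).
#' @param rate_floor As in [build_tira_clock()].
#' @return A `clock_curve`, as for [build_tira_clock()].
#' @export
build_sila_clock <- function(samples, anchor, interval, dt = 0.05,
                             n_value_bins = 50, bandwidth = 0.2,
                             rate_floor = 1e-4) {
  stopifnot(dt > 0, n_value_bins >= 5, bandwidth > 0)
  lo <- as.numeric(interval[1]); hi <- as.numeric(interval[2])
  if (anchor <= lo || anchor >= hi) abort("`anchor` must lie inside `interval`.")

  pair_rates <- samples |>
    dplyr::arrange(.data$subject_id, .data$age) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::reframe(mid = (head(.data$value, -1) + tail(.data$value, -1)) / 2,
                   drate = diff(.data$value) / diff(.data$age))
  pair_rates <- pair_rates[pair_rates$mid >= lo & pair_rates$mid <= hi, ]
  if (nrow(pair_rates) < n_value_bins / 2) {
    abort("Too few consecutive-pair rates inside `interval`.")
  }

  # mean discrete rate in evenly distributed value bins
  breaks <- seq(lo, hi, length.out = n_value_bins + 1)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  bin <- pmin(pmax(findInterval(pair_rates$mid, breaks,
                                rightmost.closed = TRUE), 1L), n_value_bins)
  bin_mean <- tapply(pair_rates$drate, factor(bin, levels = seq_len(n_value_bins)),
                     mean)
  empty <- is.na(bin_mean)
  if (mean(empty) > 0.2) {
    abort(sprintf("%.0f%% of value bins are empty; data do not span `interval`.",
                  100 * mean(empty)))
  }
  filled <- centers[!empty]
  means <- as.numeric(bin_mean[!empty])

  # local linear smoothing of binned mean rates (Gaussian kernel)
  h <- bandwidth * (hi - lo)
  rate_at <- function(v) {
    vapply(v, function(vi) {
      w <- exp(-0.5 * ((filled - vi) / h)^2)
      x <- filled - vi
      sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
      sy <- sum(w * means); sxy <- sum(w * x * means)
      det <- sw * sxx - sx^2
      if (det < 1e-12) sy / sw else (sxx * sy - sx * sxy) / det
    }, numeric(1))
  }
  smoothed <- rate_at(centers)
  if (any(smoothed <= rate_floor)) {
    bad <- centers[smoothed <= rate_floor]
    abort(sprintf("Smoothed rate <= %g near value %.4g; cannot integrate.",
                  rate_floor, bad[1]))
  }
  rate_interp <- function(v) {
    approx(centers, smoothed, xout = v, rule = 2)$y
  }

  path <- sila_euler_integrate(rate_interp, anchor, c(lo, hi), dt)
  new_clock_curve(path$value, path$years_from_positivity, "SILA", anchor,
                  c(lo, hi))
}

#' Euler integration of a rate-versus-level relationship
#'
#' The integration core of the SILA construction, exposed so its numerical
#' behavior (first-order convergence in `dt`) can be studied with an
#' analytic rate function. Integrates \eqn{dv/d\tau = r(v)} forward and
#' backward from `(anchor, 0)` with step `dt` until the trajectory leaves
#' `interval`, and returns the path as a value-indexed clock table.
#'
#' @param rate_fn Function of the biomarker value returning rates (>0).
#' @param anchor Starting value, mapped to time 0.
#' @param interval Numeric length-2 integration limits.
#' @param dt Euler time step in years.
#' @return A tibble `value`, `years_from_positivity`, strictly increasing
#'   in both columns.
#' @export
sila_euler_integrate <- function(rate_fn, anchor, interval, dt = 0.05) {
  stopifnot(dt > 0, interval[1] < anchor, anchor < interval[2])
  step <- function(direction) {
    v <- anchor; tau <- 0
    vs <- numeric(0); taus <- numeric(0)
    lim <- if (direction > 0) interval[2] else interval[1]
    for (i in seq_len(ceiling(400 / dt))) {
      r <- rate_fn(v)
      if (!is.finite(r) || r <= 0) break
      v_next <- v + direction * r * dt
      tau <- tau + direction * dt
      if ((direction > 0 && v_next > lim) || (direction < 0 && v_next < lim)) break
      v <- v_next
      vs <- c(vs, v); taus <- c(taus, tau)
    }
    list(v = vs, tau = taus)
  }
  fwd <- step(+1)
  bwd <- step(-1)
  v_all <- c(rev(bwd$v), anchor, fwd$v)
  tau_all <- c(rev(bwd$tau), 0, fwd$tau)
  keep <- !duplicated(v_all)
  tibble::tibble(value = v_all[keep], years_from_positivity = tau_all[keep])
}

#' Evaluate or invert a clock curve
#'
#' `clock_time_at_value()` maps a biomarker value to years from positivity
#' by monotone piecewise-linear interpolation; `clock_value_at_time()` is
#' the symmetric inverse lookup. Values outside the clock's valid interval
#' are a hard error, never an extrapolation: outside the interval of
#' consistent change the biomarker-time relationship is not identified, and
#' a very high (or low) value only supports the qualitative statement that
#' the subject is far past (or before) positivity.
#'
#' @param clock A `clock_curve`.
#' @param v Biomarker value(s), strictly inside the valid interval.
#' @param tau Years from positivity, inside the clock's time range.
#' @return Numeric vector.
#' @export
clock_time_at_value <- function(clock, v) {
  stopifnot(inherits(clock, "clock_curve"))
  vi <- attr(clock, "valid_interval")
  out_of_range <- v <= vi[1] | v >= vi[2]
  if (any(out_of_range)) {
    abort(sprintf(
      "Value(s) %s outside the clock's valid interval (%.4g, %.4g); the clock cannot be used there.",
      paste(signif(v[out_of_range], 4), collapse = ", "), vi[1], vi[2]))
  }
  approx(clock$value, clock$years_from_positivity, xout = v, rule = 1)$y
}

#' @rdname clock_time_at_value
#' @export
clock_value_at_time <- function(clock, tau) {
  stopifnot(inherits(clock, "clock_curve"))
  rng <- range(clock$years_from_positivity)
  if (any(tau < rng[1] | tau > rng[2])) {
    abort(sprintf("Time(s) outside the clock's range [%.3g, %.3g] years.",
                  rng[1], rng[2]))
  }
  approx(clock$years_from_positivity, clock$value, xout = tau, rule = 1)$y
}

#' Export or import a clock curve as CSV
#'
#' The table has columns `value`, `years_from_positivity`, `method`,
#' `anchor`, `interval_lower`, `interval_upper`; import validates
#' monotonicity and the anchoring and round-trips exactly.
#'
#' @param clock A `clock_curve`.
#' @param path CSV path.
#' @return `export_clock()` returns `path` invisibly; `import_clock()`
#'   returns a `clock_curve`.
#' @export
export_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_curve"))
  vi <- attr(clock, "valid_interval")
  df <- data.frame(value = clock$value,
                   years_from_positivity = clock$years_from_positivity,
                   method = attr(clock, "method"),
                   anchor = attr(clock, "anchor"),
                   interval_lower = as.numeric(vi[1]),
                   interval_upper = as.numeric(vi[2]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_clock
#' @export
import_clock <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("value", "years_from_positivity", "method", "anchor",
                "interval_lower", "interval_upper")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Clock table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  new_clock_curve(df$value, df$years_from_positivity, df$method[1],
                  df$anchor[1], c(df$interval_lower[1], df$interval_upper[1]))
}
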
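#' Estimate each subject's age at biomarker positivity
#'
#' For every sample with a value inside the clock's valid interval, the
#' estimated age at positivity is the age at the plasma draw minus the clock
#' time at the measured value (for example, an 80-year-old with a value whose
#' clock time is 8.8 years is estimated to have become positive at 71.2).
#' A subject's estimate is the arithmetic mean over all usable samples;
#' samples outside the valid interval are skipped (not clamped) and counted.
#'
#' @param samples Biomarker tibble (`subject_id`, `age`, `value`).
#' @param clock A `clock_curve`.
#' @return A tibble with one row per subject that has at least one usable
#'   sample: `subject_id`, `estimated_age`, `n_samples_used`,
#'   `n_samples_skipped`, and a list-column `per_sample_ages`.
#' @export
#' @examples
#' ck <- build_tira_clock(
#'   tibble::tibble(value = seq(1, 11, length.out = 201), rate = 1),
#'   anchor = 4.06, interval = c(1, 11))
#' estimate_positivity_ages(
#'   tibble::tibble(subject_id = "a", age = 80, value = 7.06), ck)
estimate_positivity_ages <- function(samples, clock) {
  stopifnot(inherits(clock, "clock_curve"))
  vi <- attr(clock, "valid_interval")
  samples |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(x, key) {
      usable <- x$value > vi[1] & x$value < vi[2]
      if (!any(usable)) {
        return(tibble::tibble(estimated_age = NA_real_, n_samples_used = 0L,
                              n_samples_skipped = sum(!usable),
                              per_sample_ages = list(numeric(0))))
      }
      ages <- x$age[usable] - clock_time_at_value(clock, x$value[usable])
      tibble::tibble(estimated_age = mean(ages),
                     n_samples_used = sum(usable),
                     n_samples_skipped = sum(!usable),
                     per_sample_ages = list(ages))
    }) |>
    dplyr::ungroup()
}

#' Observed age at biomarker conversion
#'
#' The observed conversion age is the average of the age at the last
#' non-positive value and the age at the first positive value after it
#' (positivity is strict: value > threshold). With non-monotone series the
#' rule is applied to the *last* non-positive sample: the conversion pair is
#' (age of last non-positive sample, age of first positive sample after it).
#' Returns `NA` when the subject is never positive, always positive, or has
#' no positive sample after the last non-positive one.
#'
#' @param samples Samples for one subject, or a multi-subject tibble when
#'   using [observed_conversion_ages()].
#' @param threshold Positivity threshold.
#' @return A single conversion age in years, or `NA_real_`.
#' @export
observed_conversion_age <- function(samples, threshold) {
  x <- dplyr::arrange(samples, .data$age)
  pos <- x$value > threshold
  if (all(pos) || !any(pos)) return(NA_real_)
  last_neg <- max(which(!pos))
  after <- which(pos & seq_along(pos) > last_neg)
  if (!length(after)) return(NA_real_)
  mean(c(x$age[last_neg], x$age[min(after)]))
}

#' @rdname observed_conversion_age
#' @return `observed_conversion_ages()`: a tibble `subject_id`,
#'   `conversion_age` over all subjects.
#' @export
observed_conversion_ages <- function(samples, threshold) {
  samples |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ tibble::tibble(
      conversion_age = observed_conversion_age(.x, threshold))) |>
    dplyr::ungroup()
}

#' Concordance metrics between two age estimates
#'
#' Adjusted R-squared from the simple linear regression of `y` on `x`,
#' Spearman's rank correlation, and the concordance correlation coefficient
#' (CCC)
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}
#'   {\mathrm{var}(x)+\mathrm{var}(y)+(\bar x-\bar y)^2},}
#' which penalizes location and scale shifts as well as loss of correlation.
#' `ccc_type = "rank"` computes the CCC on global ranks (a non-parametric
#' variant robust to monotone distortions).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @param ccc_type `"lin"` (default) or `"rank"`.
#' @return A tibble with columns `adjusted_r2`, `spearman_rho`, `ccc`, `n`.
#' @export
concordance_metrics <- function(x, y, ccc_type = c("lin", "rank")) {
  ccc_type <- match.arg(ccc_type)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || length(y) != n) abort("Need >= 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0) abort("Zero variance in `x` or `y`.")
  fit <- lm(y ~ x)
  # summary.lm warns on exact fits; perfect agreement is a legitimate input
  tibble::tibble(
    adjusted_r2 = suppressWarnings(summary(fit)$adj.r.squared),
    spearman_rho = cor(x, y, method = "spearman"),
    ccc = if (ccc_type == "lin") lin_ccc(x, y) else lin_ccc(rank(x), rank(y)),
    n = n
  )
}

# Lin's CCC with population (1/n) moments, the standard estimator
lin_ccc <- function(x, y) {
  n <- length(x)
  sxy <- mean((x - mean(x)) * (y - mean(y)))
  sx2 <- mean((x - mean(x))^2)
  sy2 <- mean((y - mean(y))^2)
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}
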
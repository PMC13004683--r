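#' Concordance index for interval-censored data
#'
#' A pair (i, j) is comparable when subject i's event interval wholly
#' precedes subject j's observation window: \eqn{R_i < L_j}, where
#' \eqn{R_i} is finite only for subjects whose event was observed
#' (interval- or left-censored records) and \eqn{L_j} is the last
#' unimpaired assessment for event records or the censoring age for
#' right-censored records. A comparable pair is concordant when the model
#' assigns subject i the higher risk score; risk ties count 1/2.
#'
#' @param model An `ic_cox` fit (used for the risk scores); alternatively
#'   supply `risk` directly.
#' @param records Survival records (defaults to the model's own records).
#' @param risk Optional numeric vector of risk scores overriding the
#'   model's linear predictor.
#' @return The concordance index in `[0, 1]`.
#' @export
ic_cindex <- function(model = NULL, records = NULL, risk = NULL) {
  if (is.null(records)) {
    stopifnot(inherits(model, "ic_cox"))
    records <- model$records
  }
  if (is.null(risk)) {
    stopifnot(inherits(model, "ic_cox"))
    X <- as.matrix(records[, model$covariates, drop = FALSE])
    risk <- as.numeric(sweep(X, 2, model$x_center) %*% model$beta)
  }
  kind <- records$censor_kind
  R_ev <- ifelse(kind %in% c("interval", "left"), records$right, Inf)
  L_win <- ifelse(kind == "left", -Inf, records$left)
  comparable <- outer(R_ev, L_win, `<`)
  diag(comparable) <- FALSE
  if (!any(comparable)) abort("No comparable pairs.")
  risk_gt <- outer(risk, risk, `>`)
  risk_eq <- outer(risk, risk, `==`)
  sum(comparable * (risk_gt + 0.5 * risk_eq)) / sum(comparable)
}

#' Bootstrap the interval-censored C-index
#'
#' Resamples subjects with replacement, refits the model on each resample
#' (warm-started from the full-data fit) and recomputes the C-index, giving
#' a percentile confidence interval.
#'
#' @param records Survival records.
#' @param covariates Covariate names passed to [fit_ic_cox()].
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param conf_level Confidence level for the percentile interval.
#' @return A tibble `cindex`, `conf_low`, `conf_high`, `n_boot`.
#' @export
bootstrap_cindex <- function(records, covariates = "positivity_age",
                             n_boot = 500, seed = 1, conf_level = 0.95) {
  if (n_boot < 100) abort("`n_boot` must be >= 100.")
  set.seed(seed)
  full <- fit_ic_cox(records, covariates, se = FALSE)
  point <- ic_cindex(full)
  init <- list(beta = full$beta)
  stats <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(records), replace = TRUE)
    res <- tryCatch({
      fit <- fit_ic_cox(records[idx, , drop = FALSE], covariates,
                        se = FALSE, init = init)
      ic_cindex(fit)
    }, error = function(e) NA_real_)
    res
  }, numeric(1))
  stats <- stats[is.finite(stats)]
  alpha <- (1 - conf_level) / 2
  qs <- quantile(stats, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(cindex = point, conf_low = qs[1], conf_high = qs[2],
                 n_boot = length(stats))
}

#' Kaplan-Meier estimate on a chosen timescale
#'
#' Product-limit estimator of remaining cognitively unimpaired, via
#' [survival::survfit()]. For interval-censored onsets the event time is
#' placed at the interval's right endpoint (the first symptomatic
#' assessment, i.e. when onset is first observed); set
#' `event_time = "midpoint"` for the interval-midpoint convention.
#' Timescales shift ages by a per-subject reference: years from the first
#' positive sample, from estimated positivity, or from predicted onset.
#'
#' @param records Survival records (`left`, `right`, `censor_kind`).
#' @param reference_age Optional per-subject reference age subtracted from
#'   event/censoring ages (e.g. estimated positivity age); default 0 keeps
#'   the age timescale.
#' @param group Optional grouping factor (e.g. positivity-age bins).
#' @param event_time `"right"` (default) or `"midpoint"`.
#' @return A tibble `group`, `time`, `survival`, `n_risk`, `n_event`.
#' @export
kaplan_meier <- function(records, reference_age = 0, group = NULL,
                         event_time = c("right", "midpoint")) {
  event_time <- match.arg(event_time)
  kind <- records$censor_kind
  if (any(kind == "left")) {
    warn("Left-censored records are treated as events at their right endpoint.")
  }
  is_event <- kind %in% c("interval", "left")
  tt <- ifelse(is_event,
               if (event_time == "right") records$right
               else (records$left + records$right) / 2,
               records$left)
  tt <- tt - reference_age
  if (any(!is.finite(tt))) abort("Non-finite event/censoring times.")
  if (any(tt < 0)) abort("Negative times on the requested timescale.")
  grp <- if (is.null(group)) factor(rep("all", length(tt))) else factor(group)
  out <- lapply(levels(grp), function(g) {
    i <- grp == g
    sf <- survival::survfit(survival::Surv(tt[i], is_event[i]) ~ 1)
    tibble::tibble(group = g, time = sf$time, survival = sf$surv,
                   n_risk = sf$n.risk, n_event = sf$n.event)
  })
  dplyr::bind_rows(out)
}

#' Bin subjects by estimated positivity age
#'
#' The age strata used throughout the analysis: younger than 70, 70 to 80,
#' and 80 or older at estimated biomarker positivity.
#'
#' @param positivity_age Numeric vector of estimated positivity ages.
#' @return A factor with levels `"<70"`, `"70-80"`, `">=80"`.
#' @export
positivity_age_bins <- function(positivity_age) {
  cut(positivity_age, breaks = c(-Inf, 70, 80, Inf),
      labels = c("<70", "70-80", ">=80"), right = FALSE)
}
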
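#' End-to-end clock analysis pipeline
#'
#' Runs the full analysis on a cohort: eligibility filtering, individual
#' rate estimation, the rate-versus-level smooth, the interval of consistent
#' change, clock construction (TIRA and/or SILA), per-subject positivity-age
#' estimation, the interval-censored survival model, the onset-age linear
#' model and its diagnostics. Input is either a generated cohort (via
#' `sim` = a [sim_config()]) or file paths to biomarker/clinical tables.
#'
#' @param sim Optional [sim_config()]; when given, the cohort is simulated.
#' @param biomarker_path,clinical_path Paths to delimited tables (used when
#'   `sim` is `NULL`).
#' @param assay An [assay_config()]; its threshold anchors the clocks.
#' @param methods Clock methods to build: subset of `c("TIRA", "SILA")`.
#' @param interval `"fit"` (default) to estimate the interval of consistent
#'   change from the data, or a numeric length-2 override.
#' @param min_gap Minimum follow-up span (years) for clock inclusion.
#' @param n_boot Bootstrap resamples for the C-index CI; 0 skips the
#'   bootstrap.
#' @param include_left_censored Keep left-censored subjects in the survival
#'   model.
#' @param seed Seed for the bootstrap stage.
#' @param out_dir Optional directory; when given, clock tables, per-subject
#'   estimates and a JSON metrics file are written there.
#' @return A list of class `clock_pipeline` with elements `interval`,
#'   `rate_curve`, `clocks`, `positivity`, `survival`, `onset`, `metrics`.
#' @export
run_pipeline <- function(sim = NULL, biomarker_path = NULL,
                         clinical_path = NULL,
                         assay = assay_config(),
                         methods = c("TIRA", "SILA"),
                         interval = "fit", min_gap = 1, n_boot = 0,
                         include_left_censored = FALSE,
                         seed = 1, out_dir = NULL) {
  methods <- match.arg(methods, c("TIRA", "SILA"), several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (!is.null(sim)) {
    cohort <- stage("simulate", generate_cohort(sim))
    biomarker <- cohort$biomarker
    clinical <- cohort$clinical
  } else {
    biomarker <- stage("ingest", read_biomarker_table(biomarker_path))
    clinical <- stage("ingest", read_clinical_table(clinical_path))
  }

  rates <- stage("rates", {
    eligible <- apply_clock_inclusion(
      biomarker, c(0, Inf), min_gap = min_gap)
    fit_individual_rates(
      biomarker[biomarker$subject_id %in% eligible$subject_id, ])
  })
  rate_curve <- stage("rates", fit_rate_curve(rates))

  interval <- stage("interval", {
    if (identical(interval, "fit")) {
      trim_interval_to_positive_rate(
        rate_curve,
        consistent_change_interval(rate_curve, anchor = assay$threshold),
        anchor = assay$threshold)
    } else {
      iv <- value_interval(interval[1], interval[2])
      if (assay$threshold <= iv[1] || assay$threshold >= iv[2]) {
        abort("The positivity threshold lies outside the clock interval.")
      }
      iv
    }
  })

  clock_samples <- stage("clocks", {
    eligible <- apply_clock_inclusion(biomarker, interval, min_gap = min_gap)
    biomarker[biomarker$subject_id %in% eligible$subject_id, ]
  })
  clocks <- list()
  if ("TIRA" %in% methods) {
    clocks$TIRA <- stage("clocks",
                         build_tira_clock(rate_curve, assay$threshold, interval))
  }
  if ("SILA" %in% methods) {
    clocks$SILA <- stage("clocks",
                         build_sila_clock(clock_samples, assay$threshold, interval))
  }

  positivity <- stage("positivity", {
    purrr::imap(clocks, function(ck, nm) {
      estimate_positivity_ages(biomarker, ck)
    })
  })

  primary <- positivity[[methods[1]]]
  onset_intervals <- stage("survival", derive_onset_intervals(clinical))
  covars <- primary |>
    dplyr::filter(is.finite(.data$estimated_age)) |>
    dplyr::transmute(.data$subject_id, positivity_age = .data$estimated_age)
  records <- stage("survival",
                   make_survival_records(onset_intervals, covars,
                                         include_left_censored = include_left_censored))
  surv_fit <- stage("survival", fit_ic_cox(records))
  cindex <- stage("survival", ic_cindex(surv_fit))
  boot <- if (n_boot > 0) {
    stage("survival", bootstrap_cindex(records, n_boot = n_boot, seed = seed))
  } else NULL

  onset <- stage("onset", {
    obs <- records |>
      dplyr::filter(.data$censor_kind == "interval") |>
      dplyr::transmute(.data$subject_id, onset_age = .data$right,
                       positivity_age = .data$positivity_age)
    if (nrow(obs) >= 3) fit_onset_model(obs) else NULL
  })
  diagnostics <- if (!is.null(onset)) stage("onset", run_diagnostics(onset)) else NULL

  groups <- stage("groups",
                  classify_diagnostic_group(onset_intervals, clinical, primary))

  metrics <- list(
    interval_lower = as.numeric(interval[1]),
    interval_upper = as.numeric(interval[2]),
    n_subjects = length(unique(biomarker$subject_id)),
    n_clock_subjects = length(unique(clock_samples$subject_id)),
    cox_log_hr = unname(surv_fit$beta[1]),
    cindex = cindex,
    median_years_pos60 = median_time_from_positivity(surv_fit, 60),
    median_years_pos80 = median_time_from_positivity(surv_fit, 80),
    onset_intercept = if (!is.null(onset)) onset$intercept else NA_real_,
    onset_slope = if (!is.null(onset)) onset$slope else NA_real_,
    onset_adjusted_r2 = if (!is.null(onset)) onset$adjusted_r2 else NA_real_,
    onset_n = if (!is.null(onset)) onset$n else 0L
  )
  if (!is.null(boot)) {
    metrics$cindex_conf_low <- boot$conf_low
    metrics$cindex_conf_high <- boot$conf_high
  }

  result <- structure(list(
    interval = interval, rate_curve = rate_curve, clocks = clocks,
    positivity = positivity, survival = list(fit = surv_fit, records = records,
                                             cindex = cindex, bootstrap = boot),
    onset = onset, diagnostics = diagnostics, groups = groups,
    metrics = metrics
  ), class = "clock_pipeline")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (nm in names(clocks)) {
      export_clock(clocks[[nm]], file.path(out_dir, paste0("clock_", nm, ".csv")))
    }
    write.csv(primary[, c("subject_id", "estimated_age", "n_samples_used")],
              file.path(out_dir, "positivity_estimates.csv"), row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  result
}

#' @export
print.clock_pipeline <- function(x, ...) {
  cat("Plasma biomarker clock pipeline\n")
  cat(sprintf("  interval of consistent change: (%.3f, %.3f)\n",
              x$interval[1], x$interval[2]))
  cat("  clocks:", paste(names(x$clocks), collapse = ", "), "\n")
  cat(sprintf("  Cox log-HR per year of positivity age: %.3f (C-index %.3f)\n",
              x$metrics$cox_log_hr, x$metrics$cindex))
  if (!is.null(x$onset)) {
    cat(sprintf("  onset model: onset = %.1f + %.3f * positivity_age (adj R2 %.3f, n %d)\n",
                x$metrics$onset_intercept, x$metrics$onset_slope,
                x$metrics$onset_adjusted_r2, x$metrics$onset_n))
  }
  invisible(x)
}
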
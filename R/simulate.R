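#' Parameters of the latent biomarker trajectory
#'
#' The synthetic cohort assumes every converting subject follows one shared
#' monotone trajectory of plasma %p-tau217 against disease time \eqn{\tau}
#' (years from biomarker positivity), a four-parameter logistic
#' \deqn{g(\tau) = f + \frac{M - f}{1 + e^{-k(\tau - \tau_0)}}}
#' with the centering \eqn{\tau_0} chosen so that \eqn{g(0)} equals the
#' positivity threshold (the anchor) exactly. Individuals differ only in the
#' age at which they cross the threshold.
#'
#' @param floor_value Lower asymptote, in biomarker units (%).
#' @param max_value Upper asymptote (%). Must exceed `anchor_value`.
#' @param steepness Logistic growth rate \eqn{k}, per year. Positive.
#' @param anchor_value Positivity threshold mapped to \eqn{\tau = 0}
#'   (default 4.06%, the plasma %p-tau217 value aligned with amyloid PET
#'   Centiloid 20).
#'
#' @return An object of class `curve_params`.
#' @export
#' @examples
#' cp <- curve_params()
#' true_trajectory(0, cp) # the anchor, exactly
curve_params <- function(floor_value = 0.5, max_value = 15,
                         steepness = 0.25, anchor_value = 4.06) {
  stopifnot(is.numeric(floor_value), is.numeric(max_value),
            is.numeric(steepness), is.numeric(anchor_value))
  if (!(floor_value < anchor_value && anchor_value < max_value)) {
    abort("`floor_value` < `anchor_value` < `max_value` is required.")
  }
  if (steepness <= 0) abort("`steepness` must be > 0.")
  structure(
    list(floor_value = floor_value, max_value = max_value,
         steepness = steepness, anchor_value = anchor_value,
         # solve g(0) = anchor for the logistic center
         tau0 = log((max_value - floor_value) / (anchor_value - floor_value) - 1) /
           steepness),
    class = "curve_params"
  )
}

#' Evaluate the latent biomarker trajectory
#'
#' @param tau Years from biomarker positivity (vectorized).
#' @param params A [curve_params()] object.
#' @return Biomarker values (%), strictly increasing in `tau`.
#' @export
true_trajectory <- function(tau, params = curve_params()) {
  stopifnot(inherits(params, "curve_params"))
  with(params, floor_value +
         (max_value - floor_value) / (1 + exp(-steepness * (tau - tau0))))
}

#' Analytic rate of change of the latent trajectory
#'
#' \eqn{g'(\tau)} expressed as a function of the biomarker value \eqn{v},
#' i.e. \eqn{r(v) = g'(g^{-1}(v)) = k (v - f)(M - v)/(M - f)}. Used as the
#' ground-truth rate-versus-level curve in recovery tests.
#'
#' @param value Biomarker values (%), strictly between the asymptotes.
#' @inheritParams true_trajectory
#' @return Rates in % per year.
#' @export
true_rate_at_value <- function(value, params = curve_params()) {
  stopifnot(inherits(params, "curve_params"))
  with(params, steepness * (value - floor_value) * (max_value - value) /
         (max_value - floor_value))
}

#' Inverse of the latent trajectory
#'
#' @inheritParams true_rate_at_value
#' @return Years from positivity at which the trajectory attains `value`.
#' @export
true_time_at_value <- function(value, params = curve_params()) {
  stopifnot(inherits(params, "curve_params"))
  with(params,
       tau0 - log((max_value - floor_value) / (value - floor_value) - 1) /
         steepness)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a longitudinal aging cohort of the kind the clock
#' analysis targets: subjects cross the plasma %p-tau217 positivity threshold
#' at widely varying ages (mean 70, sd 8 years), are sampled every ~2 years
#' over 3-6 plasma draws, and are clinically assessed annually. Symptom onset
#' follows positivity after a lag that shrinks with the age at positivity
#' (intercept 37.4 years, slope -0.39 per year of positivity age, matching a
#' lag of ~14 years at positivity age 60 and ~6 years at 80).
#'
#' @param n_subjects Number of subjects.
#' @param frac_never_positive Fraction of subjects who never cross the
#'   threshold and keep flat low values.
#' @param positivity_age_mean,positivity_age_sd Normal distribution of the
#'   true age at biomarker positivity (years).
#' @param curve_params Latent trajectory, see [curve_params()].
#' @param baseline_offset_range First plasma draw occurs at
#'   `true_positivity_age + runif(min, max)` for converters (years); controls
#'   how much of the trajectory each subject's follow-up covers.
#' @param visit_interval_mean,visit_interval_jitter Plasma draw spacing:
#'   mean interval and half-width of its uniform jitter (years).
#' @param n_visits_range Integer pair: min/max number of plasma draws.
#' @param noise_sd Additive Gaussian measurement noise on the % scale,
#'   truncated so observed values stay nonnegative.
#' @param onset_lag_intercept,onset_lag_slope Linear model of the lag from
#'   positivity to symptom onset as a function of positivity age (years;
#'   slope < 0 makes the lag shorter at older ages).
#' @param onset_lag_sd Gaussian noise on the lag (years).
#' @param assessment_interval Spacing of clinical assessments (years).
#' @param clinical_extra_years Clinical follow-up continues this many years
#'   past the last plasma draw (clinical observation typically outlasts the
#'   biomarker substudy).
#' @param dropout_hazard Per-visit probability of dropping out after each
#'   plasma draw beyond the minimum two.
#' @param frac_non_ad Fraction of never-positive subjects who develop
#'   cognitive impairment with a non-AD syndrome.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 300,
                       frac_never_positive = 0.4,
                       positivity_age_mean = 70,
                       positivity_age_sd = 8,
                       curve_params = plasmaclock::curve_params(),
                       baseline_offset_range = c(-12, 2),
                       visit_interval_mean = 2,
                       visit_interval_jitter = 0.5,
                       n_visits_range = c(3L, 6L),
                       noise_sd = 0.3,
                       onset_lag_intercept = 37.4,
                       onset_lag_slope = -0.39,
                       onset_lag_sd = 2,
                       assessment_interval = 1,
                       clinical_extra_years = 8,
                       dropout_hazard = 0.05,
                       frac_non_ad = 0.1,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              frac_never_positive = frac_never_positive,
              positivity_age_mean = positivity_age_mean,
              positivity_age_sd = positivity_age_sd,
              curve_params = curve_params,
              baseline_offset_range = baseline_offset_range,
              visit_interval_mean = visit_interval_mean,
              visit_interval_jitter = visit_interval_jitter,
              n_visits_range = as.integer(n_visits_range),
              noise_sd = noise_sd,
              onset_lag_intercept = onset_lag_intercept,
              onset_lag_slope = onset_lag_slope,
              onset_lag_sd = onset_lag_sd,
              assessment_interval = assessment_interval,
              clinical_extra_years = clinical_extra_years,
              dropout_hazard = dropout_hazard,
              frac_non_ad = frac_non_ad,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(test, msg) if (!test) abort(paste0("Invalid sim_config: ", msg))
  ok(cfg$n_subjects >= 1, "n_subjects >= 1")
  ok(cfg$frac_never_positive >= 0 && cfg$frac_never_positive <= 1,
     "frac_never_positive in [0, 1]")
  ok(cfg$positivity_age_sd >= 0, "positivity_age_sd >= 0")
  ok(inherits(cfg$curve_params, "curve_params"), "curve_params class")
  ok(length(cfg$n_visits_range) == 2 && cfg$n_visits_range[1] >= 2,
     "n_visits_range[1] >= 2")
  ok(cfg$n_visits_range[2] >= cfg$n_visits_range[1], "n_visits_range ordered")
  ok(cfg$noise_sd >= 0, "noise_sd >= 0")
  ok(cfg$onset_lag_sd >= 0, "onset_lag_sd >= 0")
  ok(cfg$visit_interval_mean > 0, "visit_interval_mean > 0")
  ok(cfg$visit_interval_jitter >= 0 &&
       cfg$visit_interval_jitter < cfg$visit_interval_mean,
     "0 <= visit_interval_jitter < visit_interval_mean")
  ok(cfg$assessment_interval > 0, "assessment_interval > 0")
  ok(cfg$dropout_hazard >= 0 && cfg$dropout_hazard < 1, "dropout_hazard in [0, 1)")
  ok(cfg$frac_non_ad >= 0 && cfg$frac_non_ad <= 1, "frac_non_ad in [0, 1]")
  ok(diff(cfg$baseline_offset_range) > 0, "baseline_offset_range ordered")
  invisible(cfg)
}

#' Generate a synthetic longitudinal cohort
#'
#' Produces the three tables the analysis consumes: a long-format biomarker
#' table (one row per plasma draw), a clinical table (one row per assessment,
#' with CDR and syndrome label), and a ground-truth table for recovery tests.
#' Converting subjects follow the shared latent trajectory shifted to their
#' own positivity age, with additive truncated-Gaussian measurement noise;
#' never-positive subjects produce flat values jittered around the trajectory
#' floor. Clinical assessments are CDR 0 until the first scheduled assessment
#' at or after the true onset age, and CDR > 0 with an AD syndrome from then
#' on. Onsets beyond the end of clinical follow-up are simply unobserved
#' (right censoring arises naturally); subjects already past onset at their
#' first assessment enter impaired (left censoring arises naturally).
#'
#' @param config A [sim_config()].
#' @param assay Assay label written into the biomarker table.
#' @return A list with tibbles `biomarker` (subject_id, age, assay, value),
#'   `clinical` (subject_id, age, cdr, syndrome) and `truth` (subject_id,
#'   true_positivity_age, true_onset_age; `NA` where undefined).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_subjects = 20, seed = 7))
#' head(cohort$biomarker)
generate_cohort <- function(config = sim_config(), assay = "plasma_ptau217") {
  validate_sim_config(config)
  set.seed(config$seed)
  cp <- config$curve_params
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  converter <- runif(n) >= config$frac_never_positive
  pos_age <- ifelse(converter,
                    rnorm(n, config$positivity_age_mean, config$positivity_age_sd),
                    NA_real_)
  lag <- config$onset_lag_intercept + config$onset_lag_slope * pos_age +
    rnorm(n, 0, config$onset_lag_sd)
  onset_age <- ifelse(converter, pos_age + pmax(lag, 1), NA_real_)

  bio <- vector("list", n)
  clin <- vector("list", n)
  non_ad_onset <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    # plasma draw schedule
    n_target <- sample(seq(config$n_visits_range[1], config$n_visits_range[2]), 1)
    base_age <- if (converter[i]) {
      pos_age[i] + runif(1, config$baseline_offset_range[1],
                         config$baseline_offset_range[2])
    } else {
      rnorm(1, config$positivity_age_mean, config$positivity_age_sd)
    }
    gaps <- config$visit_interval_mean +
      runif(n_target - 1, -config$visit_interval_jitter,
            config$visit_interval_jitter)
    ages <- base_age + c(0, cumsum(gaps))
    # geometric per-visit dropout beyond the minimum two draws
    keep <- n_target
    if (n_target > 2) {
      drop_at <- which(runif(n_target - 2) < config$dropout_hazard)
      if (length(drop_at)) keep <- 1 + drop_at[1]
    }
    ages <- ages[seq_len(keep)]

    latent <- if (converter[i]) {
      true_trajectory(ages - pos_age[i], cp)
    } else {
      rep(cp$floor_value, length(ages))
    }
    value <- pmax(latent + rnorm(length(ages), 0, config$noise_sd), 0)
    bio[[i]] <- tibble::tibble(subject_id = ids[i], age = ages,
                               assay = assay, value = value)

    # clinical assessments: annual grid from baseline to past the last draw
    a_ages <- seq(base_age, max(ages) + config$clinical_extra_years,
                  by = config$assessment_interval)
    if (converter[i]) {
      impaired <- a_ages >= onset_age[i]
      # only impaired-at-or-after-onset assessments carry the AD syndrome
      cdr <- ifelse(impaired, 0.5, 0)
      syndrome <- ifelse(impaired, "AD", "none")
      # follow-up stops a couple of assessments after onset is first seen
      if (any(impaired)) {
        stop_idx <- min(which(impaired)) + 2L
        keep_a <- seq_len(min(stop_idx, length(a_ages)))
        a_ages <- a_ages[keep_a]; cdr <- cdr[keep_a]; syndrome <- syndrome[keep_a]
      }
    } else if (runif(1) < config$frac_non_ad) {
      non_ad_onset[i] <- base_age +
        runif(1, 0, diff(range(a_ages)) %||% config$clinical_extra_years)
      impaired <- a_ages >= non_ad_onset[i]
      cdr <- ifelse(impaired, 0.5, 0)
      syndrome <- ifelse(impaired, "non-AD", "none")
    } else {
      cdr <- rep(0, length(a_ages))
      syndrome <- rep("none", length(a_ages))
    }
    clin[[i]] <- tibble::tibble(subject_id = ids[i], age = a_ages,
                                cdr = cdr, syndrome = syndrome)
  }

  list(
    biomarker = dplyr::arrange(dplyr::bind_rows(bio), .data$subject_id, .data$age),
    clinical = dplyr::arrange(dplyr::bind_rows(clin), .data$subject_id, .data$age),
    truth = tibble::tibble(subject_id = ids,
                           true_positivity_age = pos_age,
                           true_onset_age = onset_age)
  )
}

#' Write a generated cohort to delimited text files
#'
#' Writes `biomarker.csv`, `clinical.csv` and `truth.csv` (UTF-8, header row)
#' into `dir`.
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(all(c("biomarker", "clinical", "truth") %in% names(cohort)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(cohort$biomarker, file.path(dir, "biomarker.csv"), row.names = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
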
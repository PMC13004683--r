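#' Assay configuration
#'
#' Holds the positivity threshold and units for one plasma assay. Positivity
#' is strict: a value is positive when it exceeds the threshold (`value >
#' threshold`, not `>=`). The default describes plasma %p-tau217 with the
#' 4.06% threshold aligned to amyloid PET Centiloid 20; [assay_presets()]
#' lists thresholds for the other supported plasma measures.
#'
#' @param name Assay name.
#' @param threshold Positivity threshold in assay units; must be > 0.
#' @param units Units label.
#' @return An object of class `assay_config`.
#' @export
assay_config <- function(name = "plasma_ptau217", threshold = 4.06,
                         units = "%") {
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("`threshold` must be a positive number.")
  }
  structure(list(name = name, threshold = threshold, units = units,
                 direction = "increasing"),
            class = "assay_config")
}

#' Published positivity thresholds for supported plasma assays
#'
#' Thresholds aligned with amyloid PET Centiloid 20 for each assay the clock
#' methodology has been applied to.
#'
#' @return A tibble with columns `assay`, `threshold`, `units`.
#' @export
assay_presets <- function() {
  tibble::tribble(
    ~assay,                        ~threshold, ~units,
    "plasma_ptau217",                   4.06,  "%",
    "c2n_ptau217",                      2.34,  "pg/ml",
    "fujirebio_ptau217",               0.158,  "pg/ml",
    "janssen_ptau217",                0.0615,  "pg/ml",
    "alzpath_ptau217",                 0.444,  "pg/ml",
    "fujirebio_ptau217_ab42",        0.00631,  "ratio"
  )
}

#' Read an assay configuration from a YAML file
#'
#' Expects keys `name`, `threshold` and optionally `units`.
#'
#' @param path Path to a YAML file.
#' @return An [assay_config()] object.
#' @export
read_assay_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read assay configuration files.")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name) || is.null(cfg$threshold)) {
    abort("Assay config must provide `name` and `threshold`.")
  }
  assay_config(name = cfg$name, threshold = cfg$threshold,
               units = cfg$units %||% "")
}

valid_cdr <- c(0, 0.5, 1, 2, 3)
valid_syndrome <- c("none", "AD", "non-AD")

#' Read longitudinal biomarker and clinical tables
#'
#' `read_biomarker_table()` expects columns `subject_id`, `age`, `assay`,
#' `value`; `read_clinical_table()` expects `subject_id`, `age`, `cdr`,
#' `syndrome`. Both validate the rows, reject duplicates at the same
#' (subject, age) for the same assay, and return rows sorted by subject then
#' age.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A tibble.
#' @export
read_biomarker_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "assay", "value")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Biomarker table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  check_numeric_column(df, "age", positive = TRUE)
  check_numeric_column(df, "value")
  dup <- duplicated(df[, c("subject_id", "age", "assay")])
  if (any(dup)) {
    abort(paste0("Duplicate (subject_id, age, assay) rows at row(s): ",
                 paste(which(dup), collapse = ", ")))
  }
  dplyr::arrange(tibble::as_tibble(df[, required]), .data$subject_id, .data$age)
}

#' @rdname read_biomarker_table
#' @export
read_clinical_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "cdr", "syndrome")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("Clinical table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  df$subject_id <- as.character(df$subject_id)
  check_numeric_column(df, "age", positive = TRUE)
  bad_cdr <- which(!df$cdr %in% valid_cdr)
  if (length(bad_cdr)) {
    abort(paste0("Invalid CDR value (allowed: 0, 0.5, 1, 2, 3) at row(s): ",
                 paste(head(bad_cdr, 5), collapse = ", ")))
  }
  bad_syn <- which(!df$syndrome %in% valid_syndrome)
  if (length(bad_syn)) {
    abort(paste0("Invalid syndrome label (allowed: none, AD, non-AD) at row(s): ",
                 paste(head(bad_syn, 5), collapse = ", ")))
  }
  incons <- which(df$cdr == 0 & df$syndrome != "none")
  if (length(incons)) {
    abort(paste0("CDR = 0 rows must have syndrome 'none'; violated at row(s): ",
                 paste(head(incons, 5), collapse = ", ")))
  }
  dup <- duplicated(df[, c("subject_id", "age")])
  if (any(dup)) {
    abort(paste0("Duplicate (subject_id, age) assessments at row(s): ",
                 paste(which(dup), collapse = ", ")))
  }
  dplyr::arrange(tibble::as_tibble(df[, required]), .data$subject_id, .data$age)
}

check_numeric_column <- function(df, col, positive = FALSE) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(x))
  if (length(bad)) {
    abort(paste0("Non-numeric or non-finite `", col, "` at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (positive) {
    neg <- which(x <= 0)
    if (length(neg)) {
      abort(paste0("`", col, "` must be positive; violated at row(s): ",
                   paste(head(neg, 5), collapse = ", ")))
    }
  }
  invisible(TRUE)
}

#' Clock-cohort inclusion filter
#'
#' A subject is eligible for clock construction when at least two of their
#' samples have values strictly inside `interval` and the span of ages among
#' those in-range samples is at least `min_gap` years.
#'
#' @param samples Biomarker tibble (`subject_id`, `age`, `value`).
#' @param interval Numeric length-2: the interval of consistent change
#'   (values strictly inside are usable).
#' @param min_gap Minimum follow-up span in years among in-range samples.
#' @return A tibble with one row per eligible subject: `subject_id`,
#'   `n_in_range`, `span`.
#' @export
apply_clock_inclusion <- function(samples, interval, min_gap = 1) {
  stopifnot(length(interval) == 2, interval[1] < interval[2], min_gap >= 0)
  samples |>
    dplyr::filter(.data$value > interval[1], .data$value < interval[2]) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_in_range = dplyr::n(),
                     span = max(.data$age) - min(.data$age),
                     .groups = "drop") |>
    dplyr::filter(.data$n_in_range >= 2, .data$span >= min_gap)
}

#' Derive the symptom-onset censoring interval for each subject
#'
#' Symptomatic AD onset is interval-censored between the last cognitively
#' unimpaired assessment (CDR = 0) and the first assessment with CDR > 0 and
#' an AD syndrome, and counts only when the subject is impaired with an AD
#' syndrome at their *last* assessment (transient impairment that resolves,
#' or a final non-AD diagnosis, is not AD onset). Subjects unimpaired
#' throughout are right-censored at their last assessment; subjects already
#' impaired with AD at their first assessment are left-censored there.
#'
#' @param clinical Clinical tibble (`subject_id`, `age`, `cdr`, `syndrome`),
#'   sorted by age within subject.
#' @return A tibble with one row per subject: `subject_id`, `left`, `right`,
#'   `censor_kind` in `{"interval", "right", "left"}`. For right-censored
#'   records `right` is `Inf`; for left-censored records `left` is `-Inf`.
#' @export
derive_onset_intervals <- function(clinical) {
  if (nrow(clinical) == 0) abort("Empty clinical table.")
  clinical |>
    dplyr::arrange(.data$subject_id, .data$age) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ onset_interval_one(.x)) |>
    dplyr::ungroup()
}

onset_interval_one <- function(x) {
  n <- nrow(x)
  last_is_ad <- x$cdr[n] > 0 && x$syndrome[n] == "AD"
  if (!last_is_ad) {
    # unimpaired throughout, transient impairment, or final non-AD syndrome:
    # no AD onset observed; right-censor at the last assessment
    return(tibble::tibble(left = x$age[n], right = Inf, censor_kind = "right"))
  }
  first_ad <- min(which(x$cdr > 0 & x$syndrome == "AD"))
  prior_cu <- which(x$cdr == 0 & seq_len(n) < first_ad)
  if (!length(prior_cu)) {
    return(tibble::tibble(left = -Inf, right = x$age[first_ad],
                          censor_kind = "left"))
  }
  tibble::tibble(left = x$age[max(prior_cu)], right = x$age[first_ad],
                 censor_kind = "interval")
}

#' Classify subjects into longitudinal diagnostic groups
#'
#' Four mutually exclusive groups, evaluated at the last assessment:
#' `unimpaired` (CDR 0 throughout), `AD_biomarker_positive` (symptomatic AD
#' at the last assessment with symptoms starting at or after estimated
#' biomarker positivity), `AD_biomarker_negative` (symptomatic AD with
#' symptoms starting before estimated positivity) and `non_AD` (impaired
#' with a non-AD diagnosis at the last assessment). "Symptoms starting after
#' positivity" compares the onset interval's right endpoint (the first
#' symptomatic assessment) to the estimated positivity age; set
#' `endpoint = "left"` to compare the last unimpaired age instead.
#'
#' @param onset_intervals Tibble from [derive_onset_intervals()].
#' @param clinical Clinical tibble used to detect final non-AD impairment.
#' @param positivity Tibble with `subject_id`, `estimated_age` (e.g. from
#'   [estimate_positivity_ages()]); subjects without an estimate get `NA`
#'   comparisons and are grouped on clinical grounds alone.
#' @param endpoint Which interval endpoint to compare to positivity age.
#' @return A tibble `subject_id`, `group`.
#' @export
classify_diagnostic_group <- function(onset_intervals, clinical, positivity,
                                      endpoint = c("right", "left")) {
  endpoint <- match.arg(endpoint)
  last_state <- clinical |>
    dplyr::arrange(.data$subject_id, .data$age) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(last_cdr = dplyr::last(.data$cdr),
                     last_syndrome = dplyr::last(.data$syndrome),
                     .groups = "drop")
  df <- onset_intervals |>
    dplyr::left_join(last_state, by = "subject_id") |>
    dplyr::left_join(positivity[, c("subject_id", "estimated_age")],
                     by = "subject_id")
  onset_ref <- if (endpoint == "right") df$right else df$left
  group <- dplyr::case_when(
    df$last_cdr > 0 & df$last_syndrome == "non-AD" ~ "non_AD",
    df$censor_kind %in% c("interval", "left") &
      !is.na(df$estimated_age) & onset_ref >= df$estimated_age ~
      "AD_biomarker_positive",
    df$censor_kind %in% c("interval", "left") ~ "AD_biomarker_negative",
    TRUE ~ "unimpaired"
  )
  tibble::tibble(subject_id = df$subject_id, group = group)
}
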
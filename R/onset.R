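#' Linear model of symptom-onset age on estimated positivity age
#'
#' Ordinary least squares `onset_age ~ positivity_age` over subjects whose
#' AD symptom onset occurred after estimated biomarker positivity (set
#' `include_onset_before_positivity = TRUE` for the sensitivity analysis
#' that keeps the others). Candidate covariates (e.g. sex, years of
#' education, APOE e4 carrier status) are screened by adding each singly to
#' the base model; a candidate enters the final model only when its
#' coefficient is significant at `alpha`.
#'
#' @param data Tibble with columns `onset_age`, `positivity_age` and any
#'   candidate covariate columns.
#' @param candidate_covariates Character vector of columns to screen.
#' @param alpha Significance level for the covariate screen.
#' @param include_onset_before_positivity Keep subjects with
#'   `onset_age < positivity_age` (default `FALSE`).
#' @return An object of class `onset_model`: list with the fitted `lm`
#'   (`fit`), `intercept`, `slope`, `adjusted_r2`, `spearman_rho`, `n`,
#'   `covariate_screen` (tibble), `data`.
#' @export
fit_onset_model <- function(data, candidate_covariates = character(),
                            alpha = 0.05,
                            include_onset_before_positivity = FALSE) {
  stopifnot(all(c("onset_age", "positivity_age") %in% names(data)))
  df <- data[is.finite(data$onset_age) & is.finite(data$positivity_age), ]
  if (!include_onset_before_positivity) {
    df <- df[df$onset_age >= df$positivity_age, ]
  }
  if (nrow(df) < 3) abort("Need >= 3 subjects with onset and positivity ages.")
  if (var(df$positivity_age) == 0) abort("Degenerate predictor: positivity_age is constant.")

  screen <- purrr::map_dfr(candidate_covariates, function(cv) {
    f <- stats::reformulate(c("positivity_age", cv), response = "onset_age")
    fit_cv <- lm(f, data = df)
    sm <- summary(fit_cv)$coefficients
    rows <- grep(paste0("^", cv), rownames(sm))
    tibble::tibble(covariate = cv,
                   p_value = min(sm[rows, "Pr(>|t|)"]),
                   selected = min(sm[rows, "Pr(>|t|)"]) < alpha)
  })
  selected <- if (nrow(screen)) screen$covariate[screen$selected] else character()
  f <- stats::reformulate(c("positivity_age", selected), response = "onset_age")
  fit <- lm(f, data = df)

  structure(list(
    fit = fit,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)["positivity_age"]),
    adjusted_r2 = suppressWarnings(summary(fit)$adj.r.squared),
    spearman_rho = cor(df$positivity_age, df$onset_age, method = "spearman"),
    n = nrow(df),
    covariate_screen = screen,
    data = df
  ), class = "onset_model")
}

#' Diagnostics for an onset model
#'
#' Shapiro-Wilk normality of residuals, Breusch-Pagan homoscedasticity,
#' AIC and sequential F-tests comparing linear, quadratic and cubic
#' polynomial specifications, and an influence sensitivity analysis that
#' refits after excluding observations with Cook's distance > 4/n. The
#' primary fit is never altered; the refit is reported alongside it.
#'
#' @param model An `onset_model`.
#' @return A list of class `onset_diagnostics`: `shapiro_p`, `breusch_pagan_p`,
#'   `aic` (named linear/quadratic/cubic), `poly_f_p` (quadratic-vs-linear and
#'   cubic-vs-quadratic F-test p-values), `influential` (subject rows with
#'   Cook's D > 4/n), `refit_slope`, `refit_slope_p`.
#' @export
run_diagnostics <- function(model) {
  stopifnot(inherits(model, "onset_model"))
  fit <- model$fit
  df <- model$data
  res <- residuals(fit)
  n <- model$n

  fits <- list(linear = fit)
  aic <- c(linear = AIC(fit), quadratic = NA_real_, cubic = NA_real_)
  poly_f_p <- c(quadratic_vs_linear = NA_real_, cubic_vs_quadratic = NA_real_)
  if (n >= 4) {
    fits$quadratic <- lm(onset_age ~ poly(positivity_age, 2), data = df)
    aic["quadratic"] <- AIC(fits$quadratic)
    base_lin <- lm(onset_age ~ positivity_age, data = df)
    poly_f_p["quadratic_vs_linear"] <-
      anova(base_lin, fits$quadratic)[2, "Pr(>F)"]
    if (n >= 5) {
      fits$cubic <- lm(onset_age ~ poly(positivity_age, 3), data = df)
      aic["cubic"] <- AIC(fits$cubic)
      poly_f_p["cubic_vs_quadratic"] <-
        anova(fits$quadratic, fits$cubic)[2, "Pr(>F)"]
    }
  }

  cd <- cooks.distance(fit)
  infl <- which(cd > 4 / n)
  refit_slope <- NA_real_
  refit_slope_p <- NA_real_
  if (length(infl) && n - length(infl) >= 3) {
    refit <- lm(onset_age ~ positivity_age, data = df[-infl, ])
    sm <- summary(refit)$coefficients
    refit_slope <- sm["positivity_age", "Estimate"]
    refit_slope_p <- sm["positivity_age", "Pr(>|t|)"]
  }

  structure(list(
    shapiro_p = shapiro.test(res)$p.value,
    breusch_pagan_p = as.numeric(lmtest::bptest(fit)$p.value),
    aic = aic,
    poly_f_p = poly_f_p,
    influential = df[infl, , drop = FALSE],
    cooks_threshold = 4 / n,
    refit_slope = refit_slope,
    refit_slope_p = refit_slope_p
  ), class = "onset_diagnostics")
}

#' Predict onset age from positivity age
#'
#' @param model An `onset_model`.
#' @param positivity_age Numeric vector (for models with screened-in
#'   covariates, supply a data frame via `newdata` instead).
#' @param newdata Optional data frame overriding `positivity_age`.
#' @return Predicted onset ages in years.
#' @export
predict_onset <- function(model, positivity_age = NULL, newdata = NULL) {
  stopifnot(inherits(model, "onset_model"))
  if (is.null(newdata)) {
    newdata <- data.frame(positivity_age = positivity_age)
  }
  as.numeric(predict(model$fit, newdata = newdata))
}

#' Prediction-error metrics
#'
#' Median absolute error, concordance correlation coefficient and adjusted
#' R-squared of predicted versus observed onset ages. Supports
#' train-on-one-cohort / evaluate-on-another workflows: fit the model on
#' cohort A, predict for cohort B, then call this on the B pairs.
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return A tibble `mdae`, `ccc`, `adjusted_r2`, `n`.
#' @export
prediction_error <- function(predicted, observed) {
  if (!length(predicted) || length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must be nonempty and equal length.")
  }
  cm <- concordance_metrics(predicted, observed)
  tibble::tibble(mdae = median(abs(predicted - observed)),
                 ccc = cm$ccc, adjusted_r2 = cm$adjusted_r2,
                 n = length(predicted))
}

#' @export
print.onset_model <- function(x, ...) {
  cat("Onset-age model: onset_age ~ positivity_age\n")
  cat(sprintf("  onset = %.2f + %.3f * positivity_age   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("  adjusted R2 = %.3f, Spearman rho = %.3f\n",
              x$adjusted_r2, x$spearman_rho))
  invisible(x)
}

#' @export
tidy.onset_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                 std.error = sm[, "Std. Error"],
                 statistic = sm[, "t value"], p.value = sm[, "Pr(>|t|)"])
}

#' @export
glance.onset_model <- function(x, ...) {
  tibble::tibble(adjusted_r2 = x$adjusted_r2, spearman_rho = x$spearman_rho,
                 n = x$n, sigma = summary(x$fit)$sigma, aic = AIC(x$fit))
}
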
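test_that("an exact linear relationship is fitted perfectly", {
  pos <- c(62, 67, 71, 76, 83)
  df <- tibble::tibble(positivity_age = pos, onset_age = 30 + 0.6 * pos)
  m <- fit_onset_model(df)
  expect_equal(m$intercept, 30, tolerance = 1e-9)
  expect_equal(m$slope, 0.6, tolerance = 1e-9)
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(max(abs(residuals(m$fit))), 0, tolerance = 1e-9)
})

test_that("coefficients match the hand normal-equation solution", {
  x <- c(60, 64, 70, 77, 85)
  y <- c(75, 74, 82, 84, 93)
  # closed-form simple regression: b = S_xy / S_xx, a = ybar - b xbar
  b_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a_hand <- mean(y) - b_hand * mean(x)
  m <- fit_onset_model(tibble::tibble(positivity_age = x, onset_age = y))
  expect_equal(m$slope, b_hand, tolerance = 1e-12)
  expect_equal(m$intercept, a_hand, tolerance = 1e-12)
  expect_equal(m$n, 5L)
})

test_that("onset-before-positivity subjects are excluded unless requested", {
  df <- tibble::tibble(positivity_age = c(60, 65, 70, 75, 80),
                       onset_age = c(75, 77, 80, 84, 70))
  m <- fit_onset_model(df)
  expect_equal(m$n, 4L)
  m2 <- fit_onset_model(df, include_onset_before_positivity = TRUE)
  expect_equal(m2$n, 5L)
  expect_error(fit_onset_model(df[1, ]), ">= 3")
  expect_error(
    fit_onset_model(tibble::tibble(positivity_age = rep(70, 4),
                                   onset_age = 71:74)),
    "Degenerate")
})

test_that("covariate screening admits only significant candidates", {
  set.seed(55)
  n <- 80
  pos <- runif(n, 60, 85)
  strong <- rnorm(n)
  noise <- rnorm(n)
  df <- tibble::tibble(positivity_age = pos,
                       onset_age = 20 + 0.7 * pos + 3 * strong + rnorm(n),
                       strong = strong, noise = noise)
  m <- fit_onset_model(df, candidate_covariates = c("strong", "noise"))
  sc <- m$covariate_screen
  expect_true(sc$selected[sc$covariate == "strong"])
  expect_false(sc$selected[sc$covariate == "noise"])
  expect_true("strong" %in% names(coef(m$fit)))
  expect_false("noise" %in% names(coef(m$fit)))
})

test_that("the generator's negative lag slope yields a fitted slope below 1", {
  co <- generate_cohort(sim_config(n_subjects = 300, seed = 37))
  oi <- derive_onset_intervals(co$clinical)
  obs <- oi[oi$censor_kind == "interval", ]
  df <- merge(obs, co$truth, by = "subject_id")
  m <- fit_onset_model(tibble::tibble(positivity_age = df$true_positivity_age,
                                      onset_age = df$right))
  expect_lt(m$slope, 1)
  # onset - positivity = a + (b - 1) pos: the lag shrinks with age
  lag_slope <- coef(lm(I(df$right - df$true_positivity_age) ~
                         df$true_positivity_age))[2]
  expect_equal(unname(lag_slope), m$slope - 1, tolerance = 1e-9)
  expect_lt(lag_slope, 0)
})

test_that("diagnostics flag constructed outliers and prefer the true order", {
  set.seed(91)
  pos <- runif(40, 60, 85)
  df <- tibble::tibble(positivity_age = pos,
                       onset_age = 25 + 0.65 * pos + rnorm(40, 0, 1.5))
  df$onset_age[7] <- df$onset_age[7] + 25  # gross outlier
  m <- fit_onset_model(df)
  d <- run_diagnostics(m)
  expect_true(df$positivity_age[7] %in% d$influential$positivity_age)
  expect_true(is.finite(d$refit_slope))
  expect_true(all(is.finite(d$aic)))
  expect_true(all(d$poly_f_p >= 0 & d$poly_f_p <= 1, na.rm = TRUE))
})

test_that("Shapiro-Wilk p-values are uniform under Gaussian residuals", {
  set.seed(101)
  reps <- 300
  ps <- vapply(seq_len(reps), function(r) {
    pos <- runif(30, 60, 85)
    df <- tibble::tibble(positivity_age = pos,
                         onset_age = 25 + 0.65 * pos + rnorm(30, 0, 2))
    run_diagnostics(fit_onset_model(df))$shapiro_p
  }, numeric(1))
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("AIC prefers the linear model under a linear truth", {
  set.seed(111)
  wins <- vapply(1:100, function(r) {
    pos <- runif(40, 60, 85)
    df <- tibble::tibble(positivity_age = pos,
                         onset_age = 25 + 0.65 * pos + rnorm(40, 0, 2))
    d <- run_diagnostics(fit_onset_model(df))
    d$aic["linear"] < d$aic["cubic"]
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("prediction is affine and errors match hand computations", {
  df <- tibble::tibble(positivity_age = c(60, 65, 70, 75, 82),
                       onset_age = c(74, 77, 82, 83, 91))
  m <- fit_onset_model(df)
  lambda <- 0.3; x1 <- 63; x2 <- 79
  expect_equal(predict_onset(m, lambda * x1 + (1 - lambda) * x2),
               lambda * predict_onset(m, x1) +
                 (1 - lambda) * predict_onset(m, x2),
               tolerance = 1e-10)

  obs <- c(74, 77, 82, 83, 91)
  expect_equal(prediction_error(obs, obs)$mdae, 0)
  expect_equal(prediction_error(obs, obs)$ccc, 1)
  expect_equal(prediction_error(obs + 2, obs)$mdae, 2)
  pred <- c(73, 79, 80, 86, 90)
  # hand-sorted absolute differences: 1, 2, 2, 3, 1 -> median 2
  expect_equal(prediction_error(pred, obs)$mdae, 2)
  expect_error(prediction_error(numeric(0), numeric(0)), "nonempty")
})

test_that("cross-cohort prediction error is close to within-cohort error", {
  make_pairs <- function(seed) {
    co <- generate_cohort(sim_config(n_subjects = 300, seed = seed))
    oi <- derive_onset_intervals(co$clinical)
    obs <- oi[oi$censor_kind == "interval", ]
    df <- merge(obs, co$truth, by = "subject_id")
    tibble::tibble(positivity_age = df$true_positivity_age,
                   onset_age = df$right)
  }
  a <- make_pairs(61); b <- make_pairs(62)
  m_a <- fit_onset_model(a)
  m_b <- fit_onset_model(b)
  within_b <- prediction_error(predict_onset(m_b, b$positivity_age),
                               b$onset_age)$mdae
  cross_b <- prediction_error(predict_onset(m_a, b$positivity_age),
                              b$onset_age)$mdae
  expect_lt(abs(cross_b - within_b), 1)
})

test_that("tidy and glance summarize fitted models", {
  df <- tibble::tibble(positivity_age = c(60, 65, 70, 75, 82),
                       onset_age = c(74, 77, 82, 83, 91))
  m <- fit_onset_model(df)
  td <- tidy(m)
  expect_setequal(td$term, c("(Intercept)", "positivity_age"))
  gl <- glance(m)
  expect_equal(gl$n, 5L)
  expect_true(is.finite(gl$aic))
})
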
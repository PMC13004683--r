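test_that("constant covariate is unidentifiable and reduces to Turnbull", {
  sim <- simulate_ic_records(n = 120, beta_true = 0, seed = 7)
  rec <- dplyr::mutate(sim$records, x = 1)
  expect_warning(fit <- fit_ic_cox(rec, covariates = "x", se = FALSE),
                 "unidentifiable")
  expect_equal(unname(fit$beta), 0)

  # independent oracle: the nonparametric Turnbull estimator
  L <- rec$left
  R <- ifelse(is.finite(rec$right), rec$right, NA)
  sf <- survival::survfit(survival::Surv(L, R, type = "interval2") ~ 1)
  s_turnbull <- stats::stepfun(sf$time, c(1, sf$surv))
  s_model <- exp(-fit$baseline$cumhaz)
  expect_lt(max(abs(s_model - s_turnbull(fit$baseline$time))), 1e-3)
})

test_that("log-likelihood trace is nondecreasing and fits are deterministic", {
  sim <- simulate_ic_records(n = 150, seed = 3)
  f1 <- fit_ic_cox(sim$records, covariates = "x", se = FALSE)
  expect_true(all(diff(f1$loglik_trace) >= -1e-10))
  f2 <- fit_ic_cox(sim$records, covariates = "x", se = FALSE)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$baseline, f2$baseline)
})

test_that("interval-censored fit recovers a known log hazard ratio", {
  # scaled-down recovery run; the full 50-replicate study is in the
  # acceptance suite
  reps <- 10
  res <- vapply(seq_len(reps), function(r) {
    sim <- simulate_ic_records(n = 400, beta_true = log(2), seed = 100 + r)
    fit <- fit_ic_cox(sim$records, covariates = "x")
    oracle <- survival::coxph(survival::Surv(sim$t_true, rep(1, 400)) ~ sim$x)
    c(beta = unname(fit$beta), se = unname(fit$se),
      oracle = unname(coef(oracle)))
  }, numeric(3))
  covered <- abs(res["beta", ] - log(2)) <= 2 * res["se", ]
  expect_gte(sum(covered), reps - 1)
  # estimates center on the truth and track the uncensored oracle
  expect_lt(abs(mean(res["beta", ]) - log(2)), 0.1)
  expect_lt(abs(mean(res["beta", ] - res["oracle", ])), 0.1)
})

test_that("predicted survival has proportional-hazards structure", {
  sim <- simulate_ic_records(n = 200, seed = 5)
  fit <- fit_ic_cox(sim$records, covariates = "x", se = FALSE)
  ages <- seq(0, 28, by = 0.5)
  s0 <- predict_survival(fit, 0, ages)
  s1 <- predict_survival(fit, 1, ages)
  expect_true(all(diff(s0$survival) <= 1e-12))
  expect_true(all(s1$survival <= s0$survival + 1e-12))
  # log-log survival curves are parallel where both are strictly inside (0,1)
  in01 <- s0$survival < 1 & s0$survival > 0.01 & s1$survival > 0.01
  ratio <- log(s1$survival[in01]) / log(s0$survival[in01])
  expect_lt(diff(range(ratio)), 1e-6)
})

test_that("median onset time handles flat and crossing curves", {
  sim <- simulate_ic_records(n = 200, seed = 6)
  fit <- fit_ic_cox(sim$records, covariates = "x", se = FALSE)
  m0 <- median_time_from_positivity(fit, 0)
  expect_true(is.finite(m0))
  # a zero-hazard model never reaches the median
  flat <- fit
  flat$baseline$hazard_jump <- rep(0, nrow(flat$baseline))
  flat$baseline$cumhaz <- rep(0, nrow(flat$baseline))
  expect_true(all(predict_survival(flat, 0, c(1, 10, 20))$survival == 1))
  expect_true(is.na(median_time_from_positivity(flat, 0)))
})

test_that("concordance index matches exhaustive pair enumeration", {
  # four records, all pairwise relations hand-enumerable
  rec <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    left = c(2, 5, 9, 12),
    right = c(3, 6, 10, Inf),
    censor_kind = c("interval", "interval", "interval", "right"),
    x = c(4, 3, 2, 1)
  )
  risk <- rec$x
  # brute force with explicit loops, independent of the implementation
  num <- 0; den <- 0
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ri <- if (rec$censor_kind[i] == "right") Inf else rec$right[i]
    if (ri < rec$left[j]) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  expect_equal(ic_cindex(records = rec, risk = risk), num / den)
  expect_equal(ic_cindex(records = rec, risk = risk), 1)
  # reversing the scores reverses concordance
  expect_equal(ic_cindex(records = rec, risk = -risk), 0)
  # ties score one half
  expect_equal(ic_cindex(records = rec, risk = rep(1, 4)), 0.5)
})

test_that("concordance is invariant under monotone risk transforms", {
  sim <- simulate_ic_records(n = 120, seed = 11)
  risk <- sim$x + runif(120, 0, 0.1)
  c1 <- ic_cindex(records = sim$records, risk = risk)
  c2 <- ic_cindex(records = sim$records, risk = exp(3 * risk) + 5)
  expect_equal(c1, c2)
})

test_that("random risk scores give chance-level concordance", {
  set.seed(77)
  sim <- simulate_ic_records(n = 300, beta_true = 0, seed = 15)
  cs <- vapply(1:40, function(i) {
    ic_cindex(records = sim$records, risk = sample(300))
  }, numeric(1))
  mc_se <- sd(cs) / sqrt(length(cs))
  expect_lt(abs(mean(cs) - 0.5), 3 * mc_se + 0.01)
})

test_that("bootstrap C-index returns a sane percentile interval", {
  sim <- simulate_ic_records(n = 120, seed = 21)
  expect_error(bootstrap_cindex(sim$records, "x", n_boot = 10), ">= 100")
  bt <- bootstrap_cindex(sim$records, covariates = "x", n_boot = 100,
                         seed = 4)
  expect_true(bt$conf_low <= bt$cindex && bt$cindex <= bt$conf_high)
  expect_gt(bt$cindex, 0.5)
  # seeded: identical on repeat
  bt2 <- bootstrap_cindex(sim$records, covariates = "x", n_boot = 100,
                          seed = 4)
  expect_equal(bt, bt2)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  rec <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    left = c(0.5, 1.5, 1.6),
    right = c(1, Inf, 2),
    censor_kind = c("interval", "right", "interval")
  )
  km <- kaplan_meier(rec)
  # events at 1 and 2, censored at 1.5: S(1) = 2/3, S(2) = 0
  expect_equal(km$survival[km$time == 1], 2 / 3)
  expect_equal(km$survival[km$time == 2], 0)

  # no events: survival stays 1
  rec2 <- tibble::tibble(subject_id = c("a", "b"), left = c(3, 4),
                         right = Inf, censor_kind = "right")
  expect_true(all(kaplan_meier(rec2)$survival == 1))

  # all events at the same time: a single drop to 0
  rec3 <- tibble::tibble(subject_id = c("a", "b"), left = c(1, 1),
                         right = c(2, 2), censor_kind = "interval")
  expect_equal(kaplan_meier(rec3)$survival, 0)

  # timescale shift and the negative-time guard
  km_shift <- kaplan_meier(rec, reference_age = 0.25)
  expect_equal(sort(km_shift$time), sort(km$time - 0.25))
  expect_error(kaplan_meier(rec, reference_age = 10), "Negative")

  # midpoint convention moves the event time
  km_mid <- kaplan_meier(rec3, event_time = "midpoint")
  expect_equal(km_mid$time, 1.5)
})

test_that("positivity-age bins use the three published strata", {
  b <- positivity_age_bins(c(65, 70, 75, 80, 85))
  expect_equal(as.character(b), c("<70", "70-80", "70-80", ">=80", ">=80"))
})
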
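test_that("per-subject OLS path recovers exact two-point slopes", {
  tb <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:12), each = 2),
    age = rep(c(60, 62), 12),
    value = as.vector(vapply(1:12, function(i) c(2, 4) + 0.1 * i, numeric(2)))
  )
  rates <- fit_individual_rates(tb, method = "ols")
  expect_equal(rates$rate, rep(1, 12), tolerance = 1e-12)
  # midpoint of a two-point line is the mean of the two values
  expect_equal(rates$midpoint_value, 3 + 0.1 * (1:12), tolerance = 1e-12)
  expect_equal(rates$followup_span, rep(2, 12))
})

test_that("identical linear trajectories give the common slope for everyone", {
  tb <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:15),
                           age = c(60, 62, 64))
  tb$value <- 1 + 0.5 * tb$age
  # degenerate random effects: whether the mixed model survives with
  # near-zero variances or falls back to OLS, every slope is the common one
  rates <- suppressWarnings(fit_individual_rates(tb))
  expect_equal(rates$rate, rep(0.5, 15), tolerance = 1e-6)
})

test_that("subjects with one sample are skipped with a warning", {
  tb <- tibble::tibble(subject_id = c("a", "a", "b"),
                       age = c(60, 62, 70), value = c(1, 2, 3))
  expect_warning(rates <- fit_individual_rates(tb, method = "ols"),
                 "skipped")
  expect_equal(rates$subject_id, "a")
})

test_that("mixed-model rates track the generator's analytic derivative", {
  co <- generate_cohort(sim_config(n_subjects = 250, seed = 17))
  eligible <- apply_clock_inclusion(co$biomarker, c(1.06, 10.45), 1)
  rates <- fit_individual_rates(
    co$biomarker[co$biomarker$subject_id %in% eligible$subject_id, ])
  mid <- rates$midpoint_value
  keep <- mid > 2 & mid < 8
  ratio <- rates$rate[keep] / true_rate_at_value(mid[keep])
  # noisy per-subject estimates, but centered on the analytic rate
  expect_lt(abs(mean(ratio) - 1), 0.15)
})

test_that("rate estimation is equivariant under shifting all ages", {
  co <- small_cohort(seed = 23, n = 40)
  shifted <- dplyr::mutate(co$biomarker, age = age + 7)
  r1 <- fit_individual_rates(co$biomarker, method = "ols")
  r2 <- fit_individual_rates(shifted, method = "ols")
  expect_equal(r1$rate, r2$rate, tolerance = 1e-10)
  expect_equal(r1$midpoint_value, r2$midpoint_value, tolerance = 1e-10)
})

test_that("rate curve recovers linear and constant generating functions", {
  set.seed(41)
  v <- runif(300, 1, 10)
  rates <- tibble::tibble(subject_id = as.character(seq_along(v)),
                          rate = 0.2 * v + rnorm(300, 0, 0.02),
                          midpoint_value = v, followup_span = 2)
  rc <- fit_rate_curve(rates)
  expect_equal(nrow(rc), 512)
  central <- rc$value > quantile(v, 0.1) & rc$value < quantile(v, 0.9)
  rel <- rc$rate[central] / (0.2 * rc$value[central]) - 1
  expect_lt(max(abs(rel)), 0.1)

  rates_const <- dplyr::mutate(rates, rate = 0.7)
  rc2 <- fit_rate_curve(rates_const)
  expect_equal(rc2$rate, rep(0.7, 512), tolerance = 1e-8)
  expect_lt(diff(range(rc2$pred_se)), 1e-6)

  # deterministic refit
  rc3 <- fit_rate_curve(rates)
  expect_identical(rc$rate, rc3$rate)

  expect_error(fit_rate_curve(rates[1:5, ]), ">= 20")
  expect_error(fit_rate_curve(dplyr::mutate(rates, midpoint_value = 5)),
               "Degenerate")
})

test_that("consistent-change interval is the anchored low-variance run", {
  # spikes cover < 10% of the grid so the 90th-percentile cut sits in the
  # (mildly varying) baseline and the bounds land at the spike feet
  grid <- seq(0.5, 11.5, length.out = 601)
  se <- sqrt(0.01 * (1 + 0.1 * sin(grid)) +
               ifelse(grid < 1, (1 - grid)^2 * 1e4, 0) +
               ifelse(grid > 11, (grid - 11)^2 * 1e4, 0))
  curve <- tibble::tibble(value = grid, rate = 1, pred_se = se)
  iv <- consistent_change_interval(curve, anchor = 4.06)
  # brute-force oracle: scan runs of below-threshold variance directly
  cut <- quantile(se^2, 0.9)
  ok <- se^2 < cut
  anchor_idx <- which.min(abs(grid - 4.06))
  i <- anchor_idx; while (i > 1 && ok[i - 1]) i <- i - 1
  j <- anchor_idx; while (j < length(grid) && ok[j + 1]) j <- j + 1
  expect_equal(as.numeric(iv), c(grid[i], grid[j]))
  expect_true(iv[1] >= min(grid) && iv[2] <= max(grid))
  expect_true(iv[1] <= 4.06 && 4.06 <= iv[2])
  # the spikes are excluded
  expect_gt(iv[1], 0.9)
  expect_lt(iv[2], 11.1)

  # uniform variance: the whole grid is uniformly consistent
  curve2 <- tibble::tibble(value = grid, rate = 1, pred_se = 1)
  expect_equal(as.numeric(consistent_change_interval(curve2, 4.06)),
               range(grid))
  # anchor outside the low-variance region errors with diagnostics
  expect_error(consistent_change_interval(curve, anchor = 0.2),
               "outside every low-variance region")
})

test_that("interval intersection reproduces the two-cohort bounds", {
  # the two cohort-specific low-variance intervals reported for plasma
  # %p-tau217, and their published intersection
  iv <- intersect_intervals(value_interval(0.29, 10.45),
                            value_interval(1.06, 10.59))
  expect_equal(as.numeric(iv), c(1.06, 10.45), tolerance = 1e-12)
  # idempotence
  a <- value_interval(2, 6)
  expect_equal(as.numeric(intersect_intervals(a, a)), c(2, 6))
  expect_error(intersect_intervals(value_interval(0, 5), value_interval(6, 9)),
               "disjoint")
})

test_that("positive-rate trimming keeps the anchored positive-rate region", {
  grid <- seq(0, 12, length.out = 601)
  rate <- pmax(0.25 * (grid - 0.5) * (15 - grid) / 14.5, 0)
  curve <- tibble::tibble(value = grid, rate = rate, pred_se = 0.1)
  iv <- trim_interval_to_positive_rate(curve, c(0, 12), anchor = 4.06,
                                       frac = 0.1)
  r_anchor <- 0.25 * (4.06 - 0.5) * (15 - 4.06) / 14.5
  expect_true(all(rate[grid >= iv[1] & grid <= iv[2]] > 0.1 * r_anchor))
  expect_gt(iv[1], 0.5)
})
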
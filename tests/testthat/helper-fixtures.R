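# Shared fixtures, built in code at test time.

# a clock with constant rate c over (lo, hi): tau(v) = (v - anchor)/c
constant_rate_clock <- function(c_rate = 1, anchor = 4.06, lo = 1, hi = 11,
                                n = 201) {
  build_tira_clock(
    tibble::tibble(value = seq(lo, hi, length.out = n), rate = c_rate),
    anchor = anchor, interval = c(lo, hi))
}

# clock calibrated so that tau(7.06) = 8.8 exactly (the worked example):
# constant rate (7.06 - 4.06)/8.8
worked_example_clock <- function() {
  constant_rate_clock(c_rate = (7.06 - 4.06) / 8.8)
}

# analytic clock on the generator's true trajectory: rate curve sampled from
# the closed-form derivative, integrated by the TIRA quadrature
true_clock <- function(params = curve_params(), lo = 1.06, hi = 10.45,
                       n = 512) {
  grid <- seq(lo, hi, length.out = n)
  build_tira_clock(
    tibble::tibble(value = grid, rate = true_rate_at_value(grid, params)),
    anchor = params$anchor_value, interval = c(lo, hi))
}

# small deterministic cohort reused across tests
small_cohort <- function(seed = 11, n = 120) {
  generate_cohort(sim_config(n_subjects = n, seed = seed))
}

# interval-censored records with known exponential truth:
# hazard = rate0 * exp(beta_true * x), assessments on a regular grid
simulate_ic_records <- function(n = 400, beta_true = log(2), rate0 = 0.15,
                                grid_step = 2, horizon = 30, seed = 1) {
  set.seed(seed)
  x <- rep(c(0, 1), length.out = n)
  t_true <- rexp(n, rate = rate0 * exp(beta_true * x))
  left <- floor(t_true / grid_step) * grid_step
  right <- left + grid_step
  kind <- ifelse(right > horizon, "right", "interval")
  left[kind == "right"] <- horizon
  right[kind == "right"] <- Inf
  list(records = tibble::tibble(subject_id = as.character(seq_len(n)),
                                left = left, right = right,
                                censor_kind = kind, x = x),
       t_true = t_true, x = x)
}
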
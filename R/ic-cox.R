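#' Assemble interval-censored survival records
#'
#' Joins onset intervals with covariates into the record table consumed by
#' [fit_ic_cox()]. The primary covariate is the estimated age at biomarker
#' positivity.
#'
#' @param onset_intervals Tibble from [derive_onset_intervals()].
#' @param covariates Tibble with `subject_id` and covariate columns.
#' @param include_left_censored Keep left-censored subjects (the
#'   impaired-at-baseline sensitivity analysis); default `TRUE`.
#' @return A tibble `subject_id`, `left`, `right`, `censor_kind`, plus the
#'   covariate columns; rows with missing covariates are dropped.
#' @export
make_survival_records <- function(onset_intervals, covariates,
                                  include_left_censored = TRUE) {
  out <- dplyr::inner_join(onset_intervals, covariates, by = "subject_id")
  if (!include_left_censored) {
    out <- dplyr::filter(out, .data$censor_kind != "left")
  }
  cov_cols <- setdiff(names(covariates), "subject_id")
  out[complete.cases(out[, cov_cols, drop = FALSE]), , drop = FALSE]
}

# Turnbull support: merge all left endpoints (L) and right endpoints (R);
# an innermost interval is an L immediately followed by an R in the merged
# order (L sorts before R on ties). All probability mass -- here, all jumps
# of the baseline cumulative hazard -- can be placed at the right endpoints
# of innermost intervals.
turnbull_support <- function(left, right) {
  lpts <- left[is.finite(left) | left == -Inf]
  rpts <- right[is.finite(right)]
  if (!length(rpts)) abort("No finite event endpoints; all records right-censored.")
  ep <- rbind(data.frame(t = lpts, type = 0L), data.frame(t = rpts, type = 1L))
  # intervals are half-open (L, R]: an event can sit exactly at R but not
  # at L, so at tied times right endpoints precede left endpoints
  ep <- ep[order(ep$t, -ep$type), ]
  innermost_r <- ep$t[ep$type == 1L & c(FALSE, head(ep$type, -1) == 0L)]
  sort(unique(innermost_r))
}

#' Interval-censored proportional hazards regression
#'
#' Fits the semiparametric Cox model to interval-, right- and left-censored
#' event times by maximizing
#' \deqn{\prod_i \left[S(L_i \mid x_i) - S(R_i \mid x_i)\right]}
#' (right-censored records contribute \eqn{S(L_i)}, left-censored records
#' \eqn{1 - S(R_i)}) with \eqn{S(t \mid x) = \exp(-\Lambda_0(t) e^{x\beta})}
#' and \eqn{\Lambda_0} a nondecreasing step function with jumps on the
#' Turnbull innermost-interval endpoints. Estimation alternates (a) an
#' expectation-maximization update of the baseline jumps, derived from a
#' latent Poisson-process representation of the interval-censored
#' likelihood, with (b) a likelihood-ascent (Newton-type, backtracking)
#' update of \eqn{\beta}; both steps increase the observed-data
#' log-likelihood, so the recorded trace is nondecreasing by construction.
#' Standard errors for \eqn{\beta} come from the curvature of the profile
#' log-likelihood (baseline refitted at perturbed \eqn{\beta}).
#'
#' @param records Tibble from [make_survival_records()] (columns `left`,
#'   `right`, `censor_kind`, covariates).
#' @param covariates Character vector of covariate column names.
#' @param max_iter Maximum outer iterations.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param se Compute profile-likelihood standard errors (default `TRUE`).
#' @param init Optional list with starting `beta` and `lambda` (warm start).
#' @return An object of class `ic_cox`: list with `beta`, `se`,
#'   `baseline` (tibble `time`, `hazard_jump`, `cumhaz`), `loglik_trace`,
#'   `converged`, `n`, `covariates`, `records`.
#' @export
fit_ic_cox <- function(records, covariates = "positivity_age",
                       max_iter = 500, tol = 1e-6, se = TRUE, init = NULL) {
  stopifnot(all(c("left", "right", "censor_kind") %in% names(records)),
            all(covariates %in% names(records)))
  kind <- records$censor_kind
  if (!any(kind %in% c("interval", "left"))) {
    abort("Need at least one non-right-censored record.")
  }
  X <- as.matrix(records[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  no_var <- apply(X, 2, function(z) length(unique(z)) < 2)
  if (all(no_var)) {
    warn("Covariate(s) constant across subjects; beta is unidentifiable and fixed at 0.")
  }
  # center covariates for numerical stability; baseline refers to x = mean
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)

  L <- records$left
  R <- records$right
  L[kind == "left"] <- -Inf
  R[kind == "right"] <- Inf
  support <- turnbull_support(L, R)
  K <- length(support)
  # indicator matrices: support point k is <= L_i / <= R_i
  AL <- outer(L, support, `>=`) * 1
  AR <- outer(R, support, `>=`) * 1
  is_event <- kind %in% c("interval", "left")
  if (any(is_event & rowSums(AR - AL) == 0)) {
    abort("An event interval contains no Turnbull support point; check the records.")
  }
  # risk region: exposure up to R for event records, up to L for right-censored
  RISK <- AR
  RISK[kind == "right", ] <- AL[kind == "right", , drop = FALSE]

  loglik <- function(beta, lambda) {
    eta <- as.numeric(exp(Xc %*% beta))
    HL <- as.numeric(AL %*% lambda) * eta
    HR <- as.numeric(AR %*% lambda) * eta
    ll <- numeric(length(eta))
    iv <- kind == "interval"
    # log(exp(-HL) - exp(-HR)) = -HL + log1p(-exp(-(HR-HL)))
    ll[iv] <- -HL[iv] + log1p(-exp(-(HR[iv] - HL[iv])))
    ll[kind == "right"] <- -HL[kind == "right"]
    ll[kind == "left"] <- log1p(-exp(-HR[kind == "left"]))
    sum(ll)
  }

  score_beta <- function(beta, lambda) {
    eta <- as.numeric(exp(Xc %*% beta))
    LL <- as.numeric(AL %*% lambda)
    LR <- as.numeric(AR %*% lambda)
    a <- LL * eta; b <- LR * eta
    u <- numeric(length(eta))
    iv <- kind == "interval"
    d <- exp(-a[iv]) - exp(-b[iv])
    u[iv] <- (-a[iv] * exp(-a[iv]) + b[iv] * exp(-b[iv])) / d
    u[kind == "right"] <- -a[kind == "right"]
    lf <- kind == "left"
    u[lf] <- b[lf] * exp(-b[lf]) / (1 - exp(-b[lf]))
    as.numeric(crossprod(Xc, u))
  }

  # one EM update of the baseline jumps at fixed beta (monotone in loglik):
  # latent N_ik ~ Poisson(lambda_k * eta_i) on the risk region; E-step
  # spreads each event's conditional expected count over its window,
  # M-step divides by total exposure.
  em_lambda <- function(beta, lambda) {
    eta <- as.numeric(exp(Xc %*% beta))
    W <- (AR - AL) * is_event  # event windows
    mu_w <- as.numeric(W %*% lambda) * eta
    wt <- ifelse(is_event, 1 / (1 - exp(-pmax(mu_w, 1e-12))), 0)
    # expected counts per support point: sum_i wt_i * eta_i * W_ik * lambda_k
    num <- as.numeric(crossprod(W, wt * eta)) * lambda
    den <- as.numeric(crossprod(RISK, eta))
    ifelse(den > 0, num / den, 0)
  }

  p <- ncol(Xc)
  beta <- init$beta %||% rep(0, p)
  lambda <- init$lambda %||% rep(sum(is_event) / max(sum(RISK), 1), K)
  ll <- loglik(beta, lambda)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # several EM sweeps per outer iteration: each is monotone and cheap,
    # and the baseline converges much more slowly than beta
    ll_em <- loglik(beta, lambda)
    for (sweep in 1:25) {
      lambda <- em_lambda(beta, lambda)
      ll_sw <- loglik(beta, lambda)
      if (ll_sw - ll_em < tol / 10) break
      ll_em <- ll_sw
    }
    if (!all(no_var)) {
      g <- score_beta(beta, lambda)
      # Newton direction from a finite-difference Hessian of the score
      eps <- 1e-6
      H <- vapply(seq_len(p), function(j) {
        bj <- beta; bj[j] <- bj[j] + eps
        (score_beta(bj, lambda) - g) / eps
      }, numeric(p))
      H <- (H + t(H)) / 2
      dir <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(dir) || sum(dir * g) <= 0) {
        # fall back to a Cauchy (steepest-ascent) step
        curv <- as.numeric(crossprod(g, H %*% g))
        dir <- if (is.finite(curv) && curv < 0) -g * sum(g * g) / curv else
          g / max(sqrt(sum(g^2)), 1)
      }
      ll_cur <- loglik(beta, lambda)
      t_step <- 1
      for (bt in 1:30) {
        cand <- beta + t_step * dir
        ll_new <- loglik(cand, lambda)
        if (is.finite(ll_new) && ll_new >= ll_cur) { beta <- cand; break }
        t_step <- t_step / 2
      }
    }
    ll_new <- loglik(beta, lambda)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) { converged <- TRUE; ll <- ll_new; break }
    ll <- ll_new
  }
  if (!converged) {
    abort(paste0("fit_ic_cox did not converge in ", max_iter,
                 " iterations; last log-likelihood ", signif(ll, 8), "."))
  }

  se_beta <- rep(NA_real_, p)
  if (se && !all(no_var)) {
    se_beta <- profile_se(beta, lambda, Xc, loglik, em_lambda, tol)
  }

  structure(list(
    beta = setNames(as.numeric(beta) * ifelse(no_var, 0, 1), covariates),
    se = setNames(se_beta, covariates),
    x_center = setNames(x_center, covariates),
    baseline = tibble::tibble(time = support, hazard_jump = lambda,
                              cumhaz = cumsum(lambda)),
    loglik_trace = trace,
    loglik = ll,
    converged = converged,
    n = nrow(records),
    n_events = sum(is_event),
    covariates = covariates,
    records = records
  ), class = "ic_cox")
}

# curvature of the profile log-likelihood by central differences, with the
# baseline refitted (EM to convergence, warm start) at each perturbed beta
profile_se <- function(beta, lambda, Xc, loglik, em_lambda, tol) {
  p <- length(beta)
  pll <- function(b) {
    lam <- lambda
    ll <- loglik(b, lam)
    for (i in 1:2000) {
      lam <- em_lambda(b, lam)
      ll_new <- loglik(b, lam)
      if (abs(ll_new - ll) < tol) break
      ll <- ll_new
    }
    ll
  }
  vapply(seq_len(p), function(j) {
    h <- max(0.05, abs(beta[j]) * 0.05)
    b_hi <- beta; b_hi[j] <- beta[j] + h
    b_lo <- beta; b_lo[j] <- beta[j] - h
    d2 <- (pll(b_hi) - 2 * pll(beta) + pll(b_lo)) / h^2
    if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
  }, numeric(1))
}

#' Predicted survival from an interval-censored Cox model
#'
#' \eqn{S(a \mid x) = \exp(-\Lambda_0(a) e^{(x - \bar x)\beta})}, evaluated
#' at the requested ages.
#'
#' @param model An `ic_cox` fit.
#' @param covariate_value Named vector (or single number for one-covariate
#'   models) of covariate values.
#' @param ages Ages at which to evaluate the survival function.
#' @return A tibble `age`, `survival`.
#' @export
predict_survival <- function(model, covariate_value, ages) {
  stopifnot(inherits(model, "ic_cox"))
  x <- as.numeric(covariate_value)
  if (length(x) != length(model$beta)) {
    abort("`covariate_value` must match the model's covariates.")
  }
  eta <- exp(sum((x - model$x_center) * model$beta))
  cumhaz <- stats::stepfun(model$baseline$time, c(0, model$baseline$cumhaz))
  tibble::tibble(age = ages, survival = exp(-cumhaz(ages) * eta))
}

#' Median years from positivity until symptomatic AD
#'
#' The first age at which the predicted probability of remaining unimpaired
#' drops to 0.5 or below, minus the age at biomarker positivity. `NA` when
#' the survival curve never reaches 0.5 within the baseline support.
#'
#' @param model An `ic_cox` fit whose (single) covariate is the estimated
#'   positivity age.
#' @param positivity_age Age(s) at biomarker positivity.
#' @return Years from positivity to the median onset age (vectorized).
#' @export
median_time_from_positivity <- function(model, positivity_age) {
  stopifnot(inherits(model, "ic_cox"))
  vapply(positivity_age, function(pa) {
    s <- predict_survival(model, pa, model$baseline$time)
    hit <- which(s$survival <= 0.5)
    if (!length(hit)) return(NA_real_)
    s$age[min(hit)] - pa
  }, numeric(1))
}

#' @export
print.ic_cox <- function(x, ...) {
  cat("Interval-censored proportional hazards model\n")
  cat("  n =", x$n, " (", x$n_events, "non-right-censored )\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  for (j in seq_along(x$beta)) {
    cat(sprintf("  beta[%s] = %.4f (se %.4f)\n", names(x$beta)[j],
                x$beta[j], x$se[j]))
  }
  invisible(x)
}

#' @export
tidy.ic_cox <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = as.numeric(x$beta),
                 std.error = as.numeric(x$se),
                 statistic = as.numeric(x$beta) / as.numeric(x$se),
                 p.value = 2 * pnorm(-abs(as.numeric(x$beta) /
                                            as.numeric(x$se))))
}

#' @export
glance.ic_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 iterations = length(x$loglik_trace) - 1L,
                 converged = x$converged)
}
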
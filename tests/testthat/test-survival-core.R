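test_that("partial likelihood matches hand-enumerated risk sets", {
  # two subjects, both events, single binary column, coef 0:
  # risk sets of sizes 2 and 1 give -log 2 - log 1
  d2 <- toy_dataset(time = c(1, 2), event = c(1, 1), exposure = c(0, 1),
                    mediators = matrix(0, 2, 1))
  expect_equal(log_partial_likelihood(d2, coefs = 0), -log(2),
               tolerance = 1e-12)

  # with all coefficients zero the likelihood is -sum(log risk-set size),
  # including under ties (Breslow: tied subjects share the full risk set)
  tm <- c(3, 1, 2, 2, 5, 4)
  ev <- c(1, 0, 1, 1, 1, 0)
  d6 <- toy_dataset(tm, ev, exposure = c(0, 1, 0, 1, 1, 0),
                    mediators = matrix(rnorm(6), 6, 1))
  rsizes <- vapply(which(ev == 1), function(i) sum(tm >= tm[i]), numeric(1))
  expect_equal(log_partial_likelihood(d6, coefs = c(0, 0), mediators = 1),
               -sum(log(rsizes)), tolerance = 1e-12)

  # brute-force oracle agreement over a coefficient grid, 3 distinct times
  set.seed(5)
  x <- rnorm(3)
  d3 <- toy_dataset(time = c(2, 1, 3), event = c(1, 1, 1),
                    exposure = c(1, 0, 1), mediators = matrix(x, 3, 1))
  for (b in seq(-2, 2, by = 0.25)) {
    expect_equal(log_partial_likelihood(d3, coefs = b, mediators = 1,
                                        include_exposure = FALSE),
                 loglik_oracle(d3$time, d3$event, matrix(x, 3, 1), b),
                 tolerance = 1e-10)
  }

  # oracle agreement with ties, exposure + mediator columns
  set.seed(6)
  for (b1 in c(-0.5, 0.3)) for (b2 in c(-1, 0.7)) {
    expect_equal(
      log_partial_likelihood(d6, coefs = c(b1, b2), mediators = 1),
      loglik_oracle(d6$time, d6$event,
                    cbind(d6$exposure, d6$mediators[, 1]), c(b1, b2)),
      tolerance = 1e-10)
  }

  expect_error(log_partial_likelihood(d2, coefs = c(0, 0)), "length")
  dce <- toy_dataset(c(1, 2), c(0, 0), c(0, 1), matrix(0, 2, 1))
  expect_error(log_partial_likelihood(dce, coefs = 0), "no events")
})

test_that("fit_cox matches survival::coxph (Breslow) in coefficients, SEs and likelihood", {
  skip_if_not_installed("survival")
  ds <- sim_quick(n = 150, p = 6, seed = 31)
  f <- fit_cox(ds, mediators = 1:4)
  cf <- survival::coxph(
    survival::Surv(ds$time, ds$event) ~ ds$exposure + ds$covariates +
      ds$mediators[, 1:4], ties = "breslow")
  expect_equal(unname(f$coefficients), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(f$standard_errors),
               unname(sqrt(diag(vcov(cf)))), tolerance = 1e-7)
  expect_equal(f$log_partial_likelihood, cf$loglik[2], tolerance = 1e-8)
})

test_that("fit_cox flags degenerate designs and datasets", {
  ds <- sim_quick(n = 60, p = 3, seed = 7)
  ds$mediators[, 2] <- ds$mediators[, 1]
  expect_error(fit_cox(ds, mediators = 1:2), "singular information")
  ds$mediators[, 3] <- 1.5
  expect_error(fit_cox(ds, mediators = 3), "singular information")
  dce <- toy_dataset(rexp(20), rep(0, 20), rbinom(20, 1, 0.5),
                     matrix(rnorm(20), 20, 1))
  expect_error(fit_cox(dce), "no events")
})

test_that("fit is invariant to time shifts and positive rescaling", {
  ds <- sim_quick(n = 100, p = 3, seed = 12)
  f0 <- fit_cox(ds, mediators = 1:2)
  ds_shift <- ds
  ds_shift$time <- ds$time + 7.5
  ds_scale <- ds
  ds_scale$time <- ds$time * 3.2
  expect_equal(fit_cox(ds_shift, mediators = 1:2)$coefficients,
               f0$coefficients, tolerance = 1e-10)
  expect_equal(fit_cox(ds_scale, mediators = 1:2)$coefficients,
               f0$coefficients, tolerance = 1e-10)
})

test_that("solution maximizes the partial likelihood", {
  ds <- sim_quick(n = 80, p = 2, seed = 3)
  f <- fit_cox(ds, mediators = 1)
  # score at the optimum is numerically zero
  expect_lt(max(abs(f$score)), 1e-6)
  # beats the zero vector
  expect_gte(f$log_partial_likelihood,
             log_partial_likelihood(ds, coefs = rep(0, 4), mediators = 1))
  # 1-predictor fit agrees with a golden-section 1D maximizer
  f1 <- fit_cox(ds, mediators = 1, include_exposure = FALSE,
                include_covariates = FALSE)
  opt <- optimize(function(b)
    log_partial_likelihood(ds, coefs = b, mediators = 1,
                           include_exposure = FALSE,
                           include_covariates = FALSE),
    interval = c(-5, 5), maximum = TRUE, tol = 1e-9)
  expect_equal(unname(f1$coefficients), opt$maximum, tolerance = 1e-6)
})

test_that("null 1D fits are calibrated: |estimate| < 3 SE in at least 95% of seeds", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 30
    d <- toy_dataset(rexp(n), rbinom(n, 1, 0.8), rbinom(n, 1, 0.5),
                     matrix(rnorm(n), n, 1))
    f <- fit_cox(d, mediators = 1, include_exposure = FALSE)
    abs(f$coefficients[1]) < 3 * f$standard_errors[1]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("parameter recovery on simulated data: truth within 3 SE", {
  cfg <- simulation_config(n = 1000, p = 8, c0 = 1.4)
  ds <- simulate_dataset(cfg, seed = 99)
  f <- fit_cox(ds, mediators = which(cfg$beta != 0))
  truth <- c(cfg$gamma, cfg$theta, cfg$beta[cfg$beta != 0])
  expect_true(all(abs(f$coefficients - truth) < 3 * f$standard_errors))
})

test_that("Breslow baseline cumulative hazard matches hand computation", {
  # 5 subjects, null coefficients: jumps are d_j / |R_j| at event times
  tm <- c(1, 2, 2, 4, 5)
  ev <- c(1, 1, 0, 1, 0)
  d5 <- toy_dataset(tm, ev, exposure = c(0, 1, 0, 1, 0),
                    mediators = matrix(rnorm(5), 5, 1))
  f <- fit_cox(d5, include_covariates = FALSE)
  f$coefficients[] <- 0  # evaluate the estimator at the null
  H <- baseline_cumulative_hazard(f, d5)
  expect_equal(H(1), 1 / 5)
  expect_equal(H(3), 1 / 5 + 1 / 4)
  expect_equal(H(10), 1 / 5 + 1 / 4 + 1 / 2)
  # single event at t with risk-set size r jumps by 1/r
  d1 <- toy_dataset(c(1, 2, 3), c(0, 1, 0), c(1, 0, 1),
                    matrix(0.5, 3, 1))
  f1 <- fit_cox(d1, include_covariates = FALSE)
  f1$coefficients[] <- 0
  H1 <- baseline_cumulative_hazard(f1, d1)
  expect_equal(H1(2), 1 / 2)
  expect_equal(H1(1.99), 0)
  # nondecreasing step function; with general coefficients matches the
  # explicit Breslow sum
  ds <- sim_quick(n = 60, p = 2, seed = 21)
  fg <- fit_cox(ds, mediators = 1)
  Hg <- baseline_cumulative_hazard(fg, ds)
  eta <- drop(cbind(ds$exposure, ds$covariates,
                    ds$mediators[, 1]) %*% fg$coefficients)
  t0 <- sort(unique(ds$time[ds$event == 1]))[3]
  manual <- sum(vapply(sort(unique(ds$time[ds$event == 1]))[1:3],
                       function(tt) sum(ds$event == 1 & ds$time == tt) /
                         sum(exp(eta[ds$time >= tt])), numeric(1)))
  expect_equal(Hg(t0), manual, tolerance = 1e-10)
  grid <- sort(ds$time)
  expect_true(all(diff(Hg(grid)) >= 0))
})
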
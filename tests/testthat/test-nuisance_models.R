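test_that("toy arm Breslow baseline: one censoring event, jump 1/risk-set", {
  # three subjects, censoring event (delta = 0) at time 2, risk set {2, 3}
  smp <- make_arm_sample(U = c(1, 2, 3), delta = c(1, 0, 1))
  cm <- fit_censoring_model(smp, 1)
  expect_equal(cm$baseline$time, 2)
  expect_equal(cm$baseline$haz, 1 / 2)

  # closed-form evaluation: single jump 0.5 at t = 2, exp(X beta) = 1
  expect_equal(censoring_survival(cm, 3, 0), exp(-0.5), tolerance = 1e-12)
  expect_equal(censoring_survival(cm, 2, 0, side = "left"), 1)
  expect_equal(censoring_survival(cm, 0, 0), 1)
})

test_that("no-covariate Cox censoring fit equals Nelson-Aalen", {
  set.seed(31)
  n <- 300
  U <- pmin(rexp(n), rexp(n, 0.8))
  delta <- as.numeric(runif(n) < 0.5)
  smp <- make_arm_sample(U, delta)
  cm <- fit_censoring_model(smp, 1)
  fit <- survival::survfit(survival::Surv(U, 1 - delta) ~ 1,
                           stype = 2, ctype = 1)
  na_jumps <- diff(c(0, fit$cumhaz))[fit$n.event > 0]
  expect_equal(cm$baseline$haz, na_jumps, tolerance = 1e-10)
  expect_equal(cm$baseline$time, fit$time[fit$n.event > 0],
               tolerance = 1e-12)
})

test_that("censoring model recovers the generating coefficients", {
  # censoring hazard exp(0.1 X1 + 0.4 X2 - 0.6 X3), unit baseline
  set.seed(32)
  n <- 5000
  X1 <- rnorm(n); X2 <- rnorm(n); X3 <- rbinom(n, 1, 0.5)
  C <- rexp(n) / exp(0.1 * X1 + 0.4 * X2 - 0.6 * X3)
  T <- rexp(n) / exp(0.2 * X1 - 0.6 * X2 + 0.6 * X3)
  df <- data.frame(S = c(rep(1, n + 1), 0),
                   A = c(rep(1, n), 0, NA),
                   U = c(pmin(T, C), 1, NA),
                   delta = c(as.numeric(T <= C), 1, NA),
                   w_survey = 1,
                   X1 = c(X1, 0, 0), X2 = c(X2, 0, 0), X3 = c(X3, 0, 0))
  smp <- combined_sample(df)
  cm <- fit_censoring_model(smp, 1, c("X1", "X2", "X3"))
  ref <- survival::coxph(survival::Surv(U, 1 - delta) ~ X1 + X2 + X3,
                         data = df[df$S == 1 & df$A == 1, ],
                         ties = "breslow")
  se <- sqrt(diag(vcov(ref)))
  expect_true(all(abs(cm$beta - c(0.1, 0.4, -0.6)) < 3.5 * se))

  # outcome Cox fit recovers its own coefficients too
  om <- fit_outcome_model(smp, 1, c("X1", "X2", "X3"), "cox")
  ref2 <- survival::coxph(survival::Surv(U, delta) ~ X1 + X2 + X3,
                          data = df[df$S == 1 & df$A == 1, ],
                          ties = "breslow")
  se2 <- sqrt(diag(vcov(ref2)))
  expect_true(all(abs(om$beta - c(0.2, -0.6, 0.6)) < 3.5 * se2))
})

test_that("no censoring events degenerate to K identically 1", {
  smp <- make_arm_sample(U = c(1, 2, 3), delta = c(1, 1, 1))
  expect_warning(cm <- fit_censoring_model(smp, 1), "no censoring")
  expect_equal(censoring_survival(cm, 10, 0), 1)
})

test_that("lognormal AFT without covariates matches closed-form MLE", {
  # uncensored log-times (-1, 0, 1): gamma0 = mean = 0, survival at the
  # median H(1) = P(eps >= 0) = 0.5
  smp <- make_arm_sample(U = exp(c(-1, 0, 1)), delta = c(1, 1, 1))
  om <- fit_outcome_model(smp, 1, character(0), "lognormal")
  expect_equal(om$gamma0, 0, tolerance = 1e-6)
  expect_equal(om$scale, sqrt(2 / 3), tolerance = 1e-4)  # MLE, not s/(n-1)
  expect_equal(outcome_survival(om, 1, 0), 0.5, tolerance = 1e-6)
})

test_that("weibull AFT on exponential data estimates unit shape", {
  set.seed(33)
  U <- rexp(4000)
  smp <- make_arm_sample(U, delta = rep(1, length(U)))
  om <- fit_outcome_model(smp, 1, character(0), "weibull")
  expect_equal(om$scale, 1, tolerance = 0.05)
  expect_equal(outcome_survival(om, 1, 0), exp(-exp(-om$gamma0 / om$scale)),
               tolerance = 1e-10)
})

test_that("conditional survival functions satisfy the shape invariants", {
  fx <- make_fitted_toy()
  grid <- seq(0, 2, by = 0.1)
  for (mod in c(fx$cmods, fx$omods)) {
    s <- vapply(grid, function(t) {
      f <- if (inherits(mod, "censoring_model")) censoring_survival else
        outcome_survival
      f(mod, t, c(X1 = 0.5))
    }, numeric(1))
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s > 0 & s <= 1))
  }
  # extrapolation beyond the last jump carries the last baseline forward
  cm <- fx$cmods[[1]]
  tmax <- max(cm$baseline$time)
  expect_equal(censoring_survival(cm, tmax + 5, c(X1 = 0)),
               censoring_survival(cm, tmax, c(X1 = 0)))
})

test_that("AFT survival uses the stated standardized-residual tails", {
  smp <- make_arm_sample(U = c(0.5, 1, 2, 4), delta = c(1, 1, 0, 1),
                         X1 = c(-1, 0, 1, 2))
  for (fam in c("lognormal", "weibull", "loglogistic")) {
    om <- fit_outcome_model(smp, 1, "X1", fam)
    z <- (log(2) - om$gamma0 - 1.5 * om$gamma[["X1"]]) / om$scale
    want <- switch(fam, lognormal = pnorm(-z), weibull = exp(-exp(z)),
                   loglogistic = plogis(-z))
    expect_equal(outcome_survival(om, 2, c(X1 = 1.5)), want,
                 tolerance = 1e-12)
    expect_equal(outcome_survival(om, 0, c(X1 = 1.5)), 1)
  }
})

test_that("baseline_table exports the step baseline", {
  fx <- make_fitted_toy()
  bt <- baseline_table(fx$cmods[[2]])
  expect_equal(bt$cumulative_hazard, cumsum(bt$hazard_increment))
  expect_error(baseline_table(fit_outcome_model(make_arm_sample(
    U = c(1, 2, 3), delta = c(1, 1, 1)), 1, character(0), "lognormal")),
    "baseline")
})
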
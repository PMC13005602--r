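# Hand-computable configurations for the weighting estimators, plus the
# structural invariants (pi-invariance, weight placement, monotonicity).

test_that("IPW1 matches the hand-computed Horvitz-Thompson example", {
  # one trial subject per arm, no censoring (K = 1), omega = 0.5 so
  # tau = 1, pi = 0.5, four survey records of weight 1:
  # S_a(t) = (1 * 1 / 0.5) / 4 = 0.5 in each arm, delta-hat = 0
  df <- data.frame(S = rep(c(1, 0), c(2, 4)),
                   A = c(1, 0, rep(NA, 4)),
                   U = c(2, 2, rep(NA, 4)),
                   delta = c(1, 1, rep(NA, 4)),
                   X1 = rep(0, 6))
  smp <- combined_sample(df, pi = 0.5)
  cmods <- suppressWarnings(list(fit_censoring_model(smp, 0),
                                 fit_censoring_model(smp, 1)))
  est <- estimate_ipw1(smp, rep(0.5, 6), cmods, times = 1)
  expect_equal(est$S1, 0.5)
  expect_equal(est$S0, 0.5)
  expect_equal(est$delta, 0)

  # beyond every trial U all indicators vanish
  est2 <- estimate_ipw1(smp, rep(0.5, 6), cmods, times = 3)
  expect_equal(est2$S1, 0)
  expect_equal(est2$S0, 0)
})

test_that("IPW2 self-normalizes and ignores pi and survey weights", {
  fx <- make_fitted_toy(pi = 0.4)
  est <- estimate_ipw2(fx$smp, fx$omega, fx$cmods, times = c(0.4, 0.7))

  # changing pi leaves IPW2 bit-identical, scales IPW1 trial terms
  smp3 <- make_toy_sample(pi = 0.3)
  est3 <- estimate_ipw2(smp3, fx$omega, fx$cmods, times = c(0.4, 0.7))
  expect_identical(est$S1, est3$S1)
  expect_identical(est$S0, est3$S0)
  ipw1_a <- estimate_ipw1(fx$smp, fx$omega, fx$cmods, times = 0.4)
  ipw1_b <- estimate_ipw1(smp3, fx$omega, fx$cmods, times = 0.4)
  expect_equal(ipw1_b$S1, ipw1_a$S1 * 0.4 / 0.3, tolerance = 1e-12)
  expect_equal(ipw1_b$S0, ipw1_a$S0 * 0.6 / 0.7, tolerance = 1e-12)

  # rescaling survey weights (omega fixed) leaves IPW2 unchanged but
  # halves IPW1 (weight placement rules)
  df <- as.data.frame(fx$smp)
  df$w_survey[df$S == 0] <- df$w_survey[df$S == 0] * 2
  smp2 <- combined_sample(df, pi = 0.4)
  est2 <- estimate_ipw2(smp2, fx$omega, fx$cmods, times = c(0.4, 0.7))
  expect_identical(est$S1, est2$S1)
  ipw1_c <- estimate_ipw1(smp2, fx$omega, fx$cmods, times = 0.4)
  expect_equal(ipw1_c$S1, ipw1_a$S1 / 2, tolerance = 1e-12)
})

test_that("IPW2 with no censoring and constant omega is the empirical
           survival fraction; a single-subject arm estimates 1", {
  df <- data.frame(S = rep(c(1, 0), c(5, 2)),
                   A = c(1, 1, 1, 1, 0, NA, NA),
                   U = c(1, 2, 3, 4, 2, NA, NA),
                   delta = c(1, 1, 1, 1, 1, NA, NA),
                   X1 = rep(0, 7))
  smp <- combined_sample(df)
  cmods <- suppressWarnings(list(fit_censoring_model(smp, 0),
                                 fit_censoring_model(smp, 1)))
  est <- estimate_ipw2(smp, rep(0.3, 7), cmods, times = 2.5)
  expect_equal(est$S1, 0.5)   # 2 of 4 treated subjects have U >= 2.5
  expect_equal(est$S0, 0)     # the single control has U < 2.5
  est2 <- estimate_ipw2(smp, rep(0.3, 7), cmods, times = 1.5)
  expect_equal(est2$S0, 1)    # self-normalization: single subject at risk
})

test_that("OM is the survey-weighted mean of fitted survival", {
  fx <- make_fitted_toy()
  t <- 0.6
  est <- estimate_om(fx$smp, fx$omods, times = c(0, t))
  sv <- as.data.frame(fx$smp)
  sv <- sv[sv$S == 0, ]
  for (a in c(0, 1)) {
    mod <- if (fx$omods[[1]]$arm == a) fx$omods[[1]] else fx$omods[[2]]
    want <- sum(sv$w_survey * vapply(seq_len(nrow(sv)), function(i)
      outcome_survival(mod, t, c(X1 = sv$X1[i])), numeric(1))) /
      sum(sv$w_survey)
    got <- if (a == 1) est$S1[2] else est$S0[2]
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_equal(est$S1[1], 1)  # H(0|.) = 1
  expect_equal(est$S0[1], 1)
})

test_that("martingale augmentation has the stated closed forms", {
  # event subject, no baseline jumps before min(U, t): both terms vanish
  fx <- make_fitted_toy()
  subj <- data.frame(U = 0.5, delta = 1, X1 = 0.2)
  cm1 <- fx$cmods[[2]]
  om1 <- fx$omods[[2]]
  first_jump <- min(cm1$baseline$time)
  expect_gt(first_jump, 0.5)  # fixture has no censoring jump before 0.5
  expect_equal(martingale_augmentation(subj, cm1, om1, 0.5), 0)
  # t = 0 gives an empty integral for everyone
  expect_equal(martingale_augmentation(subj, cm1, om1, 0), 0)

  # censored at U = 1 <= t with K(1-) = 1 (degenerate censoring model)
  # and H(t)/H(1) = 0.5: single-jump hand computation gives 0.5
  arm <- make_arm_sample(U = c(1, 2, 3), delta = c(1, 1, 1))
  cm_deg <- suppressWarnings(fit_censoring_model(arm, 1))
  om_hand <- structure(list(arm = 1, family = "cox", beta = numeric(0),
                            baseline = list(time = c(0.5, 1.5),
                                            haz = c(0.3, log(2))),
                            covariate_names = character(0),
                            model_type = "cox"),
                       class = "outcome_model")
  subj2 <- data.frame(U = 1, delta = 0, X1 = 0)
  expect_equal(martingale_augmentation(subj2, cm_deg, om_hand, 2), 0.5,
               tolerance = 1e-12)
})

test_that("DR2 is pi-invariant; DR1 is not; survey-weight placement", {
  fx <- make_fitted_toy(pi = 0.4)
  times <- c(0.4, 0.7, 1.0)
  d2a <- estimate_dr2(fx$smp, fx$omega, fx$cmods, fx$omods, times)
  smp3 <- make_toy_sample(pi = 0.25)
  d2b <- estimate_dr2(smp3, fx$omega, fx$cmods, fx$omods, times)
  expect_identical(d2a$S1, d2b$S1)
  expect_identical(d2a$S0, d2b$S0)
  d1a <- estimate_dr1(fx$smp, fx$omega, fx$cmods, fx$omods, times)
  d1b <- estimate_dr1(smp3, fx$omega, fx$cmods, fx$omods, times)
  expect_false(isTRUE(all.equal(d1a$S1, d1b$S1)))

  # rescaling survey weights with omega fixed: DR2's weighting part nu1
  # is untouched, its outcome part and DR1 are not
  nuis <- list(omega_hat = fx$omega, censoring_models = fx$cmods,
               outcome_models = fx$omods)
  dec_a <- influence_decomposition(fx$smp, "DR2", nuis, 0.7)
  df <- as.data.frame(fx$smp)
  df$w_survey[df$S == 0] <- df$w_survey[df$S == 0] * 2
  smp2 <- combined_sample(df, pi = 0.4)
  dec_b <- influence_decomposition(smp2, "DR2", nuis, 0.7)
  expect_identical(dec_a$nu1, dec_b$nu1)
  d1c <- estimate_dr1(smp2, fx$omega, fx$cmods, fx$omods, times)
  expect_false(isTRUE(all.equal(d1a$S1, d1c$S1)))
})

test_that("with unit survey weights the DR estimators equal the
           unweighted (1/m) estimating-equation forms", {
  fx <- make_fitted_toy(unit_weights = TRUE)
  t <- 0.7
  orc <- oracle_estimates(fx$smp, fx$omega, fx$cmods, fx$omods, t)
  # oracle divides by sum of weights = m, i.e. the unweighted form
  d1 <- estimate_dr1(fx$smp, fx$omega, fx$cmods, fx$omods, t)
  d2 <- estimate_dr2(fx$smp, fx$omega, fx$cmods, fx$omods, t)
  expect_equal(d1$S1, unname(orc[["1"]]["dr1"]), tolerance = 1e-12)
  expect_equal(d1$S0, unname(orc[["0"]]["dr1"]), tolerance = 1e-12)
  expect_equal(d2$S1, unname(orc[["1"]]["dr2"]), tolerance = 1e-12)
  expect_equal(d2$S0, unname(orc[["0"]]["dr2"]), tolerance = 1e-12)
})

test_that("weighting estimator curves are non-increasing in t", {
  scen <- small_scenario()
  smp <- generate_sample(scen, seed = 5)
  fit <- transport_survival(smp, times = seq(0.05, 1.2, by = 0.05),
                            estimators = c("wkm", "ipw1", "ipw2"))
  for (est in fit) {
    expect_true(all(diff(est$S1) <= 1e-12), info = est$estimator)
    expect_true(all(diff(est$S0) <= 1e-12), info = est$estimator)
  }
})

test_that("WKM with equal weights reproduces the ordinary Kaplan-Meier", {
  set.seed(8)
  n <- 60
  U <- pmax(round(pmin(rexp(n), rexp(n, 0.7)), 2), 0.01)  # some ties
  delta <- as.numeric(runif(n) < 0.6)
  smp <- make_arm_sample(U, delta)
  est <- estimate_wkm(smp, rep(0.5, nrow(smp)), times = c(0.3, 0.8, 1.5))
  km <- survival::survfit(survival::Surv(U, delta) ~ 1)
  for (j in seq_along(est$times)) {
    # I(U >= t) convention: the product-limit value just before t
    want <- c(1, km$surv)[sum(km$time < est$times[j]) + 1]
    expect_equal(est$S1[j], want, tolerance = 1e-12)
  }
})

test_that("taste extracts on-grid values and refuses interpolation", {
  fx <- make_fitted_toy()
  est <- estimate_ipw2(fx$smp, fx$omega, fx$cmods, times = c(0.4, 0.7))
  tt <- taste(est, 0.7)
  expect_equal(tt$delta, est$delta[2])
  expect_equal(tt$ci_lo, est$delta[2] - qnorm(0.975) * est$se[2])
  expect_error(taste(est, 0.55), "grid")
})

test_that("transport_survival wires estimators, truncation and families", {
  scen <- small_scenario()
  smp <- generate_sample(scen, seed = 6)
  fit <- transport_survival(smp, times = 0.331,
                            estimators = c("ipw2", "om", "dr2"),
                            outcome_family = "lognormal",
                            truncate_pct = 10)
  expect_named(fit, c("ipw2", "om", "dr2"))
  expect_s3_class(attr(fit, "sampling_score"), "sampling_score_model")
  expect_equal(attr(fit, "outcome_models")[[1]]$family, "lognormal")
  # truncation floors the smallest 10% of trial scores
  omega <- attr(fit, "omega_hat")[smp$S == 1]
  expect_gte(min(omega), survtransport:::.upper_quantile(
    predict(attr(fit, "sampling_score"), smp)[smp$S == 1], 10))
})
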
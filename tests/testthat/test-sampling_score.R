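# The saturated-model example: a single binary covariate with cell counts
# (S=1,x=1)=2, (S=0,x=1)=2, (S=1,x=0)=1, (S=0,x=0)=3, all weights 1. The
# saturated logistic MLE equals the cell proportions, verified below both
# against the closed form and by brute-force likelihood maximization.
make_saturated_sample <- function() {
  df <- data.frame(
    S = c(1, 1, 1, 0, 0, 0, 0, 0),
    A = c(1, 0, 1, rep(NA, 5)),
    U = c(1, 2, 3, rep(NA, 5)),
    delta = c(1, 1, 1, rep(NA, 5)),
    X1 = c(1, 1, 0, 1, 1, 0, 0, 0)
  )
  combined_sample(df)
}

test_that("saturated logistic fit reproduces cell proportions", {
  smp <- make_saturated_sample()
  fit <- fit_sampling_score(smp, "X1")
  om <- predict(fit, data.frame(X1 = c(1, 0)))
  expect_equal(unname(om), c(0.5, 0.25), tolerance = 1e-7)

  # brute-force oracle: grid-maximize the (unweighted) log-likelihood
  ll <- function(th) {
    p <- plogis(th[1] + th[2] * smp$X1)
    sum(smp$S * log(p) + (1 - smp$S) * log(1 - p))
  }
  grid <- expand.grid(t0 = seq(-3, 3, 0.01), t1 = seq(-3, 3, 0.01))
  best <- grid[which.max(apply(grid, 1, ll)), ]
  expect_equal(unname(fit$theta[1]), best$t0, tolerance = 0.02)
  expect_equal(unname(fit$theta[2]), best$t1, tolerance = 0.03)
})

test_that("intercept-only model gives omega = n/(n+m) everywhere", {
  smp <- make_saturated_sample()
  fit <- fit_sampling_score(smp, character(0))
  om <- predict(fit, smp)
  expect_equal(unname(om), rep(3 / 8, 8), tolerance = 1e-8)
})

test_that("with unit weights the fit equals an unweighted glm", {
  fx <- make_fitted_toy(unit_weights = TRUE)
  fit <- fit_sampling_score(fx$smp, c("X1", "X2"))
  ref <- glm(S ~ X1 + X2, family = binomial(), data = as.data.frame(fx$smp))
  expect_equal(unname(fit$theta), unname(coef(ref)), tolerance = 1e-8)
})

test_that("weighted score equations are satisfied at the estimate", {
  fx <- make_fitted_toy()   # unequal survey weights
  fit <- fit_sampling_score(fx$smp, c("X1", "X2"))
  df <- as.data.frame(fx$smp)
  w <- ifelse(df$S == 1, 1, df$w_survey)
  mu <- predict(fit, df)
  sc <- crossprod(cbind(1, df$X1, df$X2), w * (df$S - mu))
  expect_lt(max(abs(sc)), 1e-6)
  expect_true(all(mu > 0 & mu < 1))
})

test_that("rank-deficient design errors naming the collinear column", {
  smp <- make_toy_sample()
  smp$X3 <- smp$X1 * 2
  smp2 <- combined_sample(as.data.frame(smp), pi = 0.4)
  expect_error(fit_sampling_score(smp2, c("X1", "X3")), "X3")
})

test_that("inverse odds weights follow the odds identity and truncation", {
  # theta chosen so the two trial records get omega exactly 0.2 and 0.4
  df <- data.frame(S = c(1, 1, 0, 0), A = c(1, 0, NA, NA),
                   U = c(1, 1, NA, NA), delta = c(1, 1, NA, NA),
                   X1 = c(0, 1, 0, 1))
  smp <- combined_sample(df)
  mdl <- structure(list(theta = c(qlogis(0.2), qlogis(0.4) - qlogis(0.2)),
                        covariate_names = "X1", converged = TRUE,
                        max_abs_score = 0),
                   class = "sampling_score_model")
  expect_equal(inverse_odds_weights(mdl, smp), c(4, 1.5), tolerance = 1e-10)
  # truncation at the 50% percentile floors both scores at 0.4
  expect_equal(inverse_odds_weights(mdl, smp, truncate_pct = 50),
               c(1.5, 1.5), tolerance = 1e-10)
  expect_error(inverse_odds_weights(mdl, smp, truncate_pct = 60), "50")
  # omega = 0.5 gives tau = 1; omega = 0.25 gives tau = 3
  mdl$theta <- c(qlogis(0.5), qlogis(0.25) - qlogis(0.5))
  expect_equal(inverse_odds_weights(mdl, smp), c(1, 3), tolerance = 1e-10)
})

test_that("SMD is zero for identical distributions and follows the formula", {
  # identical trial and target covariate values, tau = 1
  df <- data.frame(S = c(1, 1, 0, 0), A = c(1, 0, NA, NA),
                   U = c(1, 1, NA, NA), delta = c(1, 1, NA, NA),
                   X1 = c(0.3, -0.3, 0.3, -0.3))
  bt <- smd_table(combined_sample(df))
  expect_equal(bt$smd_unweighted, 0, tolerance = 1e-12)

  # trial mean 1, target mean 0, target SD exactly 2 -> SMD 0.5
  df2 <- data.frame(S = c(1, 1, 0, 0), A = c(1, 0, NA, NA),
                    U = c(1, 1, NA, NA), delta = c(1, 1, NA, NA),
                    X1 = c(1, 1, sqrt(2), -sqrt(2)))
  bt2 <- smd_table(combined_sample(df2))
  expect_equal(bt2$sd_target, 2, tolerance = 1e-12)
  expect_equal(bt2$smd_unweighted, 0.5, tolerance = 1e-12)
})

test_that("saturated sampling score weights balance a binary covariate", {
  smp <- make_saturated_sample()
  fit <- fit_sampling_score(smp, "X1")
  tau <- inverse_odds_weights(fit, smp)
  bt <- smd_table(smp, tau)
  expect_lt(bt$smd_weighted, 1e-7)
  expect_gt(bt$smd_unweighted, 0.1)   # imbalanced before weighting
})

test_that("survey-weighted SD reduces to the ordinary SD for equal weights", {
  fx <- make_fitted_toy(unit_weights = TRUE)
  bt <- smd_table(fx$smp)
  sv <- as.data.frame(fx$smp)
  sv <- sv[sv$S == 0, ]
  expect_equal(bt$sd_target[bt$covariate == "X1"], sd(sv$X1),
               tolerance = 1e-12)
  # also invariant to a common rescaling of all survey weights
  df <- as.data.frame(fx$smp)
  df$w_survey[df$S == 0] <- 3
  bt3 <- smd_table(combined_sample(df, pi = 0.4))
  expect_equal(bt3$sd_target, bt$sd_target, tolerance = 1e-12)
})

test_that("zero-variance covariate yields NA SMD with a warning", {
  df <- data.frame(S = c(1, 1, 0, 0), A = c(1, 0, NA, NA),
                   U = c(1, 1, NA, NA), delta = c(1, 1, NA, NA),
                   X1 = c(0.2, 0.4, 1, 1))
  expect_warning(bt <- smd_table(combined_sample(df)), "variance")
  expect_true(is.na(bt$smd_unweighted))
})
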
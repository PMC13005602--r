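# Shared fixtures built in code (no stored data files).

# Deterministic 10-record fixture: 6 trial records (3 per arm, mixed
# events/censorings) + 4 survey records with unequal design weights.
make_toy_sample <- function(pi = 0.4, unit_weights = FALSE) {
  df <- data.frame(
    S = rep(c(1, 0), c(6, 4)),
    A = c(1, 1, 1, 0, 0, 0, rep(NA, 4)),
    U = c(0.5, 1.2, 0.8, 0.6, 1.5, 0.9, rep(NA, 4)),
    delta = c(1, 0, 1, 0, 1, 1, rep(NA, 4)),
    w_survey = c(rep(1, 6), if (unit_weights) rep(1, 4) else
      c(2.5, 1.5, 4, 3)),
    X1 = c(0.2, -0.5, 1.1, -0.3, 0.7, -1.2, 0.4, -0.8, 1.5, 0.1),
    X2 = c(-0.4, 0.9, 0.3, -1.1, 0.5, 0.2, -0.6, 1.3, -0.2, 0.8)
  )
  combined_sample(df, pi = pi)
}

# Fixture with all nuisances fitted; used by oracle and reduction tests.
make_fitted_toy <- function(pi = 0.4, unit_weights = FALSE,
                            score_covars = c("X1", "X2"),
                            cens_covars = "X1", out_covars = "X1") {
  smp <- make_toy_sample(pi = pi, unit_weights = unit_weights)
  ssm <- fit_sampling_score(smp, score_covars)
  list(
    smp = smp,
    omega = predict(ssm, smp),
    cmods = list(fit_censoring_model(smp, 0, cens_covars),
                 fit_censoring_model(smp, 1, cens_covars)),
    omods = list(fit_outcome_model(smp, 0, out_covars),
                 fit_outcome_model(smp, 1, out_covars))
  )
}

# Desk-scale simulation world: same data-generating process, smaller
# population so that nuisance fits stay quick in unit tests.
small_scenario <- function(sampling = "weak", censoring = "cox",
                           population_size = 2e5) {
  scen <- preset_scenario(sampling, censoring)
  scen$population_size <- population_size
  scen
}

# Arm-only survival data as a combined_sample (adds a token opposite-arm
# record and survey record so the container validates).
make_arm_sample <- function(U, delta, X1 = NULL, arm = 1) {
  n <- length(U)
  if (is.null(X1)) X1 <- rep(0, n)
  df <- data.frame(
    S = c(rep(1, n + 1), 0),
    A = c(rep(arm, n), 1 - arm, NA),
    U = c(U, max(U), NA),
    delta = c(delta, 1, NA),
    w_survey = 1,
    X1 = c(X1, 0, 0)
  )
  combined_sample(df, pi = 0.5)
}
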
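# Approximate influence-function variance estimators for the TASTE.
# Nuisance-estimation uncertainty (sampling score, censoring and outcome
# model parameters) is deliberately ignored: for the IPW estimators this
# is known to be conservative, for the DR estimators it is close to
# nominal. Each variance is computed per analysis time.

# ---- internal variance kernels reusing .components -------------------------

# Per-record influence vectors for arm a, ordered trial-then-survey.
.infl_ipw1 <- function(cmp, a, S_a) {
  arm <- cmp$arms[[as.character(a)]]
  tr <- numeric(cmp$n_trial)
  tr[arm$idx] <- arm$ipw_num / .pi_a(cmp$pi, a)
  c(tr, -cmp$w * S_a)
}

.var_ipw1_cmp <- function(cmp, S1, S0) {
  d <- S1 - S0
  I1 <- .infl_ipw1(cmp, 1, S1)
  I0 <- .infl_ipw1(cmp, 0, S0)
  sum((I1 - I0 - d)^2) / cmp$W^2
}

.infl_ipw2 <- function(cmp, a, S_a) {
  arm <- cmp$arms[[as.character(a)]]
  tr <- numeric(cmp$n_trial)
  tr[arm$idx] <- arm$tau *
    (arm$df$delta * arm$ind / arm$KU_left - S_a) / arm$tau_sum
  c(tr, numeric(cmp$n_survey))
}

.var_ipw2_cmp <- function(cmp, S1, S0) {
  sum(.infl_ipw2(cmp, 1, S1)^2) + sum(.infl_ipw2(cmp, 0, S0)^2)
}

.infl_dr1 <- function(cmp, a, S_a) {
  arm <- cmp$arms[[as.character(a)]]
  tr <- numeric(cmp$n_trial)
  tr[arm$idx] <- arm$tau * (arm$resid + arm$aug) / .pi_a(cmp$pi, a)
  c(tr, cmp$w * (arm$Ht_survey - S_a))
}

.var_dr1_cmp <- function(cmp, S1, S0) {
  d <- S1 - S0
  I1 <- .infl_dr1(cmp, 1, S1)
  I0 <- .infl_dr1(cmp, 0, S0)
  sum((I1 - I0 - d)^2) / cmp$W^2
}

.infl_dr2 <- function(cmp, a, nu) {
  key <- as.character(a)
  arm <- cmp$arms[[key]]
  tr <- numeric(cmp$n_trial)
  tr[arm$idx] <- arm$tau *
    (arm$resid + arm$aug - nu$nu1[[key]]) / arm$tau_sum
  c(tr, cmp$w * (arm$Ht_survey - nu$nu2[[key]]) / cmp$W)
}

.var_dr2_cmp <- function(cmp, nu) {
  sum(.infl_dr2(cmp, 1, nu)^2) + sum(.infl_dr2(cmp, 0, nu)^2)
}

# ---- exported interface ----------------------------------------------------

.get_nuis <- function(nuisances, what) {
  if (is.null(nuisances[[what]])) {
    stop("nuisances$", what, " is required", call. = FALSE)
  }
  nuisances[[what]]
}

.est_at <- function(estimate, t) {
  j <- which(abs(estimate$times - t) < 1e-12)
  if (length(j) != 1L) stop("t not on the estimate's grid", call. = FALSE)
  list(S1 = estimate$S1[j], S0 = estimate$S0[j])
}

#' Approximate variance of the IPW1 TASTE estimator
#'
#' @param sample a `combined_sample`.
#' @param estimate the corresponding `survival_curve_estimate` (supplies
#'   the point estimates entering the centering).
#' @param nuisances list with elements `omega_hat` and `censoring_models`
#'   (and `outcome_models` for the DR variances).
#' @param t analysis time, on the estimate's grid.
#' @return scalar variance estimate.
#' @export
var_ipw1 <- function(sample, estimate, nuisances, t) {
  cmp <- .components(sample, .get_nuis(nuisances, "omega_hat"),
                     .get_nuis(nuisances, "censoring_models"), NULL, t)
  s <- .est_at(estimate, t)
  .var_ipw1_cmp(cmp, s$S1, s$S0)
}

#' Approximate variance of the IPW2 TASTE estimator
#' @inheritParams var_ipw1
#' @export
var_ipw2 <- function(sample, estimate, nuisances, t) {
  cmp <- .components(sample, .get_nuis(nuisances, "omega_hat"),
                     .get_nuis(nuisances, "censoring_models"), NULL, t)
  s <- .est_at(estimate, t)
  .var_ipw2_cmp(cmp, s$S1, s$S0)
}

#' Approximate variance of the DR1 TASTE estimator
#' @inheritParams var_ipw1
#' @export
var_dr1 <- function(sample, estimate, nuisances, t) {
  cmp <- .components(sample, .get_nuis(nuisances, "omega_hat"),
                     .get_nuis(nuisances, "censoring_models"),
                     .get_nuis(nuisances, "outcome_models"), t)
  s <- .est_at(estimate, t)
  .var_dr1_cmp(cmp, s$S1, s$S0)
}

#' Approximate variance of the DR2 TASTE estimator
#' @inheritParams var_ipw1
#' @export
var_dr2 <- function(sample, estimate, nuisances, t) {
  cmp <- .components(sample, .get_nuis(nuisances, "omega_hat"),
                     .get_nuis(nuisances, "censoring_models"),
                     .get_nuis(nuisances, "outcome_models"), t)
  .var_dr2_cmp(cmp, .dr2_parts(cmp))
}

#' Per-record influence decomposition
#'
#' Returns the approximate per-record, per-arm influence contributions
#' underlying the variance formulas, and for DR2 additionally the split
#' of the point estimate into the weighting part `nu1` and the
#' outcome-regression part `nu2` (their sum reproduces the DR2 point
#' estimate exactly).
#'
#' @inheritParams var_ipw1
#' @param estimator one of `"IPW1"`, `"IPW2"`, `"DR1"`, `"DR2"`.
#' @return list with `I1`, `I0` (records ordered trial then survey) and,
#'   for DR2, `nu1`, `nu2` (named by arm).
#' @export
influence_decomposition <- function(sample, estimator, nuisances, t,
                                    estimate = NULL) {
  estimator <- match.arg(estimator, c("IPW1", "IPW2", "DR1", "DR2"))
  need_out <- estimator %in% c("DR1", "DR2")
  cmp <- .components(sample, .get_nuis(nuisances, "omega_hat"),
                     .get_nuis(nuisances, "censoring_models"),
                     if (need_out) .get_nuis(nuisances, "outcome_models"),
                     t)
  if (estimator == "DR2") {
    nu <- .dr2_parts(cmp)
    return(list(I1 = .infl_dr2(cmp, 1, nu), I0 = .infl_dr2(cmp, 0, nu),
                nu1 = nu$nu1, nu2 = nu$nu2))
  }
  if (is.null(estimate)) {
    stop("estimate required for ", estimator, call. = FALSE)
  }
  s <- .est_at(estimate, t)
  fn <- switch(estimator, IPW1 = .infl_ipw1, IPW2 = .infl_ipw2,
               DR1 = .infl_dr1)
  list(I1 = fn(cmp, 1, s$S1), I0 = fn(cmp, 0, s$S0))
}

#' Wald confidence interval
#'
#' @param delta_hat point estimate.
#' @param variance its estimated variance (nonnegative).
#' @param level confidence level, default 0.95.
#' @return numeric vector `c(lo, hi)`.
#' @export
wald_ci <- function(delta_hat, variance, level = 0.95) {
  stopifnot(variance >= 0, level > 0, level < 1)
  z <- .z_quantile(level)
  c(delta_hat - z * sqrt(variance), delta_hat + z * sqrt(variance))
}
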
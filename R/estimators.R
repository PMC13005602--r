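# Point estimators of the target counterfactual survival functions
# S_a(t) = P(T(a) >= t | S = 0) and the TASTE delta(t) = S_1(t) - S_0(t).
#
# All estimators use the survival indicator convention I(U >= t) and the
# survey-weighted forms; with every survey weight equal to 1 they reduce
# exactly to the unweighted versions. IPW denominators evaluate the
# censoring survival at the subject's own time through the left limit
# K(U-|X); the doubly robust residual term evaluates K at the fixed
# analysis time t (right-continuous), matching the distinct arguments in
# the two constructions.

# ---- time-independent cache ------------------------------------------------

# Everything that does not depend on the analysis time: arm memberships,
# inverse-odds weights, each subject's own-time censoring survival, and
# the censoring-martingale compensator matrices used by the augmentation
# integral (built once over the Breslow jump set up to tmax).
.est_cache <- function(sample, omega_hat, censoring_models,
                       outcome_models = NULL, tmax) {
  sp <- .split_sample(sample)
  n_all <- nrow(sp$trial) + nrow(sp$survey)
  if (length(omega_hat) == n_all) {
    omega_trial <- omega_hat[sample$S == 1]
  } else if (length(omega_hat) == nrow(sp$trial)) {
    omega_trial <- omega_hat
  } else {
    stop("omega_hat must align with all records or with trial records",
         call. = FALSE)
  }
  omega_trial <- pmin(.floor_pos(omega_trial), 1 - 1e-12)
  w <- sp$survey$w_survey
  W <- sum(w)
  if (W <= 0) stop("zero survey-weight total", call. = FALSE)
  arms <- lapply(c(0, 1), function(a) {
    idx <- sp$trial$A == a
    if (!any(idx)) stop("no trial records in arm ", a, call. = FALSE)
    df <- sp$trial[idx, , drop = FALSE]
    om <- omega_trial[idx]
    tau <- (1 - om) / om
    cm <- .pick_arm(censoring_models, a)
    arm <- list(idx = idx, df = df, tau = tau, tau_sum = sum(tau),
                KU_left = .floor_pos(.surv_at(cm, df$U, df, side = "left")),
                cm = cm)
    if (!is.null(outcome_models)) {
      omod <- .pick_arm(outcome_models, a)
      arm$omod <- omod
      arm$HU <- .floor_pos(.surv_at(omod, df$U, df, side = "right"))
      arm$aug_ctx <- .aug_context(cm, omod, df, tmax)
    }
    arm
  })
  names(arms) <- c("0", "1")
  list(arms = arms, w = w, W = W, pi = sp$pi, survey = sp$survey,
       n_trial = nrow(sp$trial), n_survey = nrow(sp$survey))
}

# Compensator machinery of the augmentation integral over the censoring
# baseline's jump set restricted to (0, tmax]: M[i, k] holds
# dLambda0C(u_k) exp(X_i'beta) / {H(u_k|X_i) K(u_k-|X_i)} I(U_i >= u_k),
# so that the compensator at time t is H(t|X_i) * rowSums over u_k <= t.
.aug_context <- function(cm, omod, df, tmax) {
  jt <- cm$baseline$time
  keep <- jt <= tmax
  jt <- jt[keep]
  dl <- cm$baseline$haz[keep]
  n <- nrow(df)
  if (length(jt) == 0L) {
    return(list(jt = numeric(0), M = matrix(0, n, 0)))
  }
  expC <- exp(.lp_cox(cm, df))
  Hu <- .floor_pos(.surv_matrix(omod, jt, df, side = "right"))
  L0C_left <- .step_cumhaz(cm$baseline, jt, side = "left")
  Ku_left <- .floor_pos(exp(-outer(expC, L0C_left)))
  M <- (1 / (Hu * Ku_left)) * expC
  M <- M * rep(dl, each = n)
  M[outer(df$U, jt, "<")] <- 0
  list(jt = jt, M = M)
}

# Augmentation integral at analysis time t for every subject of an arm,
# given the cached compensator matrix and the subject's H(t|X) values.
.aug_eval <- function(arm, t, Ht) {
  df <- arm$df
  jump <- ifelse(df$delta == 0 & df$U <= t,
                 Ht / (arm$HU * arm$KU_left), 0)
  ctx <- arm$aug_ctx
  k <- sum(ctx$jt <= t)
  if (k == 0L) return(jump)
  comp <- Ht * rowSums(ctx$M[, seq_len(k), drop = FALSE])
  jump - comp
}

# ---- shared per-time components --------------------------------------------

# Everything the estimators and variance formulas need at one analysis
# time t. `cache` (from .est_cache) lets callers amortize the
# time-independent pieces over a time grid.
.components <- function(sample, omega_hat, censoring_models,
                        outcome_models = NULL, t, cache = NULL) {
  if (is.null(cache)) {
    cache <- .est_cache(sample, omega_hat, censoring_models,
                        outcome_models, tmax = t)
  }
  arms <- lapply(cache$arms, function(arm) {
    df <- arm$df
    ind <- as.numeric(df$U >= t)
    arm$ind <- ind
    arm$ipw_num <- arm$tau * df$delta * ind / arm$KU_left
    if (!is.null(arm$omod)) {
      nt <- rep(t, nrow(df))
      Kt <- .surv_at(arm$cm, nt, df, side = "right")
      Ht <- .surv_at(arm$omod, nt, df, side = "right")
      arm$Kt <- Kt
      arm$Ht <- Ht
      arm$resid <- (ind - Kt * Ht) / .floor_pos(Kt)
      arm$aug <- .aug_eval(arm, t, Ht)
      arm$Ht_survey <- .surv_at(arm$omod, rep(t, cache$n_survey),
                                cache$survey, side = "right")
    }
    arm
  })
  list(arms = arms, w = cache$w, W = cache$W, pi = cache$pi, t = t,
       n_trial = cache$n_trial, n_survey = cache$n_survey)
}

.pi_a <- function(pi, a) if (a == 1) pi else 1 - pi

#' Martingale augmentation term for a single trial subject
#'
#' The censoring-martingale integral that augments the doubly robust
#' estimators: the counting-process jump contribution (present when the
#' subject is censored at or before `t`, weighted by the inverse
#' censoring survival at the left limit) minus the model compensator
#' accumulated over the Breslow jump times of the censoring baseline up
#' to `min(U, t)`.
#'
#' @param subject one-row data frame (or list) with the subject's `U`,
#'   `delta` and covariate columns.
#' @param cens fitted `censoring_model` for the subject's arm.
#' @param out fitted `outcome_model` for the subject's arm.
#' @param t analysis time.
#' @return scalar augmentation value.
#' @export
martingale_augmentation <- function(subject, cens, out, t) {
  df <- as.data.frame(subject)
  stopifnot(nrow(df) == 1L, t >= 0)
  arm <- list(df = df,
              KU_left = .floor_pos(.surv_at(cens, df$U, df, side = "left")),
              HU = .floor_pos(.surv_at(out, df$U, df, side = "right")),
              omod = out, cm = cens,
              aug_ctx = .aug_context(cens, out, df, t))
  Ht <- .surv_at(out, t, df, side = "right")
  drop(.aug_eval(arm, t, Ht))
}

# ---- estimator assembly ----------------------------------------------------

.new_estimate <- function(tag, times, S1, S0, var, conf_level, nuisance,
                          flags = NULL) {
  delta <- S1 - S0
  se <- sqrt(pmax(var, 0))
  z <- .z_quantile(conf_level)
  structure(list(estimator = tag, times = times, S1 = S1, S0 = S0,
                 delta = delta, se = se,
                 ci_lo = delta - z * se, ci_hi = delta + z * se,
                 conf_level = conf_level, nuisance = nuisance,
                 out_of_range = flags),
            class = "survival_curve_estimate")
}

#' @export
print.survival_curve_estimate <- function(x, ...) {
  cat(sprintf("%s estimate of target counterfactual survival\n", x$estimator))
  print(data.frame(time = x$times, S1 = x$S1, S0 = x$S0, delta = x$delta,
                   se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi))
  if (!is.null(x$out_of_range) && any(x$out_of_range)) {
    cat("note: estimate outside [0, 1] at",
        sum(x$out_of_range), "time(s) (not clipped)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.survival_curve_estimate <- function(x, ...) {
  data.frame(estimator = x$estimator, time = x$times, S1 = x$S1, S0 = x$S0,
             delta = x$delta, se = x$se, ci_lo = x$ci_lo, ci_hi = x$ci_hi)
}

#' Horvitz-Thompson style IPW estimator (IPW1)
#'
#' Combines inverse odds of sampling weights with inverse probability of
#' censoring weights, normalized by the survey-weight total:
#' S_a(t) = sum over trial arm a of
#' tau_i Delta_i I(U_i >= t) / (pi_a K_a(U_i- | X_i)), divided by
#' sum over survey records of w_i. The weights are not self-normalized,
#' so the estimate at t = 0 is not forced to 1.
#'
#' @param sample a `combined_sample`.
#' @param omega_hat fitted sampling scores, aligned with all records of
#'   `sample` (or with its trial records).
#' @param censoring_models list of two per-arm `censoring_model` objects.
#' @param times analysis time grid within the trial follow-up range.
#' @param conf_level confidence level for Wald intervals.
#' @return a `survival_curve_estimate`.
#' @export
estimate_ipw1 <- function(sample, omega_hat, censoring_models, times,
                          conf_level = 0.95) {
  cache <- .est_cache(sample, omega_hat, censoring_models, NULL, max(times))
  res <- vapply(times, function(t) {
    cmp <- .components(sample, omega_hat, censoring_models, NULL, t, cache)
    S1 <- sum(cmp$arms[["1"]]$ipw_num) / (.pi_a(cmp$pi, 1) * cmp$W)
    S0 <- sum(cmp$arms[["0"]]$ipw_num) / (.pi_a(cmp$pi, 0) * cmp$W)
    c(S1, S0, .var_ipw1_cmp(cmp, S1, S0))
  }, numeric(3))
  .new_estimate("IPW1", times, res[1, ], res[2, ], res[3, ], conf_level,
                list(censoring = censoring_models))
}

#' Hajek style self-normalized IPW estimator (IPW2)
#'
#' Per-arm self-normalized version of [estimate_ipw1()]: the same weighted
#' numerator divided by the arm's inverse-odds weight total
#' sum tau_i. The randomization probability cancels, and survey weights
#' enter only through the sampling-score fit, so the output is invariant
#' to `pi` and to rescaling of `w_survey` given `omega_hat`.
#'
#' @inheritParams estimate_ipw1
#' @export
estimate_ipw2 <- function(sample, omega_hat, censoring_models, times,
                          conf_level = 0.95) {
  cache <- .est_cache(sample, omega_hat, censoring_models, NULL, max(times))
  res <- vapply(times, function(t) {
    cmp <- .components(sample, omega_hat, censoring_models, NULL, t, cache)
    S1 <- sum(cmp$arms[["1"]]$ipw_num) / cmp$arms[["1"]]$tau_sum
    S0 <- sum(cmp$arms[["0"]]$ipw_num) / cmp$arms[["0"]]$tau_sum
    c(S1, S0, .var_ipw2_cmp(cmp, S1, S0))
  }, numeric(3))
  .new_estimate("IPW2", times, res[1, ], res[2, ], res[3, ], conf_level,
                list(censoring = censoring_models))
}

#' Outcome-regression (g-computation) estimator
#'
#' Survey-weighted average of the fitted conditional survival over the
#' target-population records:
#' S_a(t) = sum w_i H_a(t|X_i) / sum w_i over survey rows. No variance
#' formula is attached (`se = NA`); it exists mainly as the plug-in
#' component of the doubly robust estimators.
#'
#' @inheritParams estimate_ipw1
#' @param outcome_models list of two per-arm `outcome_model` objects.
#' @export
estimate_om <- function(sample, outcome_models, times, conf_level = 0.95) {
  sp <- .split_sample(sample)
  w <- sp$survey$w_survey
  W <- sum(w)
  om <- function(a, t) {
    mod <- .pick_arm(outcome_models, a)
    sum(w * .surv_at(mod, rep(t, nrow(sp$survey)), sp$survey)) / W
  }
  S1 <- vapply(times, function(t) om(1, t), numeric(1))
  S0 <- vapply(times, function(t) om(0, t), numeric(1))
  .new_estimate("OM", times, S1, S0, rep(NA_real_, length(times)),
                conf_level, list(outcome = outcome_models))
}

#' Augmented IPW doubly robust estimator (DR1)
#'
#' Adds to the outcome-regression term a weighted residual correction and
#' a censoring-martingale augmentation, all normalized by the
#' survey-weight total. Consistent when either the sampling-score and
#' censoring models or the failure-time outcome model are correctly
#' specified. Estimates may leave \\[0, 1\\] and are reported unclipped
#' with a flag.
#'
#' @inheritParams estimate_om
#' @inheritParams estimate_ipw1
#' @export
estimate_dr1 <- function(sample, omega_hat, censoring_models, outcome_models,
                         times, conf_level = 0.95) {
  cache <- .est_cache(sample, omega_hat, censoring_models, outcome_models,
                      max(times))
  res <- vapply(times, function(t) {
    cmp <- .components(sample, omega_hat, censoring_models, outcome_models,
                       t, cache)
    est <- function(a) {
      arm <- cmp$arms[[as.character(a)]]
      trial_part <- sum(arm$tau * (arm$resid + arm$aug)) / .pi_a(cmp$pi, a)
      (trial_part + sum(cmp$w * arm$Ht_survey)) / cmp$W
    }
    S1 <- est(1); S0 <- est(0)
    c(S1, S0, .var_dr1_cmp(cmp, S1, S0))
  }, numeric(3))
  out <- .new_estimate("DR1", times, res[1, ], res[2, ], res[3, ], conf_level,
                       list(censoring = censoring_models,
                            outcome = outcome_models))
  out$out_of_range <- out$S1 < 0 | out$S1 > 1 | out$S0 < 0 | out$S0 > 1
  out
}

#' Self-normalized doubly robust estimator (DR2)
#'
#' Normalizes the weighting part of [estimate_dr1()] by the arm's
#' inverse-odds weight total (the randomization probability cancels) and
#' adds the survey-weighted outcome-regression term. The two parts
#' nu1_a(t) (weighting) and nu2_a(t) (outcome regression) satisfy
#' nu1 + nu2 = S_a(t) exactly and drive the variance decomposition.
#'
#' @inheritParams estimate_dr1
#' @export
estimate_dr2 <- function(sample, omega_hat, censoring_models, outcome_models,
                         times, conf_level = 0.95) {
  cache <- .est_cache(sample, omega_hat, censoring_models, outcome_models,
                      max(times))
  res <- vapply(times, function(t) {
    cmp <- .components(sample, omega_hat, censoring_models, outcome_models,
                       t, cache)
    nu <- .dr2_parts(cmp)
    S1 <- nu$nu1[["1"]] + nu$nu2[["1"]]
    S0 <- nu$nu1[["0"]] + nu$nu2[["0"]]
    c(S1, S0, .var_dr2_cmp(cmp, nu))
  }, numeric(3))
  out <- .new_estimate("DR2", times, res[1, ], res[2, ], res[3, ], conf_level,
                       list(censoring = censoring_models,
                            outcome = outcome_models))
  out$out_of_range <- out$S1 < 0 | out$S1 > 1 | out$S0 < 0 | out$S0 > 1
  out
}

# DR2 split into weighting part nu1 and outcome-regression part nu2.
.dr2_parts <- function(cmp) {
  nu1 <- vapply(c("0", "1"), function(a) {
    arm <- cmp$arms[[a]]
    sum(arm$tau * (arm$resid + arm$aug)) / arm$tau_sum
  }, numeric(1))
  nu2 <- vapply(c("0", "1"), function(a) {
    sum(cmp$w * cmp$arms[[a]]$Ht_survey) / cmp$W
  }, numeric(1))
  list(nu1 = nu1, nu2 = nu2)
}

#' Inverse-odds weighted Kaplan-Meier estimator (WKM)
#'
#' Reference estimator: the per-arm product-limit estimator over trial arm
#' a with subject weights tau_i = (1 - omega_i)/omega_i. It assumes random
#' censoring (no inverse probability of censoring adjustment), so it is
#' biased when censoring depends on covariates. Variance comes from a
#' weighted influence-function sandwich treating the weights as known.
#'
#' @inheritParams estimate_ipw1
#' @export
estimate_wkm <- function(sample, omega_hat, times, conf_level = 0.95) {
  sp <- .split_sample(sample)
  n_all <- nrow(sp$trial) + nrow(sp$survey)
  omega_trial <- if (length(omega_hat) == n_all) {
    omega_hat[sample$S == 1]
  } else omega_hat
  omega_trial <- pmin(.floor_pos(omega_trial), 1 - 1e-12)
  tau <- (1 - omega_trial) / omega_trial
  one_arm <- function(a) {
    idx <- sp$trial$A == a
    if (!any(idx)) stop("no trial records in arm ", a, call. = FALSE)
    .wkm_curve(sp$trial$U[idx], sp$trial$delta[idx], tau[idx], times)
  }
  k1 <- one_arm(1); k0 <- one_arm(0)
  .new_estimate("WKM", times, k1$S, k0$S, k1$var + k0$var, conf_level,
                list())
}

# Weighted product-limit curve evaluated with the I(U >= t) convention
# (product over event times strictly before t), plus an influence-function
# variance with weights treated as fixed:
#   var{S(t)} = S(t)^2 sum_i tau_i^2 { int_0^t- (dN_i - Y_i dLam)/Ybar }^2.
.wkm_curve <- function(U, delta, tau, times) {
  et <- sort(unique(U[delta == 1]))
  K <- length(et)
  if (K == 0L) {
    return(list(S = rep(1, length(times)), var = rep(0, length(times))))
  }
  o <- order(U)
  Us <- U[o]
  cum_tau <- cumsum(tau[o])
  total <- cum_tau[length(cum_tau)]
  below <- findInterval(et, Us, left.open = TRUE)   # count of U < et_k
  Ybar <- total - ifelse(below == 0L, 0, cum_tau[pmax(below, 1L)])
  ev <- delta == 1
  grp <- match(U, et)                                # NA for non-event times
  dN <- numeric(K)
  agg <- rowsum(tau[ev], grp[ev])
  dN[as.integer(rownames(agg))] <- agg[, 1]
  dLam <- dN / Ybar
  logS_steps <- cumsum(log1p(-pmin(dLam, 1 - 1e-12)))
  G <- cumsum(dLam / Ybar)   # compensator integral per subject risk span
  # subject pieces: own-event jump 1/Ybar at k(i), compensator G up to
  # min(U_i, t-) over the event-time grid
  k_own <- ifelse(ev, grp, NA_integer_)
  k_risk <- findInterval(U, et)                      # count of et_k <= U_i
  S <- numeric(length(times))
  v <- numeric(length(times))
  for (j in seq_along(times)) {
    k <- sum(et < times[j])
    S[j] <- if (k == 0L) 1 else exp(logS_steps[k])
    if (k == 0L) {
      v[j] <- 0
      next
    }
    jump <- numeric(length(U))
    sel <- !is.na(k_own) & k_own <= k
    jump[sel] <- 1 / Ybar[k_own[sel]]
    kk <- pmin(k_risk, k)
    comp <- numeric(length(U))
    comp[kk > 0L] <- G[kk[kk > 0L]]
    ci <- jump - comp
    v[j] <- S[j]^2 * sum(tau^2 * ci^2)
  }
  list(S = S, var = v)
}

#' Extract the TASTE at one analysis time
#'
#' @param est a `survival_curve_estimate`.
#' @param t a time on the estimate's grid (step estimates are not
#'   interpolated; an off-grid time is an error).
#' @return list with `delta`, `se`, `ci_lo`, `ci_hi` at `t`.
#' @export
taste <- function(est, t) {
  j <- which(abs(est$times - t) < 1e-12)
  if (length(j) != 1L) {
    stop("t = ", t, " is not on the estimate's time grid; ",
         "interpolation is refused", call. = FALSE)
  }
  list(delta = est$delta[j], se = est$se[j],
       ci_lo = est$ci_lo[j], ci_hi = est$ci_hi[j])
}
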
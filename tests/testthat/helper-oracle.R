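# Independent brute-force oracle: naive record-by-record, jump-by-jump
# transcriptions of the estimating equations and variance formulas. Kept
# deliberately loop-based and separate from the vectorized production
# code path; conditional survival values are recomputed here from the raw
# baseline jumps and coefficients.

oracle_flo <- function(v) max(v, 1e-8)

oracle_surv <- function(model, t, row, left = FALSE) {
  if (model$model_type == "cox") {
    L <- 0
    for (k in seq_along(model$baseline$time)) {
      jt <- model$baseline$time[k]
      if ((left && jt < t) || (!left && jt <= t)) L <- L + model$baseline$haz[k]
    }
    lp <- 0
    for (nm in model$covariate_names) lp <- lp + row[[nm]] * model$beta[[nm]]
    exp(-L * exp(lp))
  } else {
    if (t <= 0) return(1)
    lp <- model$gamma0
    for (nm in model$covariate_names) lp <- lp + row[[nm]] * model$gamma[[nm]]
    z <- (log(t) - lp) / model$scale
    switch(model$family,
           lognormal = stats::pnorm(-z),
           weibull = exp(-exp(z)),
           loglogistic = stats::plogis(-z))
  }
}

oracle_arm <- function(models, a) {
  if (models[[1]]$arm == a) models[[1]] else models[[2]]
}

oracle_aug <- function(row, cm, om, t) {
  Ht <- oracle_surv(om, t, row)
  jump <- 0
  if (row$delta == 0 && row$U <= t) {
    jump <- Ht / (oracle_flo(oracle_surv(om, row$U, row)) *
                    oracle_flo(oracle_surv(cm, row$U, row, left = TRUE)))
  }
  lp <- 0
  for (nm in cm$covariate_names) lp <- lp + row[[nm]] * cm$beta[[nm]]
  comp <- 0
  for (k in seq_along(cm$baseline$time)) {
    u <- cm$baseline$time[k]
    if (u <= min(row$U, t)) {
      comp <- comp + cm$baseline$haz[k] * exp(lp) * Ht /
        (oracle_flo(oracle_surv(om, u, row)) *
           oracle_flo(oracle_surv(cm, u, row, left = TRUE)))
    }
  }
  jump - comp
}

# All five point estimators at one time, by direct transcription of the
# survey-weighted estimating equations (with p_i = 1 they coincide with
# the unweighted forms).
oracle_estimates <- function(smp, omega, cmods, omods, t) {
  df <- as.data.frame(smp)
  pi <- attr(smp, "pi")
  W <- sum(df$w_survey[df$S == 0])
  m <- sum(df$S == 0)
  out <- list()
  for (a in 0:1) {
    cm <- oracle_arm(cmods, a)
    om <- oracle_arm(omods, a)
    pia <- if (a == 1) pi else 1 - pi
    ipw_num <- 0
    tau_sum <- 0
    dr_trial <- 0
    om_sum <- 0
    for (i in seq_len(nrow(df))) {
      row <- df[i, , drop = FALSE]
      if (row$S == 1 && row$A == a) {
        o <- omega[i]
        tau <- (1 - o) / o
        KUm <- oracle_flo(oracle_surv(cm, row$U, row, left = TRUE))
        ipw_num <- ipw_num + tau * row$delta * (row$U >= t) / KUm
        tau_sum <- tau_sum + tau
        Kt <- oracle_surv(cm, t, row)
        Ht <- oracle_surv(om, t, row)
        dr_trial <- dr_trial +
          tau * (((row$U >= t) - Kt * Ht) / oracle_flo(Kt) +
                   oracle_aug(row, cm, om, t))
      } else if (row$S == 0) {
        om_sum <- om_sum + row$w_survey * oracle_surv(om, t, row)
      }
    }
    out[[as.character(a)]] <- c(
      ipw1 = unname(ipw_num / (pia * W)),
      ipw2 = unname(ipw_num / tau_sum),
      om = unname(om_sum / W),
      dr1 = unname((dr_trial / pia + om_sum) / W),
      dr2 = unname(dr_trial / tau_sum + om_sum / W),
      nu1 = unname(dr_trial / tau_sum),
      nu2 = unname(om_sum / W)
    )
  }
  out
}

# Variance formulas by direct transcription.
oracle_variances <- function(smp, omega, cmods, omods, t, est) {
  df <- as.data.frame(smp)
  pi <- attr(smp, "pi")
  N <- nrow(df)
  W <- sum(df$w_survey[df$S == 0])
  infl <- function(a, type) {
    cm <- oracle_arm(cmods, a)
    om <- oracle_arm(omods, a)
    pia <- if (a == 1) pi else 1 - pi
    key <- as.character(a)
    tau_sum <- 0
    for (i in seq_len(N)) {
      if (df$S[i] == 1 && df$A[i] == a) {
        tau_sum <- tau_sum + (1 - omega[i]) / omega[i]
      }
    }
    vals <- numeric(N)
    for (i in seq_len(N)) {
      row <- df[i, , drop = FALSE]
      if (row$S == 1 && row$A == a) {
        o <- omega[i]
        tau <- (1 - o) / o
        KUm <- oracle_flo(oracle_surv(cm, row$U, row, left = TRUE))
        if (type == "ipw1") {
          vals[i] <- tau * row$delta * (row$U >= t) / (pia * KUm)
        } else if (type == "ipw2") {
          vals[i] <- tau * (row$delta * (row$U >= t) / KUm -
                              est$S[[key]]["ipw2"]) / tau_sum
        } else {
          Kt <- oracle_surv(cm, t, row)
          Ht <- oracle_surv(om, t, row)
          core <- ((row$U >= t) - Kt * Ht) / oracle_flo(Kt) +
            oracle_aug(row, cm, om, t)
          if (type == "dr1") {
            vals[i] <- tau * core / pia
          } else {
            vals[i] <- tau * (core - est$S[[key]]["nu1"]) / tau_sum
          }
        }
      } else if (row$S == 0) {
        Ht <- oracle_surv(om, t, row)
        vals[i] <- switch(type,
          ipw1 = -row$w_survey * est$S[[key]]["ipw1"],
          ipw2 = 0,
          dr1 = row$w_survey * (Ht - est$S[[key]]["dr1"]),
          dr2 = row$w_survey * (Ht - est$S[[key]]["nu2"]) / W)
      }
    }
    vals
  }
  s <- est$S
  out <- c(
    ipw1 = sum((infl(1, "ipw1") - infl(0, "ipw1") -
                  (s[["1"]]["ipw1"] - s[["0"]]["ipw1"]))^2) / W^2,
    ipw2 = sum(infl(1, "ipw2")^2) + sum(infl(0, "ipw2")^2),
    dr1 = sum((infl(1, "dr1") - infl(0, "dr1") -
                 (s[["1"]]["dr1"] - s[["0"]]["dr1"]))^2) / W^2,
    dr2 = sum(infl(1, "dr2")^2) + sum(infl(0, "dr2")^2)
  )
  out
}

# Convenience wrapper: point estimates packaged for oracle_variances.
oracle_all <- function(smp, omega, cmods, omods, t) {
  S <- oracle_estimates(smp, omega, cmods, omods, t)
  est <- list(S = S)
  list(S = S,
       delta = S[["1"]] - S[["0"]],
       var = oracle_variances(smp, omega, cmods, omods, t, est))
}
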
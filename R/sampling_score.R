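#' Fit the survey-weighted logistic sampling-score model
#'
#' Models the probability of trial participation, omega(X) = P(S = 1 | X),
#' by logistic regression of the trial indicator on covariates over the
#' combined sample, maximizing the weighted (pseudo) log-likelihood with
#' case weight 1 for trial rows and the survey design weight `1/p_i` for
#' survey rows. The survey-weighted fit makes the nonrandomized records
#' represent the full target population rather than the survey subsample.
#'
#' The solver is iteratively reweighted least squares with case weights
#' (the standard pseudo-likelihood); convergence is declared when the
#' largest absolute component of the weighted score vector is below
#' `tol`.
#'
#' @param sample a `combined_sample`.
#' @param covariates character vector of covariate columns entering the
#'   linear predictor; an empty vector fits the intercept-only model.
#' @param tol score-equation convergence tolerance.
#' @return object of class `sampling_score_model` with elements `theta`
#'   (intercept first), `covariate_names`, `converged`, `max_abs_score`.
#' @export
fit_sampling_score <- function(sample, covariates, tol = 1e-8) {
  sp <- .split_sample(sample)
  df <- as.data.frame(sample)
  X <- .design_matrix(df, covariates)
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xd))]]
    stop("sampling-score design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  w <- ifelse(df$S == 1, 1, df$w_survey)
  fit <- suppressWarnings(
    stats::glm.fit(Xd, df$S, weights = w, family = stats::quasibinomial())
  )
  theta <- fit$coefficients
  mu <- fit$fitted.values
  score <- drop(crossprod(Xd, w * (df$S - mu)))
  max_abs_score <- max(abs(score))
  if (!fit$converged || !all(is.finite(theta))) {
    stop("sampling-score fit did not converge (max |score| = ",
         format(max_abs_score), "); possible separation", call. = FALSE)
  }
  if (max_abs_score > tol * max(1, sum(w))) {
    warning("weighted score equations not solved to tolerance (max |score| = ",
            format(max_abs_score), ")")
  }
  structure(list(theta = theta, covariate_names = covariates,
                 converged = fit$converged, max_abs_score = max_abs_score),
            class = "sampling_score_model")
}

#' Predict sampling scores
#'
#' @param object a `sampling_score_model`.
#' @param newdata data frame (or `combined_sample`) holding the model's
#'   covariate columns.
#' @param ... unused.
#' @return vector of fitted omega-hat in (0, 1), one per row of `newdata`.
#' @export
predict.sampling_score_model <- function(object, newdata, ...) {
  X <- .design_matrix(as.data.frame(newdata), object$covariate_names)
  lp <- drop(cbind(1, X) %*% object$theta)
  pmin(pmax(stats::plogis(lp), 1e-12), 1 - 1e-12)
}

#' @export
print.sampling_score_model <- function(x, ...) {
  cat("Survey-weighted logistic sampling-score model\n")
  print(x$theta)
  cat(sprintf("  converged: %s (max |score| = %.2e)\n",
              x$converged, x$max_abs_score))
  invisible(x)
}

#' Inverse odds of sampling weights for trial records
#'
#' Forms tau_i = (1 - omega_hat_i) / omega_hat_i for each trial record,
#' the weight that reweights the trial arm toward the covariate
#' distribution of the nonparticipant target population. An optional
#' percentile truncation floors the sampling score (not the weight): trial
#' omega-hat values below the `truncate_pct` percentile of the trial
#' omega-hat distribution are raised to that percentile before forming
#' odds, limiting the influence of extreme weights.
#'
#' @param model fitted `sampling_score_model`.
#' @param sample a `combined_sample`.
#' @param truncate_pct percentile in \\[0, 50] or `NULL` (no truncation;
#'   the default, as appropriate for well-overlapping samples).
#' @return numeric vector of weights, one per trial (`S = 1`) record, in
#'   the row order of the sample's trial records.
#' @export
inverse_odds_weights <- function(model, sample, truncate_pct = NULL) {
  sp <- .split_sample(sample)
  omega <- unname(predict(model, sp$trial))
  if (!is.null(truncate_pct)) {
    if (truncate_pct < 0 || truncate_pct > 50) {
      stop("truncate_pct must lie in [0, 50]", call. = FALSE)
    }
    omega <- pmax(omega, .upper_quantile(omega, truncate_pct))
  }
  if (any(omega < .SURV_FLOOR)) {
    warning("sampling score at numerical floor for ",
            sum(omega < .SURV_FLOOR), " record(s); weights floored")
    omega <- .floor_pos(omega)
  }
  (1 - omega) / omega
}

#' Covariate balance table (standardized mean differences)
#'
#' For each covariate, the absolute difference between the (tau-weighted)
#' trial mean and the survey-weighted target-population mean, divided by
#' the survey-weighted standard deviation of the covariate in the target
#' population. With all trial weights equal to one the unweighted SMD
#' quantifies the pre-existing trial/target imbalance; with inverse odds
#' of sampling weights it diagnoses the fitted sampling-score model
#' (conventional adequacy thresholds 0.1 and 0.2).
#'
#' @param sample a `combined_sample`.
#' @param tau trial weight vector aligned with the `S = 1` records, or
#'   `NULL` for unweighted trial means in the `smd_weighted` column too.
#' @param covariates covariate columns to tabulate (default: all).
#' @return data frame of class `balance_table` with columns `covariate`,
#'   `smd_unweighted`, `smd_weighted`, `sd_target`, `balanced_0.1`,
#'   `balanced_0.2`.
#' @export
smd_table <- function(sample, tau = NULL, covariates = NULL) {
  sp <- .split_sample(sample)
  if (is.null(covariates)) covariates <- sp$covs
  if (is.null(tau)) tau <- rep(1, nrow(sp$trial))
  if (length(tau) != nrow(sp$trial)) {
    stop("tau must have one entry per trial record", call. = FALSE)
  }
  w <- sp$survey$w_survey
  sw <- sum(w)
  one_smd <- function(xk_t, xk_s, wt) {
    xbar <- sum(w * xk_s) / sw
    denom <- sw - sum(w^2) / sw
    s2 <- sum(w * (xk_s - xbar)^2) / denom
    if (s2 <= 0) return(c(NA_real_, NA_real_))
    trial_mean <- sum(wt * xk_t) / sum(wt)
    c(abs(trial_mean - xbar) / sqrt(s2), sqrt(s2))
  }
  res <- t(vapply(covariates, function(k) {
    u <- one_smd(sp$trial[[k]], sp$survey[[k]], rep(1, nrow(sp$trial)))
    v <- one_smd(sp$trial[[k]], sp$survey[[k]], tau)
    c(u[1], v[1], v[2])
  }, numeric(3)))
  if (anyNA(res)) {
    warning("zero target-population variance for covariate(s): ",
            paste(covariates[is.na(res[, 3])], collapse = ", "))
  }
  out <- data.frame(covariate = covariates,
                    smd_unweighted = res[, 1],
                    smd_weighted = res[, 2],
                    sd_target = res[, 3],
                    balanced_0.1 = res[, 2] < 0.1,
                    balanced_0.2 = res[, 2] < 0.2,
                    row.names = NULL)
  class(out) <- c("balance_table", "data.frame")
  out
}
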
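# Per-arm censoring and failure-time models fitted on trial data, exposing
# conditional survival functions K_a(t|X) (censoring) and H_a(t|X)
# (failure). Cox fits use the Breslow tie convention in both the partial
# likelihood and the baseline, so that a fit with no covariates reduces
# exactly to the Nelson-Aalen estimator.

.fit_cox <- function(df, covariates, event) {
  if (length(covariates) == 0L) {
    beta <- numeric(0)
    lp <- rep(0, nrow(df))
  } else {
    f <- stats::as.formula(paste("survival::Surv(U, ev) ~",
                                 paste(covariates, collapse = " + ")))
    dat <- df[covariates]
    dat$U <- df$U
    dat$ev <- event
    fit <- tryCatch(
      suppressWarnings(survival::coxph(f, data = dat, ties = "breslow")),
      error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                               call. = FALSE))
    beta <- stats::coef(fit)
    if (anyNA(beta)) {
      stop("Cox fit produced undetermined coefficient(s): ",
           paste(names(beta)[is.na(beta)], collapse = ", "), call. = FALSE)
    }
    lp <- drop(.design_matrix(df, covariates) %*% beta)
  }
  baseline <- .breslow_baseline(df$U, event, lp)
  list(beta = beta, baseline = baseline)
}

#' Fit the per-arm Cox censoring model
#'
#' Treats censoring (`delta = 0`) as the event and failures as censored
#' within trial arm `a`, maximizing the Cox partial likelihood, and
#' computes the Breslow baseline cumulative hazard at the estimate. The
#' fitted object exposes K_a(t|X) = exp(-Lambda0C(t) exp(X'beta)), the
#' conditional survival function of the potential censoring time used to
#' build inverse probability of censoring weights.
#'
#' With no censoring events the model degenerates to K identically 1
#' (logged warning); with an empty covariate list the baseline is the
#' Nelson-Aalen estimator of the censoring hazard.
#'
#' @param sample a `combined_sample`.
#' @param arm treatment arm, 0 or 1.
#' @param covariates covariate columns for the linear predictor.
#' @return object of class `censoring_model`.
#' @export
fit_censoring_model <- function(sample, arm, covariates = character(0)) {
  sp <- .split_sample(sample)
  df <- sp$trial[sp$trial$A == arm, , drop = FALSE]
  if (nrow(df) == 0L) stop("no trial records in arm ", arm, call. = FALSE)
  event <- 1 - df$delta
  if (!any(event == 1)) {
    warning("no censoring events in arm ", arm,
            "; censoring survival is identically 1")
    fit <- list(beta = rep(0, length(covariates)),
                baseline = list(time = numeric(0), haz = numeric(0)))
    names(fit$beta) <- covariates
  } else {
    fit <- .fit_cox(df, covariates, event)
  }
  structure(list(arm = arm, beta = fit$beta, baseline = fit$baseline,
                 covariate_names = covariates, model_type = "cox"),
            class = "censoring_model")
}

#' Fit the per-arm failure-time outcome model
#'
#' Models the conditional survival function H_a(t|X) = P(T(a) >= t | X)
#' from trial arm `a`. `family = "cox"` fits a Cox model by partial
#' likelihood with a Breslow baseline on the failure hazard; the AFT
#' families (`lognormal`, `weibull`, `loglogistic`) fit
#' log T = gamma0 + X'gamma1 + sigma * eps by maximum likelihood with
#' right censoring, and evaluate survival through the tail probability of
#' the standardized residual (normal, extreme value, logistic
#' respectively).
#'
#' @param sample a `combined_sample`.
#' @param arm treatment arm, 0 or 1.
#' @param covariates covariate columns.
#' @param family one of `"cox"`, `"lognormal"`, `"weibull"`,
#'   `"loglogistic"`.
#' @return object of class `outcome_model`.
#' @export
fit_outcome_model <- function(sample, arm, covariates = character(0),
                              family = c("cox", "lognormal", "weibull",
                                         "loglogistic")) {
  family <- match.arg(family)
  sp <- .split_sample(sample)
  df <- sp$trial[sp$trial$A == arm, , drop = FALSE]
  if (nrow(df) == 0L) stop("no trial records in arm ", arm, call. = FALSE)
  if (!any(df$delta == 1)) stop("no events in arm ", arm, call. = FALSE)
  if (family == "cox") {
    fit <- .fit_cox(df, covariates, df$delta)
    out <- list(arm = arm, family = family, beta = fit$beta,
                baseline = fit$baseline, covariate_names = covariates,
                model_type = "cox")
  } else {
    rhs <- if (length(covariates) == 0L) "1" else
      paste(covariates, collapse = " + ")
    f <- stats::as.formula(paste("survival::Surv(U, delta) ~", rhs))
    dat <- df[c("U", "delta", covariates)]
    sr <- tryCatch(
      suppressWarnings(survival::survreg(f, data = dat, dist = family)),
      error = function(e) stop("AFT fit failed: ", conditionMessage(e),
                               call. = FALSE))
    cf <- stats::coef(sr)
    if (anyNA(cf) || !is.finite(sr$scale) || sr$scale <= 0) {
      stop("AFT fit produced invalid parameters", call. = FALSE)
    }
    out <- list(arm = arm, family = family,
                gamma0 = unname(cf[1]),
                gamma = if (length(covariates)) cf[-1] else numeric(0),
                scale = sr$scale, covariate_names = covariates,
                model_type = "aft")
  }
  structure(out, class = "outcome_model")
}

# ---- conditional survival evaluation ---------------------------------------

.lp_cox <- function(model, data) {
  if (length(model$covariate_names) == 0L) return(rep(0, nrow(data)))
  drop(.design_matrix(data, model$covariate_names) %*% model$beta)
}

# Survival of each row of `data` at its own time `times[i]`.
.surv_at <- function(model, times, data, side = "right") {
  if (model$model_type == "cox") {
    L0 <- .step_cumhaz(model$baseline, times, side)
    exp(-L0 * exp(.lp_cox(model, data)))
  } else {
    .aft_surv(model, times, .aft_lp(model, data))
  }
}

# Matrix of survival values: rows of `data` x shared evaluation `times`.
.surv_matrix <- function(model, times, data, side = "right") {
  if (length(times) == 0L) {
    return(matrix(0, nrow = nrow(data), ncol = 0L))
  }
  if (model$model_type == "cox") {
    L0 <- .step_cumhaz(model$baseline, times, side)
    exp(-outer(exp(.lp_cox(model, data)), L0))
  } else {
    lp <- .aft_lp(model, data)
    z <- outer(-lp, log(pmax(times, .Machine$double.xmin)), "+") / model$scale
    s <- .aft_tail(model$family, z)
    s[, times == 0] <- 1
    s
  }
}

.aft_lp <- function(model, data) {
  lp <- rep(model$gamma0, nrow(data))
  if (length(model$covariate_names) > 0L) {
    lp <- lp + drop(.design_matrix(data, model$covariate_names) %*% model$gamma)
  }
  lp
}

.aft_tail <- function(family, z) {
  switch(family,
         lognormal = stats::pnorm(-z),
         weibull = exp(-exp(z)),
         loglogistic = stats::plogis(-z),
         stop("unknown AFT family"))
}

.aft_surv <- function(model, times, lp) {
  out <- numeric(length(times))
  pos <- times > 0
  out[!pos] <- 1
  if (any(pos)) {
    z <- (log(times[pos]) - lp[pos]) / model$scale
    out[pos] <- .aft_tail(model$family, z)
  }
  out
}

#' Conditional censoring survival K_a(t | X)
#'
#' Evaluates the fitted censoring survival function. `side = "left"` gives
#' the left-continuous version K(t-), the value used when a subject's own
#' observed time enters an inverse probability of censoring weight.
#' Beyond the largest baseline jump the last baseline value is carried
#' forward.
#'
#' @param model a `censoring_model`.
#' @param t evaluation time(s), nonnegative.
#' @param X covariate vector, or a matrix/data frame of covariate rows (in
#'   which case `t` must have length 1 or `nrow(X)`).
#' @param side `"right"` (cadlag value) or `"left"` (left limit).
#' @return survival probabilities in (0, 1].
#' @export
censoring_survival <- function(model, t, X, side = c("right", "left")) {
  side <- match.arg(side)
  .cond_surv(model, t, X, side)
}

#' Conditional failure-time survival H_a(t | X)
#'
#' Evaluates the fitted outcome model's conditional survival function; see
#' [censoring_survival()] for the evaluation conventions.
#'
#' @inheritParams censoring_survival
#' @param model an `outcome_model`.
#' @export
outcome_survival <- function(model, t, X, side = c("right", "left")) {
  side <- match.arg(side)
  .cond_surv(model, t, X, side)
}

.cond_surv <- function(model, t, X, side) {
  if (is.null(dim(X))) {
    X <- matrix(X, nrow = 1,
                dimnames = list(NULL, model$covariate_names))
  }
  data <- as.data.frame(X)
  if (length(t) == 1L && nrow(data) > 1L) t <- rep(t, nrow(data))
  if (nrow(data) == 1L && length(t) > 1L) {
    data <- data[rep(1L, length(t)), , drop = FALSE]
  }
  stopifnot(all(t >= 0))
  .surv_at(model, t, data, side)
}

#' Export a fitted step baseline as a jump-time/increment table
#'
#' @param model a `censoring_model` or Cox-family `outcome_model`.
#' @return data frame with columns `time`, `hazard_increment`,
#'   `cumulative_hazard`.
#' @export
baseline_table <- function(model) {
  if (model$model_type != "cox") {
    stop("parametric AFT models have no step baseline", call. = FALSE)
  }
  data.frame(time = model$baseline$time,
             hazard_increment = model$baseline$haz,
             cumulative_hazard = cumsum(model$baseline$haz))
}

#' @export
print.censoring_model <- function(x, ...) {
  cat(sprintf("Cox censoring model, arm %d (%d baseline jumps)\n",
              x$arm, length(x$baseline$time)))
  if (length(x$beta)) print(x$beta) else cat("  (no covariates)\n")
  invisible(x)
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Outcome model (%s), arm %d\n", x$family, x$arm))
  if (x$model_type == "cox") {
    if (length(x$beta)) print(x$beta) else cat("  (no covariates)\n")
  } else {
    cat(sprintf("  gamma0 = %.4f, scale = %.4f\n", x$gamma0, x$scale))
    if (length(x$gamma)) print(x$gamma)
  }
  invisible(x)
}

# Pick the model for arm `a` out of a (possibly unnamed) list of two
# per-arm models, or accept a single model directly.
.pick_arm <- function(models, a) {
  if (inherits(models, "censoring_model") || inherits(models, "outcome_model")) {
    if (models$arm != a) stop("model is for arm ", models$arm, call. = FALSE)
    return(models)
  }
  for (mod in models) if (!is.null(mod$arm) && mod$arm == a) return(mod)
  stop("no model supplied for arm ", a, call. = FALSE)
}
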
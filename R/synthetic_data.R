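# Simulator for the benchmark data-generating process: a population of
# n + N individuals with three baseline covariates, logistic selection
# into a randomized trial, logistic survey inclusion among nonparticipants
# with known design weights, Bernoulli(pi) randomization, per-arm Cox
# potential failure times with unit exponential baseline, and either
# covariate-dependent (Cox) or Uniform random censoring.

#' Define a simulation scenario
#'
#' @param theta length-4 logistic coefficients (intercept first) of trial
#'   selection P(S = 1 | X).
#' @param xi length-4 logistic coefficients of survey inclusion
#'   P(D = 1 | X, S = 0).
#' @param loghaz1,loghaz0 length-3 log-hazard coefficients on
#'   (X1, X2, X3) of the potential failure times under treatment and
#'   control, with unit exponential baseline hazard.
#' @param censoring list: either `list(type = "cox", coef = ...)` (unit
#'   exponential baseline) or `list(type = "uniform", upper = ...)`.
#' @param population_size total number of individuals n + N.
#' @param pi randomization probability.
#' @return object of class `scenario`.
#' @export
scenario <- function(theta, xi, loghaz1, loghaz0, censoring,
                     population_size = 1e6, pi = 0.5) {
  stopifnot(length(theta) == 4L, length(xi) == 4L,
            length(loghaz1) == 3L, length(loghaz0) == 3L,
            population_size >= 1, pi > 0, pi < 1)
  if (!censoring$type %in% c("cox", "uniform")) {
    stop("censoring$type must be 'cox' or 'uniform'", call. = FALSE)
  }
  if (censoring$type == "uniform" && censoring$upper <= 0) {
    stop("uniform censoring bound must be positive", call. = FALSE)
  }
  structure(list(theta = theta, xi = xi, loghaz1 = loghaz1,
                 loghaz0 = loghaz0, censoring = censoring,
                 population_size = population_size, pi = pi),
            class = "scenario")
}

#' Named benchmark scenarios
#'
#' The four stated simulation worlds: weak selection
#' (theta = (-6.5, -0.2, -0.1, -0.5)) or strong selection
#' (theta = (-6.7, -0.8, -0.4, -1)) into the trial, crossed with
#' covariate-dependent Cox censoring (log-hazard coefficients
#' (0.1, 0.4, -0.6), unit exponential baseline) or random
#' Uniform(0, 2.1) censoring. Survey inclusion uses
#' xi = (-7, 0.3, 0.4, 0.2); the population size is 1e6 and pi = 0.5,
#' yielding trial and survey sizes of roughly 1200 and 1100 with an
#' overall trial censoring rate near 45%.
#'
#' @param sampling `"weak"` or `"strong"` trial selection.
#' @param censoring `"cox"` (covariate-dependent) or `"uniform"` (random).
#' @return a `scenario`.
#' @export
preset_scenario <- function(sampling = c("weak", "strong"),
                            censoring = c("cox", "uniform")) {
  sampling <- match.arg(sampling)
  censoring <- match.arg(censoring)
  theta <- if (sampling == "weak") c(-6.5, -0.2, -0.1, -0.5) else
    c(-6.7, -0.8, -0.4, -1)
  cens <- if (censoring == "cox") {
    list(type = "cox", coef = c(0.1, 0.4, -0.6))
  } else {
    list(type = "uniform", upper = 2.1)
  }
  scenario(theta = theta, xi = c(-7, 0.3, 0.4, 0.2),
           loghaz1 = c(0.2, -0.6, 0.6), loghaz0 = c(0.2, 0.6, -0.6),
           censoring = cens, population_size = 1e6, pi = 0.5)
}

#' Generate a combined trial + survey sample from a scenario
#'
#' Draws X1, X2 ~ N(0, 1) and X3 ~ Bernoulli(0.5) for the whole
#' population, selects trial participants by the logistic sampling model,
#' selects survey records among nonparticipants by the logistic inclusion
#' model (attaching the true inverse inclusion probability as the design
#' weight), randomizes treatment, and inverts the unit-exponential-
#' baseline Cox hazards for potential failure and censoring times. Only
#' trial records and included survey records are returned.
#'
#' One master seed spawns separate sub-seeds for the population draw,
#' selection, treatment, failure and censoring stages, so that scenarios
#' sharing a seed share their population.
#'
#' @param scen a `scenario`.
#' @param seed integer master seed.
#' @return a `combined_sample`.
#' @export
generate_sample <- function(scen, seed) {
  stopifnot(inherits(scen, "scenario"))
  ss <- .spawn_seeds(seed, 5L)
  Np <- as.integer(scen$population_size)

  set.seed(ss[1])
  X1 <- stats::rnorm(Np)
  X2 <- stats::rnorm(Np)
  X3 <- as.numeric(stats::runif(Np) < 0.5)

  set.seed(ss[2])
  p_s <- stats::plogis(scen$theta[1] + scen$theta[2] * X1 +
                         scen$theta[3] * X2 + scen$theta[4] * X3)
  S <- stats::runif(Np) < p_s
  p_d <- stats::plogis(scen$xi[1] + scen$xi[2] * X1 +
                         scen$xi[3] * X2 + scen$xi[4] * X3)
  D <- !S & (stats::runif(Np) < p_d)

  trial_idx <- which(S)
  survey_idx <- which(D)
  n <- length(trial_idx)
  m <- length(survey_idx)
  if (n == 0L || m == 0L) stop("degenerate draw: empty trial or survey")

  x1t <- X1[trial_idx]; x2t <- X2[trial_idx]; x3t <- X3[trial_idx]

  set.seed(ss[3])
  A <- as.numeric(stats::runif(n) < scen$pi)

  set.seed(ss[4])
  lam1 <- exp(scen$loghaz1[1] * x1t + scen$loghaz1[2] * x2t +
                scen$loghaz1[3] * x3t)
  lam0 <- exp(scen$loghaz0[1] * x1t + scen$loghaz0[2] * x2t +
                scen$loghaz0[3] * x3t)
  Tt <- stats::rexp(n) / ifelse(A == 1, lam1, lam0)

  set.seed(ss[5])
  if (scen$censoring$type == "cox") {
    lamC <- exp(scen$censoring$coef[1] * x1t + scen$censoring$coef[2] * x2t +
                  scen$censoring$coef[3] * x3t)
    C <- stats::rexp(n) / lamC
  } else {
    C <- stats::runif(n, 0, scen$censoring$upper)
  }

  df <- data.frame(
    id = c(trial_idx, survey_idx),
    S = rep(c(1, 0), c(n, m)),
    D = 1,
    A = c(A, rep(NA_real_, m)),
    U = c(pmin(Tt, C), rep(NA_real_, m)),
    delta = c(as.numeric(Tt <= C), rep(NA_real_, m)),
    w_survey = c(rep(1, n), 1 / p_d[survey_idx]),
    X1 = c(x1t, X1[survey_idx]),
    X2 = c(x2t, X2[survey_idx]),
    X3 = c(x3t, X3[survey_idx])
  )
  combined_sample(df, pi = scen$pi, covariates = c("X1", "X2", "X3"))
}

#' Oracle true counterfactual survival and TASTE
#'
#' Monte Carlo integration of the closed-form conditional survival
#' S_a(t | X) = exp(-t exp(coef_a' X)) over the covariate law, with each
#' draw importance-weighted by P(S = 0 | X) to condition on
#' nonparticipation (exact, and far more efficient than rejection when
#' P(S = 1) is of order 1e-3).
#'
#' @param scen a `scenario`.
#' @param times evaluation times.
#' @param mc_draws number of Monte Carlo draws (1e5+ recommended).
#' @param seed integer seed.
#' @return object of class `true_taste` with `times`, `S1`, `S0`,
#'   `delta`, `mc_draws` and the per-time Monte Carlo standard error
#'   `mc_se` of `delta`.
#' @export
true_taste <- function(scen, times, mc_draws = 1e6, seed = 1) {
  stopifnot(inherits(scen, "scenario"), mc_draws >= 1)
  set.seed(seed)
  X1 <- stats::rnorm(mc_draws)
  X2 <- stats::rnorm(mc_draws)
  X3 <- as.numeric(stats::runif(mc_draws) < 0.5)
  w <- 1 - stats::plogis(scen$theta[1] + scen$theta[2] * X1 +
                           scen$theta[3] * X2 + scen$theta[4] * X3)
  sw <- sum(w)
  lam1 <- exp(scen$loghaz1[1] * X1 + scen$loghaz1[2] * X2 +
                scen$loghaz1[3] * X3)
  lam0 <- exp(scen$loghaz0[1] * X1 + scen$loghaz0[2] * X2 +
                scen$loghaz0[3] * X3)
  S1 <- S0 <- delta <- mc_se <- numeric(length(times))
  for (j in seq_along(times)) {
    s1x <- exp(-times[j] * lam1)
    s0x <- exp(-times[j] * lam0)
    S1[j] <- sum(w * s1x) / sw
    S0[j] <- sum(w * s0x) / sw
    dx <- s1x - s0x
    dbar <- sum(w * dx) / sw
    delta[j] <- dbar
    mc_se[j] <- sqrt(sum(w^2 * (dx - dbar)^2)) / sw
  }
  structure(list(times = times, S1 = S1, S0 = S0, delta = delta,
                 mc_draws = mc_draws, mc_se = mc_se),
            class = "true_taste")
}

#' @export
print.true_taste <- function(x, ...) {
  cat(sprintf("True target counterfactual survival (%g MC draws)\n",
              x$mc_draws))
  print(data.frame(time = x$times, S1 = x$S1, S0 = x$S0, delta = x$delta,
                   mc_se = x$mc_se))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Simulation scenario\n")
  cat("  theta:", paste(x$theta, collapse = ", "), "\n")
  cat("  xi:   ", paste(x$xi, collapse = ", "), "\n")
  cat("  loghaz1:", paste(x$loghaz1, collapse = ", "),
      " loghaz0:", paste(x$loghaz0, collapse = ", "), "\n")
  cat("  censoring:", x$censoring$type, "\n")
  cat(sprintf("  population %g, pi = %.2f\n", x$population_size, x$pi))
  invisible(x)
}
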
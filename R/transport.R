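#' One-call transportability analysis
#'
#' Fits the survey-weighted sampling-score model, the per-arm Cox
#' censoring models and (when needed) the per-arm outcome models, then
#' computes the requested transportability estimators of the target
#' counterfactual survival functions and the TASTE on a common time grid.
#'
#' @param sample a `combined_sample`.
#' @param times analysis time grid (within the observed trial follow-up).
#' @param estimators subset of `c("wkm", "ipw1", "ipw2", "om", "dr1",
#'   "dr2")`.
#' @param score_covars covariates of the sampling-score model.
#' @param cens_covars covariates of the censoring models.
#' @param outcome_covars covariates of the outcome models.
#' @param outcome_family outcome model family, see [fit_outcome_model()].
#' @param truncate_pct optional sampling-score truncation percentile
#'   passed to [inverse_odds_weights()] semantics (scores below the
#'   percentile are floored before forming odds).
#' @param conf_level Wald confidence level.
#' @return named list of `survival_curve_estimate` objects (class
#'   `transport_result`), with the fitted nuisances attached as
#'   attributes.
#' @examples
#' scen <- preset_scenario("weak", "cox")
#' scen$population_size <- 2e5  # desk-scale example
#' smp <- generate_sample(scen, seed = 7)
#' fit <- transport_survival(smp, times = c(0.331, 0.712),
#'                           estimators = c("ipw2", "dr2"))
#' fit$dr2
#' @export
transport_survival <- function(sample, times,
                               estimators = c("ipw1", "ipw2", "dr1", "dr2"),
                               score_covars = attr(sample, "covariates"),
                               cens_covars = attr(sample, "covariates"),
                               outcome_covars = attr(sample, "covariates"),
                               outcome_family = "cox",
                               truncate_pct = NULL,
                               conf_level = 0.95) {
  known <- c("wkm", "ipw1", "ipw2", "om", "dr1", "dr2")
  estimators <- match.arg(as.character(estimators), known, several.ok = TRUE)
  ssm <- fit_sampling_score(sample, score_covars)
  omega <- predict(ssm, sample)
  if (!is.null(truncate_pct)) {
    om_trial <- omega[sample$S == 1]
    omega[sample$S == 1] <- pmax(om_trial, .upper_quantile(om_trial,
                                                           truncate_pct))
  }
  need_cens <- any(estimators %in% c("ipw1", "ipw2", "dr1", "dr2"))
  need_out <- any(estimators %in% c("om", "dr1", "dr2"))
  cmods <- if (need_cens) {
    list(fit_censoring_model(sample, 0, cens_covars),
         fit_censoring_model(sample, 1, cens_covars))
  }
  omods <- if (need_out) {
    list(fit_outcome_model(sample, 0, outcome_covars, outcome_family),
         fit_outcome_model(sample, 1, outcome_covars, outcome_family))
  }
  out <- lapply(estimators, function(est) {
    switch(est,
           wkm = estimate_wkm(sample, omega, times, conf_level),
           ipw1 = estimate_ipw1(sample, omega, cmods, times, conf_level),
           ipw2 = estimate_ipw2(sample, omega, cmods, times, conf_level),
           om = estimate_om(sample, omods, times, conf_level),
           dr1 = estimate_dr1(sample, omega, cmods, omods, times,
                              conf_level),
           dr2 = estimate_dr2(sample, omega, cmods, omods, times,
                              conf_level))
  })
  names(out) <- estimators
  structure(out, class = "transport_result", sampling_score = ssm,
            omega_hat = omega, censoring_models = cmods,
            outcome_models = omods)
}

#' @export
print.transport_result <- function(x, ...) {
  for (est in x) print(est)
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `balance`, `estimate`, `simulate`, `truth`,
#' `mc-benchmark`. Run with no arguments for usage. Installed as the
#' executable script `cli/survtransport` under the package directory.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the calling command line).
#' @return exit status, invisibly.
#' @export
survtransport_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: survtransport <command> [options]",
    "commands:",
    "  balance      --input F --covariates X1,X2 [--truncate-pct P] --out F",
    "  estimate     --input F --estimator dr2 --times 0.1,0.2",
    "               [--score-covars ...] [--cens-covars ...]",
    "               [--outcome-covars ...] [--outcome-family cox]",
    "               [--pi 0.5] [--truncate-pct P] --out F",
    "  simulate     --scenario weak-cox --seed 7 --out F",
    "  truth        --scenario weak-cox --times 0.128,0.331,0.712",
    "               [--draws 1000000] [--seed 1]",
    "  mc-benchmark --scenario weak-cox --reps 500 --estimators dr2",
    "               [--grid all|correct] [--times ...] --seed 11 --out F",
    sep = "\n")
  if (length(args) == 0L) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- .parse_cli_opts(args[-1])
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  get_scen <- function() {
    parts <- split_csv(gsub("-", ",", opt[["scenario"]]))
    preset_scenario(parts[1], parts[2])
  }
  if (cmd == "balance") {
    smp <- read_sample(opt[["input"]])
    covs <- split_csv(opt[["covariates"]])
    ssm <- fit_sampling_score(smp, covs)
    tau <- inverse_odds_weights(ssm, smp,
                                truncate_pct = .opt_num(opt, "truncate-pct"))
    bt <- smd_table(smp, tau, covs)
    utils::write.table(bt, opt[["out"]], sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else if (cmd == "estimate") {
    smp <- read_sample(opt[["input"]],
                       pi = .opt_num(opt, "pi", 0.5))
    res <- transport_survival(
      smp, times = as.numeric(split_csv(opt[["times"]])),
      estimators = tolower(opt[["estimator"]]),
      score_covars = .opt_csv(opt, "score-covars", attr(smp, "covariates")),
      cens_covars = .opt_csv(opt, "cens-covars", attr(smp, "covariates")),
      outcome_covars = .opt_csv(opt, "outcome-covars",
                                attr(smp, "covariates")),
      outcome_family = if (is.null(opt[["outcome-family"]])) "cox" else
        opt[["outcome-family"]],
      truncate_pct = .opt_num(opt, "truncate-pct"))
    utils::write.table(as.data.frame(res[[1]]), opt[["out"]], sep = ",",
                       row.names = FALSE, quote = FALSE)
  } else if (cmd == "simulate") {
    smp <- generate_sample(get_scen(), as.integer(opt[["seed"]]))
    write_sample(smp, opt[["out"]])
  } else if (cmd == "truth") {
    tt <- true_taste(get_scen(),
                     times = as.numeric(split_csv(opt[["times"]])),
                     mc_draws = .opt_num(opt, "draws", 1e6),
                     seed = as.integer(.opt_num(opt, "seed", 1)))
    print(tt)
  } else if (cmd == "mc-benchmark") {
    grid <- spec_grid(if (is.null(opt[["grid"]])) "correct" else
      opt[["grid"]])
    summ <- run_mc(get_scen(), grid = grid,
                   estimators = split_csv(opt[["estimators"]]),
                   times = .opt_csv_num(opt, "times",
                                        c(0.128, 0.331, 0.712)),
                   n_reps = .opt_num(opt, "reps", 500),
                   master_seed = as.integer(.opt_num(opt, "seed", 1)))
    write_summary(summ, opt[["out"]])
  } else {
    cat(usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}

.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}

.opt_num <- function(opt, key, default = NULL) {
  if (is.null(opt[[key]])) default else as.numeric(opt[[key]])
}

.opt_csv <- function(opt, key, default) {
  if (is.null(opt[[key]])) default else
    strsplit(opt[[key]], ",", fixed = TRUE)[[1]]
}

.opt_csv_num <- function(opt, key, default) {
  if (is.null(opt[[key]])) default else
    as.numeric(strsplit(opt[[key]], ",", fixed = TRUE)[[1]])
}
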
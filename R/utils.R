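# Internal numerical helpers shared across modules.

# Floor applied to estimated survival probabilities and sampling scores
# wherever they enter a denominator.
.SURV_FLOOR <- 1e-8

.floor_pos <- function(x, floor = .SURV_FLOOR) pmax(x, floor)

# Evaluate a pure-jump cumulative hazard (Breslow-type baseline) at `t`.
# side = "right": sum of increments with jump time <= t (cadlag value).
# side = "left":  sum of increments with jump time <  t (left limit).
# `baseline` is a list(time = sorted jump times, haz = increments).
.step_cumhaz <- function(baseline, t, side = c("right", "left")) {
  side <- match.arg(side)
  jt <- baseline$time
  if (length(jt) == 0L) return(rep(0, length(t)))
  ch <- cumsum(baseline$haz)
  idx <- findInterval(t, jt, left.open = (side == "left"))
  out <- numeric(length(t))
  out[idx > 0L] <- ch[idx[idx > 0L]]
  out
}

# Breslow estimator of the baseline cumulative hazard increments given
# observed times, event indicators and linear predictors (uncentered).
# Ties are pooled at common event times (Breslow convention).
.breslow_baseline <- function(time, event, lp) {
  risk <- exp(lp)
  if (!any(event == 1)) return(list(time = numeric(0), haz = numeric(0)))
  ut <- sort(unique(time[event == 1]))
  o <- order(time)
  ts <- time[o]
  rs <- risk[o]
  # total risk-set score for each risk set {j : time_j >= ut_k}
  rev_cum <- rev(cumsum(rev(rs)))
  first_ge <- findInterval(ut, ts, left.open = TRUE) + 1L
  denom <- rev_cum[first_ge]
  d <- vapply(ut, function(u) sum(event == 1 & time == u), numeric(1))
  list(time = ut, haz = d / denom)
}

# Design matrix for a model's covariate set; errors on absent columns.
.design_matrix <- function(data, covariate_names) {
  if (length(covariate_names) == 0L) {
    return(matrix(0, nrow = nrow(data), ncol = 0L))
  }
  missing_cols <- setdiff(covariate_names, names(data))
  if (length(missing_cols) > 0L) {
    stop("covariate column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  as.matrix(data[covariate_names])
}

.z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

# Upper empirical quantile: smallest order statistic x_(k) with
# F(x_(k)) > p, i.e. k = floor(n p) + 1 (capped at n). Used for
# sampling-score truncation so that a 50% truncation of two values floors
# both at the larger one.
.upper_quantile <- function(x, pct) {
  xs <- sort(x)
  n <- length(xs)
  xs[min(n, floor(n * pct / 100) + 1L)]
}

# Derive bounded integer sub-seeds from one master seed without disturbing
# the caller's RNG stream more than once.
.spawn_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
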
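---
title: "Transporting trial survival effects to a survey-represented target population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transporting trial survival effects to a survey-represented target population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survtransport)
```

## The problem

A randomized trial identifies its own sample average treatment effect, but
when the distribution of effect modifiers differs between trial
participants and an external target population, that effect need not equal
the effect in the population one actually cares about. `survtransport`
estimates the *target average survival treatment effect* (TASTE)

$$\delta(t) = \mathcal S_1(t) - \mathcal S_0(t), \qquad
\mathcal S_a(t) = P\{T(a) \ge t \mid S = 0\},$$

the difference of counterfactual survival functions among
*nonparticipants* (`S = 0`), from two data sources: a randomized trial
with a right-censored time-to-event outcome (indicator `S = 1`, treatment
`A`, observed time `U = min(T, C)`, event indicator `delta`), and a
complex survey of the target population contributing covariates `X` and
design weights `w = 1/p` (inverse inclusion probabilities). The trial and
target population are disjoint (a non-nested design), so trial subjects
are reweighted by the *inverse odds of sampling*
$\tau(X) = \{1-\omega(X)\}/\omega(X)$, where
$\omega(X) = P(S = 1 \mid X)$ is the sampling score.

### Identification assumptions

1. **Randomization**: treatment is independent of the potential outcomes
   in the trial, with known assignment probability $\pi$.
2. **Strongly ignorable participation**: $S$ is independent of the
   potential failure and censoring times given `X`, with
   $0 < \omega(X) < 1$.
3. **Covariate-dependent censoring**: censoring is independent of the
   failure time given `X` and arm (it may depend on covariates).
4. **Known survey design**: the survey weights are given (or estimated
   upstream) rather than modelled here.

None of these is testable from the data alone; the balance diagnostics in
`smd_table()` check only the *fitted* sampling-score model, not the
exchangeability assumption itself.

## Estimators

Three working models are fitted:

* the **sampling score** $\omega(X)$: logistic regression of `S` on
  covariates over the combined sample, *survey-weighted* (case weight `w`
  for survey rows, 1 for trial rows) so that the survey sample stands in
  for the full population;
* the **censoring model** $K_a(t \mid X)$: per-arm Cox model treating
  censoring as the event, with Breslow baseline;
* the **outcome model** $H_a(t \mid X)$: per-arm Cox model on the failure
  hazard, or a parametric accelerated failure time model (lognormal,
  Weibull, log-logistic).

From these the package computes:

| tag | form | needs | survey weights used |
|-----|------|-------|---------------------|
| `ipw1` | Horvitz–Thompson: weighted events over $\pi_a\,\omega$-odds and censoring weights, normalized by $\sum_{S=0} w$ | $\omega$, $K_a$ | score fit + final normalization |
| `ipw2` | Hajek: same numerator, self-normalized by $\sum \tau_i$ per arm | $\omega$, $K_a$ | score fit only |
| `om`  | survey-weighted mean of $\hat H_a(t\mid X)$ over survey rows | $H_a$ | outcome term |
| `dr1` | augmented IPW: residual + censoring-martingale augmentation + outcome term, normalized by $\sum_{S=0} w$ | all three | score fit, normalization, outcome term |
| `dr2` | self-normalized DR: weighting part over $\sum \tau_i$, plus the outcome term | all three | score fit + outcome term |
| `wkm` | product-limit estimator with weights $\tau_i$, no censoring adjustment | $\omega$ | score fit only |

The DR estimators are doubly robust: consistent if either the
(sampling + censoring) pair or the outcome model is correct. `ipw2` and
`dr2` do not depend on $\pi$ at all (it cancels in the self-normalization),
which the test suite verifies bit-for-bit.

### Variance

The reported standard errors are *approximate influence-function*
variances that deliberately ignore the uncertainty of all three fitted
nuisance models. For the IPW estimators this is known to be conservative
(empirical coverage well above 95% in the replication harness); for the
DR estimators it is close to nominal. No bootstrap is provided. For DR2
the point estimate is decomposed exactly into a weighting part
$\hat\nu_{1a}(t)$ and an outcome part $\hat\nu_{2a}(t)$
(`influence_decomposition()`), each centered within its own part of the
influence function.

## A worked example

```{r example, eval = FALSE}
scen <- preset_scenario("weak", "cox")
smp <- generate_sample(scen, seed = 7)
fit <- transport_survival(smp, times = c(0.128, 0.331, 0.712),
                          estimators = c("ipw2", "dr2"))
fit$dr2
taste(fit$dr2, 0.712)
```

## The synthetic world

`preset_scenario()` reproduces the benchmark data-generating process used
throughout the tests: a population of $10^6$ individuals with
$X_1, X_2 \sim N(0,1)$ and $X_3 \sim \mathrm{Bernoulli}(0.5)$; logistic
trial selection with coefficients $(-6.5, -0.2, -0.1, -0.5)$ ("weak") or
$(-6.7, -0.8, -0.4, -1)$ ("strong"); logistic survey inclusion with
coefficients $(-7, 0.3, 0.4, 0.2)$ and design weight equal to the true
inverse inclusion probability; Bernoulli(0.5) randomization; potential
failure times from per-arm Cox models with unit exponential baseline and
log-hazards $(0.2, -0.6, 0.6)$ (treated) and $(0.2, 0.6, -0.6)$ (control);
and censoring either from a shared Cox model with log-hazards
$(0.1, 0.4, -0.6)$ or from $\mathrm{Uniform}(0, 2.1)$. These settings
yield roughly 1200 trial and 1100 survey records and an overall trial
censoring rate near 45% (about 43.7% under the uniform mechanism at weak
selection — the "approximately 45%" is an average across scenarios).

Design notes on the generator:

* The unit exponential baseline is forced by the printed hazards having no
  separate time-varying factor; failure times are drawn by inversion,
  $T^{(a)} = -\log V / \exp(\mathrm{coef}_a' X)$.
* `true_taste()` computes the oracle estimand by importance weighting each
  covariate draw by $P(S = 0 \mid X)$ instead of rejection sampling;
  with $P(S=1) \approx 10^{-3}$ the two are practically identical but the
  weighted form is exact at any draw count. Because nonparticipation is so
  close to certain, the truth under the weak and strong selection models
  differs only in the fourth decimal; the package computes whichever
  scenario it is handed.
* One master seed spawns sub-seeds for the population, selection,
  treatment, failure and censoring stages, so scenarios sharing a seed
  share their population draw.

What a green simulation test does *not* establish: the generator has
independent, well-specified covariates, a correctly specified logistic
selection model, and known survey weights. Real applications face
unmeasured effect modifiers, misspecified selection, estimated weights,
and positivity problems, none of which the synthetic world exercises.

## Numerical choices

* **Ties** are handled by the Breslow convention in both the partial
  likelihood and the baseline, matching the Breslow baseline estimator;
  with no covariates the fits reduce exactly to Nelson–Aalen.
* **Evaluation conventions**: survival indicators are closed at `t`
  (`I(U >= t)`); the censoring survival is evaluated at a subject's *own*
  time through the left limit `K(U-|X)` (standard inverse probability of
  censoring weighting practice), but at the fixed analysis time through
  the right-continuous value `K(t|X)` in the DR residual, mirroring the
  different arguments of the two constructions. The WKM curve likewise
  takes products over event times strictly before `t`.
* **Martingale integral**: the augmentation compensator is a finite sum
  over the Breslow jump set of the censoring baseline — the estimated
  hazard is a pure-jump measure, so no quadrature is involved.
* **Floors**: estimated survival probabilities and sampling scores are
  floored at `1e-8` wherever they enter a denominator; DR estimates are
  *never* clipped into [0, 1] (out-of-range values are flagged).
* **Truncation**: `truncate_pct` floors the sampling *score* (not the
  weight) at the upper empirical percentile
  $x_{(\lfloor np \rfloor + 1)}$ of the *trial* score distribution. The
  upper-quantile convention makes a 50% truncation of two scores floor
  both at the larger; the restriction to trial scores (rather than the
  combined sample) is a documented choice. Truncation is off by default —
  the simulation benchmarks use untruncated scores.
* **Extrapolation**: beyond the largest baseline jump the last value is
  carried forward; analysis times should stay within the observed trial
  follow-up.
* **Failed replications** in `run_mc()` (non-convergent fits) are dropped
  and counted, not imputed.

## Open design points resolved here

* The WKM variance is an influence-function sandwich with weights treated
  as known. It tracks the curve's sampling noise but, unlike some survey
  Kaplan–Meier implementations, it is not inflated by design effects, so
  WKM interval coverage in the harness is lower than the very conservative
  published pattern; only WKM *bias* is benchmarked.
* The variance formulas for the self-normalized estimators (`ipw2`,
  `dr2`) are implemented exactly as stated, without an additional
  survey-weight normalization in the weighting part; the asymmetry with
  the `ipw1`/`dr1` formulas is intentional.
* The record-duplication variance check is stated for the self-normalized
  estimators: duplicating every record with halved survey weights halves
  the `ipw2`/`dr2` variances exactly; the Horvitz–Thompson versions do not
  admit the same clean rescaling because trial records carry no survey
  weight.

## Limitations

No competing risks, left truncation, time-varying covariates, stratified
baselines or penalized fits; the treatment propensity is treated as known;
no calibration/entropy-balancing weights; no bootstrap; no sensitivity
analysis for unmeasured effect modifiers. The full published-scale
replication (5000 replications, four scenarios) is supported through
`run_mc(n_reps = 5000)` but the shipped tests run the 500-replication desk
scale with correspondingly widened Monte Carlo tolerances.
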
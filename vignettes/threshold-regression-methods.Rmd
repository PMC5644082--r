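---
title: "Threshold regression models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold regression models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thresholdreg)
```

## The models

Threshold (change-point) regression models express a nonlinear relationship
between an outcome and a continuous predictor $x$ through a single
interpretable parameter: the threshold $e$ at which the relationship changes
form. With adjustment covariates $z$, the linear predictor $\eta$ of a GLM
takes one of four shapes:

$$
\begin{aligned}
\eta &= \alpha_1 + \alpha_2^\top z + \beta_1 I(x > e)
  && \text{step} \\
\eta &= \alpha_1 + \alpha_2^\top z + \beta_1 (x - e)_+
  && \text{hinge} \\
\eta &= \alpha_1 + \alpha_2^\top z + \beta_1 (x - e)_+ + \gamma x
  && \text{segmented} \\
\eta &= \alpha_1 + \alpha_2^\top z + \beta_1 (x - e)_+ + \gamma x
        + \beta_2 I(x > e)
  && \text{stegmented}
\end{aligned}
$$

where $(x - e)_+ = (x - e)\, I(x > e)$ is the hinge function. Step and hinge
are flat below the threshold; segmented allows slope $\gamma$ below and
$\gamma + \beta_1$ above; stegmented adds a jump $\beta_2$, fusing the step
and segmented shapes. Step and stegmented are discontinuous at $e$; hinge
and segmented are continuous. The indicator is strict — observations with
$x = e$ contribute 0 — and the package supports the logistic link for
binary outcomes and the identity link for continuous ones. The number of
threshold-dependent design columns is $p = 2$ for stegmented and $p = 1$
otherwise; this $p$ recurs throughout the testing theory.

These shapes are common in dose-response and biomarker problems — for
example, an immune-response biomarker that is uninformative below a
protective titer and associated with decreasing risk above it is a hinge
relationship.

## Estimation

The likelihood is not smooth in $e$, so standard gradient methods do not
apply directly. Two search strategies are provided.

**Exact (grid) search.** For a fixed candidate $e$ the model reduces to an
ordinary GLM on the design $[1, z, (\gamma\,\text{column } x), x(e)]$, fit
by IRLS. `fit_exact()` evaluates this profile likelihood at every candidate
and returns the maximizer; it is globally optimal over the grid and needs no
starting value, at $O(\text{grid})$ GLM fits of cost. Candidates are the
distinct observed values of $x$ inside a central quantile window (default
5%–95%) — each candidate then induces a distinct data partition. When more
than `max_grid` (default 500) distinct values are eligible, a deterministic
subset at equally spaced ranks is used. Ties in the profile break toward the
smallest candidate, and an estimate on the grid boundary raises a warning
(the likelihood may still be climbing outside the window).

**Smooth approximation.** `fit_smooth()` replaces $I(x > e)$ by the sigmoid
$[1 + \exp\{-b(x - e)\}]^{-1}$ and $(x-e)_+$ by $(x - e)$ times that
sigmoid, making the likelihood differentiable in $e$. Estimation alternates
two blocks until the maximum relative parameter change drops below `tol`
(default $10^{-6}$, at most `max_iter = 100` iterations):

1. maximize over $(e, \beta, \gamma)$ with the remaining coefficients fixed,
   using L-BFGS-B with $e$ box-constrained to the candidate range;
2. refit all coefficients by IRLS at the current $e$ on the smoothed design.

The starting value is the candidate with the maximal score statistic (see
below), which costs a single null fit rather than a full profile pass. The
smoothing scale defaults to $b = 20/\mathrm{sd}(x)$: large enough that the
sigmoid transitions within a small fraction of the predictor's spread,
small enough that the objective retains usable curvature. Two
de-biasing steps follow convergence: the profile is re-examined on the
exact (hard-indicator) likelihood at the grid candidates within $4/b$ of
the smoothed optimum — the sigmoid displaces the optimum by $O(1/b)$, and
this local polish removes that displacement while staying local — and the
reported coefficients come from a hard-indicator refit at the final
threshold, so smooth and exact fits are directly comparable. The smooth
search can still land in a local basin on weakly informative data; the
exact search is the reference when runtime permits.

Note the sigmoid is oriented *increasing* in $x$, approaching $I(x > e)$;
with the opposite sign convention for $b$ it would approach $I(x < e$).

## Hypothesis testing

The threshold-effect null is $\beta_1 = 0$ (jointly $\beta_1 = \beta_2 = 0$
for stegmented); $\gamma$ stays in the null model and is never tested.
Under the null the threshold is unidentified, so the per-candidate
statistics are maximized over the grid and the maximum is calibrated by
Monte Carlo:

* `score_process()` fits the null model once and computes, per candidate,
  the score $S_\beta(e)$ of the threshold block at the null fit and the
  efficient information $\hat I_{\beta\beta.\alpha}(e)$ (with the nuisance
  block partialled out); the standardized statistic is
  $T(e) = S_\beta^\top \hat I_{\beta\beta.\alpha}^{-1} S_\beta$.
* `lr_process()` refits the alternative at each candidate and returns
  $Q(e) = 2\{\ell_1(e) - \ell_0\} \ge 0$. At a fixed $e$, $Q(e)$ is
  asymptotically $\chi^2_p$ and asymptotically equivalent to $T(e)$.
* `mc_null_distribution()` draws $B$ samples of length $pM$ from
  $N(0, R)$ where $R = JVJ$, $V$ is the covariance of the stacked scores
  and $J$ is block-diagonal in $\hat I_{\beta\beta.\alpha}^{-1/2}(e_m)$
  (each candidate uses its own information block); each draw is cut into
  $M$ $p$-tuples, squared and summed per tuple, and the maximum over
  tuples is one draw from the null distribution of the maximal statistic.
* `max_test()` reports $\max_m Q(e_m)$ (or $\max_m T(e_m)$; the score
  version only exists for $p = 1$) and the p-value
  $\#\{\text{draws} > \text{observed}\}/B$, with a conservative
  $(1+\#)/(1+B)$ variant behind a flag.

$V$ is assembled model-based by default — for candidates $(e_i, e_j)$,
$V_{ij} = X_i^\top W X_j - X_i^\top W Z (Z^\top W Z)^{-1} Z^\top W X_j$
with $W$ the IRLS weights at the null fit — which is the efficient-score
covariance consistent with $\hat I_{\beta\beta.\alpha}$. An empirical
variant (outer products of per-observation efficient scores) is available
via `v_type = "empirical"`. Both tests share the estimation grid by
default.

## Confidence intervals

Two constructions, with different validity:

* **Model-based** (`model_based_ci()`). For the continuous families (hinge,
  segmented) all parameters including $e$ converge at the regular
  $n^{-1/2}$ rate, so joint Wald intervals come from the observed
  information of the full parameter vector, computed numerically on the
  smoothed likelihood (where the model is differentiable) at the default
  smoothing scale. For the discontinuous families the threshold converges
  at the faster $n^{-1}$ rate and Wald theory does not apply to $e$:
  coefficients get Wald intervals at the fixed estimate and $e$ gets the
  profile-likelihood set
  $\{e: 2(\ell(\hat e) - \ell(e)) \le \chi^2_{1,\text{level}}\}$, reported
  as the hull of the set with a contiguity flag.
* **Model-robust** (`robust_ci()`), offered for the continuous families,
  whose $n^{-1/2}$ rate survives misspecification. The default is a
  nonparametric case-resampling bootstrap (percentile intervals, default
  1000 replicates, deterministic given a seed; replicates that fail to
  refit are dropped, with an error above 20%). A sandwich
  (heteroskedasticity-consistent) Wald variant for the coefficients at
  fixed $\hat e$ is available via `type = "sandwich"`; it does not produce
  an interval for $e$. The percentile bootstrap was chosen over
  closed-form robust variances because it is fully determined by the
  resampling scheme, covers $e$ as well as the coefficients, and is
  equivariant under monotone transformation of $x$.

## The synthetic-data generator

`sim_scenario()`/`gen_data()` emulate a canonical simulation design for
these models: $z \sim N(0, 1)$, $x \sim N(4.7, 1.6)$, threshold at the
center of the $x$ distribution ($e = 4.7$), logistic or Gaussian outcome.
Default effect sizes, chosen once and used by all studies:
$\alpha_2 = 0.5$, $\gamma = 0.5$ where present, hinge/segmented slope
$\beta_1 = -0.92$, step $\beta_1 = 1$, stegmented jump $\beta_2 = 0.5$.
The intercept defaults to the value giving a marginal event rate of about
one third under the logistic link, found by Gauss-Hermite quadrature over
the covariate distributions — without this calibration the $\gamma x$ term
(mean $x$ is 4.7) would push event rates above 0.8 and distort small-sample
behavior. Null scenarios set the tested $\beta$ to 0 and keep everything
else.

What the generator does *not* emulate: covariate measurement error,
assay detection limits (left-censored $x$ is common in titer data), heavy
tails or skewness in $x$, model misspecification beyond the threshold form,
and correlated covariates. Passing simulation studies therefore certify the
estimators and tests under a correctly specified threshold GLM with
Gaussian covariates — not robustness to those real-data features.

`bias_table()` reports relative bias for coefficients — Monte Carlo mean
versus truth, except the stegmented family where the median replaces the
mean because its sampling distributions are markedly skewed — and raw bias
for $e$. `iqr_table()` reports Monte Carlo interquartile ranges, and
`type1_table()` rejection rates at a nominal level, sharing one score
decomposition and one draw stream per replicate between the score and LR
tests. All reports retain per-replicate estimates, so every summary is
re-derivable, and all are deterministic given their seeds (per-replicate
seeds derive from the master seed up front, independent of evaluation
order).

## Numerical choices

* IRLS declares convergence when the relative deviance change falls below
  $10^{-8}$ *and* the coefficients have stabilized (relative step below
  $10^{-4}$), within at most 100 iterations, with step-halving whenever a
  full Newton step would decrease the likelihood. The second condition and
  the halving matter: on quasi-separated data the deviance plateaus while
  the coefficients still drift, and a plain Newton step can diverge from a
  poor start — either would make the reported profile value depend on the
  starting point, breaking the exact equality between the warm-started
  grid search and a cold-started refit. The hot profile loop is compiled
  (RcppArmadillo) with warm starts along the sorted grid; the pure-R
  fitter is the reference implementation and the two are compared in the
  tests.
* Quasi-separated reduced fits — coefficients that never settle, or
  $|\eta| > 30$ at convergence, where the likelihood has no usable
  interior maximum — are flagged non-converged and recorded as $-\infty$
  in the profile (with a warning), never silently dropped. A Gaussian fit
  that interpolates exactly (zero residual sum of squares) is recorded as
  $+\infty$, which makes perfectly separated toy examples recover their
  threshold.
* The correlation matrix $R$ is symmetrized with a unit diagonal imposed;
  if its Cholesky factorization fails, a $10^{-8}$ diagonal jitter is
  tried silently (rounding leaves $R$ indefinite at the $10^{-13}$ level),
  and only then are negative eigenvalues clipped, with a warning.
* Degenerate inputs error early: fewer than 10 eligible distinct candidate
  values, constant $x$, rank-deficient designs, non-binary outcomes under
  the logistic link. Missing values in used columns are dropped as
  complete cases with a reported count.

## Study sizes used by the shipped tests and acceptance script

The test suite runs the type-1-error study at $n = 250$ with 2,000
replicates per family and $B = 1000$ calibration draws; consistency trends
use 300 replicates per family at $n \in \{250, 500, 2000\}$;
smooth-versus-exact agreement uses 200 datasets at $n = 500$ with slope
$-2.5$ (a strong, high-power signal); the $\chi^2$ calibration checks use
2,000 replicates at $n = 1000$. `scripts/acceptance.R` recomputes the same
quantities at 500 replicates. These sizes keep Monte Carlo standard errors
near 0.005–0.01 on rejection-rate scales.

## Known limitations

* One threshold per model; no multiple change points and no
  interactions between thresholded and non-thresholded predictors.
* Only logistic and identity links.
* The maximal score test does not exist for the stegmented family
  ($p = 2$); use the LR version.
* The smooth search is local; on weak signals it can disagree with the
  exact search (both are returned with full traces, so discrepancies are
  visible).
* Model-robust intervals are offered only for the continuous families; for
  discontinuous families under misspecification (slower $n^{-1/3}$
  asymptotics) no robust interval is provided.
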
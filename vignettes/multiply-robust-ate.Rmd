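---
title: "Multiply robust ATE estimation with empirical-likelihood calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiply robust ATE estimation with empirical-likelihood calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrate)
```

## The estimation problem

In an observational study with covariates $X_i \in \mathbb{R}^p$, a binary
treatment $Z_i$ and an outcome $Y_i$, the average treatment effect (ATE) is
$\Delta = E(Y^1) - E(Y^0)$, the mean difference of the two potential
outcomes.  Under exchangeability given $X$, consistency and positivity,
$\Delta$ is identified, and the two classical estimation routes each lean on
one working model: inverse probability weighting (IPW) on a propensity-score
(PS) model $\pi(X) = P(Z = 1 \mid X)$, and g-computation on an outcome
regression (OR) model $m(X, Z) = E(Y \mid X, Z)$.  Either route is
inconsistent when its single model is misspecified.

`mrate` implements a *multiply robust* (MR) estimator: the analyst supplies
two candidate sets, $\{\pi^1, \dots, \pi^L\}$ for the PS and
$\{m^1, \dots, m^K\}$ for the OR, freely mixing parametric fits with
single-hidden-layer neural networks.  The estimator is consistent if **any
one** candidate in either set is correctly specified, and the nonparametric
network candidates extend that protection to settings where every parametric
candidate is wrong.

## The calibration weights

Each candidate is fit once on the full sample.  Writing
$\hat\theta_1^l = n^{-1}\sum_i \hat\pi^l(X_i)$,
$\hat\theta_0^l = 1 - \hat\theta_1^l$ and
$\hat\eta_z^k = n^{-1}\sum_i \hat m_z^k(X_i)$ (full-sample averages, both
arms), the treated-arm weights maximise the empirical likelihood
$\prod_{i: Z_i = 1} w_i$ subject to

$$w_i \ge 0,\qquad \sum_i w_i = 1,\qquad
  \sum_i w_i\,\hat\pi^l(X_i) = \hat\theta_1^l,\qquad
  \sum_i w_i\,\hat m_1^k(X_i) = \hat\eta_1^k,$$

with the symmetric system (using $1 - \hat\pi^l$ and $\hat m_0^k$) in the
control arm.  The solution has the closed form
$w_i = n_1^{-1} / (1 + \hat\rho^\top \hat g(X_i))$ where
$\hat g(X_i)$ stacks the centred candidate values and the Lagrange
multipliers $\hat\rho$ solve
$\sum_i \hat g(X_i) / (1 + \hat\rho^\top \hat g(X_i)) = 0$ subject to the
positivity condition $1 + \hat\rho^\top \hat g(X_i) > 0$.  The MR estimate
is the reweighted contrast
$\hat\Delta = \sum_{i \in \text{treated}} \hat w_i Y_i -
 \sum_{j \in \text{control}} \hat w_j Y_j$.

Intuitively, the weights tilt each arm as little as possible (in the
empirical-likelihood sense) while forcing it to reproduce the full-sample
average of every candidate's predictions; if one candidate is the truth,
this calibration removes the confounding that the arm's covariate imbalance
would otherwise induce.

### Numerical solution

The stationarity equations are solved through the convex dual
$F(\rho) = -\sum_i \log(1 + \rho^\top g_i)$, minimised by Newton's method
from $\rho = 0$:

* **Line search.** Each Newton step is halved until the iterate keeps every
  $1 + \rho^\top g_i$ above a feasibility buffer of $1/n_{\text{arm}}^2$
  (weights stay finite but may be very unequal) and does not increase $F$,
  with a $10^{-11}$ relative slack so full steps are not rejected once the
  decrease falls below floating-point rounding.
* **Convergence** is declared when the weight-normalised residual
  $\max_l |\sum_i w_i g_{il}|$ drops below $10^{-8}$ (cap: 50 iterations).
  The *raw* dual gradient is not a safe criterion: when the calibration
  targets lie outside the convex hull of the arm's candidate values the
  dual is unbounded and the raw gradient also tends to zero along the
  divergent path, while the normalised residual stays bounded away from it.
  Hull violations therefore surface as a structured
  `mrate_convex_hull_error` instead of a silently wrong answer.
* **Collinearity.** Near-duplicate constraint columns (e.g. two almost
  identical PS candidates) are detected by rank-revealing QR at tolerance
  $10^{-10}$, dropped, and reported; their multipliers are returned as 0.
  A singular Newton system falls back to a $10^{-10}$-ridge solve.
* The returned weights are renormalised to sum to exactly 1, removing
  $O(10^{-8})$ drift left by the finite tolerance.

These tolerances are chosen so that constraint residuals are orders of
magnitude below Monte-Carlo noise at any realistic sample size; they are
exposed as arguments of `el_solve()`.

## Candidate models

Parametric candidates are maximum-likelihood logistic regressions (PS) and
full-sample OLS fits with the treatment as a regressor (OR); counterfactual
predictions $\hat m_1, \hat m_0$ evaluate the single fit at $Z = 1, 0$.
Arm-stratified OR fitting is deliberately not used: the candidate notation
$m^k(X, Z)$ with counterfactual evaluation presumes one fit over both arms.

Network candidates use `nnet` with one hidden layer of 4 logistic units and
the package's default optimiser settings (BFGS, at most 100 iterations, no
weight decay, uniform random initial weights), a sigmoid output with entropy
loss for the PS and a linear output with squared-error loss for the OR.
Inputs enter unscaled — the built-in generator produces unit-scale
covariates; analysts feeding raw data with wildly different scales should
standardise first.  Each fit draws its initial weights from a seed derived
deterministically from the `seed` argument, so a single restart suffices for
reproducibility; `size`, `maxit` and `decay` are exposed on `ps_nnet()` /
`or_nnet()` for sensitivity analysis.

The IPW comparator defaults to the self-normalised (Hájek) form because the
MR weights it is benchmarked against are normalised by construction; the
Horvitz–Thompson form is available via `ipw_normalize = FALSE`.  Fitted
propensities are clipped to $[10^{-6}, 1 - 10^{-6}]$ before any weighting.

## Confidence intervals

`mr_ate(..., B = 200)` runs a nonparametric bootstrap: rows are resampled
i.i.d. with replacement (not stratified by arm), the *entire* pipeline —
including network refits, with resample-specific sub-seeds — is re-run, and
the variance over resamples $\widehat{\text{var}} =
(B-1)^{-1}\sum_b (\hat\Delta^b - \bar{\hat\Delta})^2$ yields the
normality-based interval $\hat\Delta \pm 1.96\,\widehat{\text{var}}^{1/2}$,
centred at the original-sample estimate (a per-resample quantity cannot
centre one interval; the bootstrap mean is kept for diagnostics).
Degenerate resamples (an empty arm, a hull violation) are skipped and
counted; more than 20% failures aborts the interval.  $B = 200$ is the
package default in the scenario engine — adequate for a variance, modest for
tail quantiles, which is why only the normal-theory interval is offered.

## The synthetic validation design

`sim_ate_data()` draws ten standard-normal covariates with
$\mathrm{corr}(X_1,X_5) = \mathrm{corr}(X_4,X_9) = 0.9$,
$\mathrm{corr}(X_2,X_6) = \mathrm{corr}(X_3,X_8) = 0.2$ and all other pairs
independent (a jointly multivariate normal draw — the minimal faithful
choice given only pairwise correlations), assigns treatment by

$$\mathrm{logit}\,P(Z=1 \mid X) = 0.8X_1 - 0.25X_2 + 0.6X_3 - 0.4X_4
  - 0.8X_5 - 0.5X_6 + 0.7X_7$$

(no intercept; prevalence ≈ 50%), and generates

$$Y = -3.85 + 0.3X_1 - 0.36X_2 - 0.73X_3 - 0.2X_4 + 0.71X_8 + 0.19X_9
  + 0.26X_{10} + 0.3X_1^2 - 0.36X_2^2 + Z + \varepsilon,\quad
  \varepsilon \sim N(0,1)$$

so the subject-level effect — hence the true ATE — is exactly 1.  The noise
is independent of $X$ and $Z$, and one seeded RNG stream per dataset covers
covariates, treatment and noise in that order.

What this emulates: moderate-dimensional correlated confounding, a
curvature term that a main-effects linear OR misses, and ~50/50 treatment
split.  What it does not: heteroscedastic or heavy-tailed noise, treatment
effect heterogeneity, poor overlap, discrete covariates, missingness.
Passing tests on this design demonstrate the estimator's algebra and its
robustness ordering, not performance on messy real data.

The four built-in scenarios of `mr_scenario()` pair this generator with
three PS and three OR candidates each (network first, then two parametric):
T1/T3 include a correctly specified parametric PS ($X_1..X_7$) and a nearly
correct parametric OR; T2/T4 shrink both parametric models to strict
subsets so that *every* parametric candidate is wrong; T3/T4 give the
networks all ten covariates instead of the relevant subsets.  The third PS
(squares only) and third OR (pairwise interactions only) candidates are
misspecified everywhere.  MR estimators are named by inclusion digits —
`MR000010` calibrates on the second OR candidate only.

One caveat discovered during validation and worth stating: the second OR
candidate of T1/T3 omits $X_4$ (its features are
$X_1, X_2, X_3, X_8, X_9, X_{10}, X_1^2, X_2^2$ and $Z$) while the
generator's outcome carries $-0.2X_4$; because $X_4$ is 0.9-correlated with
$X_9$ and enters the PS, this candidate is *nearly* but not exactly correct
and retains a small (~1%) bias at n = 2000.  The exactly correct OR
formula (including $X_4$) is used where tests assert unbiasedness itself.

## Monte-Carlo engine

`run_scenario()` pre-draws one sub-seed per replication from `base_seed`
(so summaries are identical for any `workers` count), simulates, fits the
candidate set once per replication, evaluates all requested estimators, and
aggregates the signed mean relative bias $100 \cdot
\overline{(\hat\Delta_r - 1)}$, the RMSE, and — when `B > 0` — the fraction
of per-replication 95% intervals covering 1.  Replications that fail
(hull violations, degenerate resamples) are dropped from all three metrics
and reported in `n_converged`.  Candidate models are fitted lazily: a run
that only asks for `OR.model2` never trains a network, which is what makes
the 1000-replication parametric panels run in seconds.

Problem sizes used by the shipped reproduction script
(`scripts/acceptance.R`): 1000 replications for parametric-only panels at
n = 2000 and n = 500; 200 replications for network-based rows; 200
replications × B = 200 for the coverage panel.  These were chosen as the
smallest sizes at which Monte-Carlo error is clearly smaller than the
effects being measured.

## Known limitations

* No cross-fitting or sample splitting for the network candidates; the
  same data train and evaluate them, as in the underlying method.
* No asymptotic (sandwich or EL-based) standard errors — the bootstrap is
  the only inferential route.
* ATT, risk ratios, and survival outcomes are out of scope.
* The convex-hull condition can genuinely fail in small arms with many
  candidates; the package reports this rather than working around it.
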
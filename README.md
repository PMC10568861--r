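# mrate — multiply robust estimation of the average treatment effect

`mrate` estimates the average treatment effect (ATE),
Δ = E(Y¹) − E(Y⁰), from observational data for analysts who cannot be sure
which working model is right.  Instead of betting on one propensity-score
(PS) model or one outcome-regression (OR) model, you supply *candidate
sets* — any mix of logistic/linear regressions and single-hidden-layer
neural networks — and the estimator calibrates empirical-likelihood weights
in each treatment arm against all of them:

maximise ∏ wᵢ subject to wᵢ ≥ 0, Σwᵢ = 1, Σwᵢ π̂ˡ(Xᵢ) = θ̂₁ˡ and
Σwᵢ m̂₁ᵏ(Xᵢ) = η̂₁ᵏ for every candidate (treated arm; symmetric in the
control arm), where θ̂₁ˡ and η̂₁ᵏ are full-sample averages of the fitted
candidates.  The weights have the closed form
wᵢ = n₁⁻¹/(1 + ρ̂ᵀĝ(Xᵢ)) with Lagrange multipliers ρ̂ found by a damped
Newton solve of the convex dual, and the estimate is the reweighted
contrast Δ̂ = Σ wᵢYᵢ (treated) − Σ wⱼYⱼ (control).  The estimator is
consistent if **any one** candidate model is correctly specified —
multiply robust — and including a nonparametric network candidate keeps it
honest when every parametric candidate is wrong.  Inference is via a
nonparametric bootstrap (normality-based 95% CI).

The package also ships IPW (Hájek or Horvitz–Thompson) and g-computation
comparators, a synthetic data generator with a known true ATE of 1, and a
Monte-Carlo engine that reports mean relative bias, RMSE and coverage.

## Worked example

```r
library(mrate)

d <- sim_ate_data(2000, seed = 7)      # true ATE = 1 by construction
sc <- mr_scenario("T1")                # 3 PS + 3 OR candidates (net first)
fit <- mr_ate(d, sc$ps_models, sc$or_models,
              estimators = c("IPW.model2", "OR.model2",
                             "MR000010", "MR000111"),
              B = 200, seed = 7)
fit
#> Multiply robust ATE estimation
#>   n = 2000 (treated 1018, control 982), bootstrap B = 200
#>
#>   estimator estimate    se ci_lower ci_upper boot_failed
#>  IPW.model2    0.897 0.088    0.725    1.068           0
#>   OR.model2    0.997 0.044    0.910    1.084           0
#>    MR000010    0.996 0.044    0.909    1.082           0
#>    MR000111    0.996 0.047    0.904    1.088           0
```

Estimator names: `IPW.modelK` / `OR.modelK` use the K-th candidate alone;
`MR` followed by one binary digit per candidate (PS first, then OR) selects
the calibration subset — `MR000010` calibrates on the second OR candidate
only, `MR000111` on all three OR candidates including the network.  All
four estimates bracket the true value 1; the naive difference of arm means
on this draw is 0.69, the confounding the weights remove.  `coef()`,
`confint()`, `summary()` and `plot()` work as usual on the fitted object.

Custom candidates are plain formulas:

```r
fit2 <- mr_ate(d,
  ps_models = list(ps_glm(~ X1 + X2 + X3), ps_nnet(~ X1 + X2 + X3)),
  or_models = list(or_lm(~ X1 + I(X1^2) + X3)),
  estimators = "MR111", B = 200)
```

A thin command-line front end covers the same workflow
(`exec/mrate simulate | estimate | simulate-study`).

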
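# recprobit

Semiparametric recursive bivariate probit models for estimating the effect
of a binary endogenous treatment on a binary outcome in the presence of
unobserved confounding, with penalized regression-spline smooth terms for
nonlinear covariate effects.

The motivating application is cardiology registry data on ST-elevation
myocardial infarction (STEMI): did an effective reperfusion (`STres`, >70%
ST-segment resolution after angioplasty) lower in-hospital mortality, given
that unmeasured hospital- and patient-level factors plausibly drive both?

## The model

Two probit equations with correlated latent-Gaussian errors:

```
y1* = x1' delta1 + sum_k s_1k(x_1k) + e1        (treatment: STres)
y2* = gamma y1 + x2' delta2 + sum_k s_2k(x_2k) + e2   (outcome: mortality)
(e1, e2) ~ N2(0, [[1, rho], [rho, 1]]),   y_v = 1{y_v* > 0}
```

`rho` is the correlation of the unobserved confounders (and, for
intercept-only non-recursive fits, exactly the tetrachoric correlation of
the 2x2 table). Smooths `s()` are cubic regression splines with a
second-order roughness penalty and sum-to-zero constraints. Fitting is by
penalized maximum likelihood (exact analytic gradient and Hessian, Newton
with monotone step-halving); smoothing parameters minimize a deviance-based
approximate unbiased risk estimator (UBRE); intervals come from the
Bayesian posterior covariance `V = (penalized information)^-1` at
convergence. Treatment effects are reported as probability differences with
delta-method intervals, alongside the naive comparison estimators
(additive probit; unadjusted risk difference).

## Worked example

```r
library(recprobit)

# synthetic registry-like data with known truth: gamma = -1, rho = 0.4
d <- simulate_stemi(stemi_config(n = 3000, seed = 42))

fit <- recprobit(list(STres ~ access + age + s(O2B, k = 10),
                      mortality ~ STres + killip + EF),
                 data = d)
print(fit)
#> Semiparametric recursive bivariate probit
#> n = 3000, log-likelihood = -1896.8480, total edf = 9.004
#> Smoothing parameters: eq1:s(O2B) = 1e+07
#> rho 0.705 (0.458, 0.852)

ate(fit)
#> ATE [SBP]: -0.02433  (-0.03924, -0.009423)
#>   potential-outcome average: -0.2482  (-0.3866, -0.1097)
attr(d, "true_ate")
#> [1] -0.1379139
```

This seed illustrates both outputs of `ate()`: the first line is the fitted
average *conditional* contrast `P(y2=1|y1=1,x) - P(y2=1|y1=0,x)` (the
model's reported ATE expression, attenuated toward zero by latent-error
selection when `rho != 0`); the second is the counterfactual
potential-outcome average, which is the quantity that tracks the
generator's true ATE. Across replicates the estimators center on the truth
(this particular seed sits about 1.5 standard errors off along the
well-known flat `gamma`/`rho` ridge); the package's tests run that
replication study.

`summary(fit)` prints per-equation coefficient tables (estimate, standard
error, p-value), smooth-term tables (edf, estimated rank, Wald p-value) and
the `rho` row with its delta-method interval; `plot(fit)` draws each fitted
smooth with credible bands; `tetrachoric()`, `ate_probit()`,
`ate_unadjusted()` and `ate_table()` cover the comparison analyses; and
`run_stemi_pipeline()` runs simulate → fit → report end to end with
byte-reproducible output.

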
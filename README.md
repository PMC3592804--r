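# bayesppk

Robust Bayesian population pharmacokinetics with multivariate Student-t
errors.

## The problem

Population pharmacokinetic (PPK) studies model drug concentration-time
profiles across many subjects, separating inter-individual variability
(random effects) from residual measurement scatter. The standard
assumption — normally distributed residuals on the log scale — is fragile:
one or two aberrant concentrations per subject can visibly distort the
estimated absorption and elimination parameters. `bayesppk` replaces the
normal residual model with a heavy-tailed multivariate Student-t model and
fits it with a constrained Metropolis–Hastings sampler, for analysts who
want outlier-resistant population estimates without abandoning the familiar
one-compartment framework.

## The model

The one-compartment first-order absorption curve

```
c(t) = D ka / (V (ka - ke)) * (exp(-ke t) - exp(-ka t))
```

is approximated on the log scale by a fractional-polynomial mixed model.
For subject *i* at time *t_ij*:

```
log y_ij = beta0 + beta1 * t_ij + beta2 / t_ij + b_i + e_ij
```

with `beta1 < 0` and `beta2 < 0` enforced so the fitted curve rises through
an absorption phase and decays through elimination. The random intercept
`b_i ~ N(0, sigma1)` carries inter-individual variability; the residual
vector of each subject follows an isotropic multivariate t distribution
with scatter `sigma2 * I` and `nu` degrees of freedom (small `nu` = heavy
tails; `nu -> Inf` recovers the normal model). Priors are independent
normals on `beta` and gamma distributions on the variance components.
Posterior sampling is a blocked random-walk Metropolis–Hastings scheme
whose acceptance rule additionally rejects any proposal violating the sign
constraints. Derived population parameters — time to peak
`tmax = sqrt(beta2/beta1)`, peak concentration
`cmax = exp(beta0 - 2 sqrt(beta1 beta2))`, and two labeled half-life
variants — are computed per posterior draw. Error families (t, normal,
gamma GLM) are compared by AIC with the random effects integrated out by
quadrature.

## Worked example

Simulate the clean 10-subject study design (12 samples over 36 h, 10 mg
dose, generating `beta = (0.4, -0.04, -0.2)`, both variance components
0.008) and fit the t-error model:

```r
library(bayesppk)
sim <- simulate_dataset(preset_example(1, seed = 42))
fit <- run_chain(sim$data, pk_model_spec("t", nu = 4),
                 config = mcmc_config(n_iter = 5000, burn_in = 4000,
                                      summary_window = 1000, seed = 42))
summarize_chain(fit)[1:5, ]
#>   parameter     mean    lower   upper
#> 1     beta0  0.43327  0.36019  0.4986
#> 2     beta1 -0.03923 -0.04100 -0.0378
#> 3     beta2 -0.20797 -0.22070 -0.1955
#> 4    sigma1  0.00865  0.00317  0.0282
#> 5    sigma2  0.00725  0.00427  0.0114
```

The posterior means sit near the generating values; `beta0` also absorbs
this dataset's mean random intercept, so its spread reflects the
10-subject design, not sampler noise. Derived PK parameters follow from
the same chain:

```r
posterior_derived(fit)$summary
#>         parameter  mean lower upper
#> 1            tmax  2.30  2.24  2.36
#> 2            cmax  1.29  1.20  1.37
#> 3  thalf_terminal 17.68 16.91 18.34
#> 4 thalf_post_peak 19.74 18.99 20.39
```

`tmax` of ~2.3 h and `cmax` of ~1.3 mass/volume are the population peak;
the two half-life rows are the exponential-tail value `log 2 / (-beta1)`
and the numeric post-peak half-time — they differ whenever the `beta2 / t`
term still bends the curve after the peak.

A command-line front end (`inst/scripts/bayesppk`) wraps the same
functions: `simulate`, `fit`, `compare`, `summarize`, `plot`.

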
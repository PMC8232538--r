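# sarlogit

Bayesian structured additive logistic regression for hierarchical,
geo-referenced survey data, built around the analysis of *sufficient
knowledge of mother-to-child HIV transmission (MTCT) and its prevention
(PMTCT)* among women of reproductive age.  The package is aimed at
epidemiologists and biostatisticians working with DHS-style household
surveys who need to combine categorical determinants, nonlinear effects
of metrical covariates, and smooth spatial variation across
administrative regions in a single binary-outcome model.

## The model

Each woman `i` answers five knowledge questions (ever heard of HIV;
transmission during pregnancy, delivery, breastfeeding; awareness of
preventive drugs).  A respondent answering yes to all five has
*sufficient knowledge*: `y_i = 1(score_i = 5)`.  The outcome follows a
Bernoulli distribution with success probability `p_i` and structured
additive predictor

    logit(p_i) = x_i' beta + sum_j f_j(z_ij) + f_s(s_i) + v_c(i) + u_h(i)

where

* `x_i' beta` — dummy-coded fixed effects of categorical covariates
  (residence, marital status, religion, ethnicity, education, wealth
  quintile, working status, media exposure), vague `N(0, 1/1e-6)`
  priors;
* `f_j` — penalized B-spline smooths of metrical covariates (current
  age, age at first birth, antenatal-care visits) under a second-order
  random-walk prior `beta_t = 2 beta_{t-1} - beta_{t-2} + u_t`,
  `u_t ~ N(0, tau2_j)`;
* `f_s` — an intrinsic CAR (Gaussian Markov random field) spatial
  effect over the region contiguity graph:
  `f_s(s) | f_s(t), t != s ~ N(mean of neighbours, tau2_s / N_s)`;
* `v`, `u` — iid community (cluster) and household random effects;
* every variance gets a weakly informative `IG(a, b)` hyperprior
  (default `a = b = 0.001`).

Three nested specifications form a ladder: **M1** spatial effect only,
**M2** adds fixed effects and smooths, **M3** adds household and
community effects; they are compared by DIC.  Posterior inference is by
a blocked Gibbs sampler with Pólya-Gamma augmentation of the logistic
likelihood; sum-to-zero constraints identify the spatial field and each
smooth.  Reported surfaces are posterior odds-ratio tables, a
three-way per-region significance classification (95% credible
interval above / below / covering zero), and smooth-effect curves with
credible bands.

Because the underlying survey microdata are access-restricted, the
package ships a synthetic-data generator that emulates the survey's
hierarchical structure (regions on a contiguity graph, clusters,
households) and covariate marginals with known ground-truth effects, so
the whole pipeline is validated end to end by parameter recovery.

## Worked example

```r
library(sarlogit)

sim <- simulate_dataset(sim_config(n_women = 3000), seed = 11)
sim
#> sar_sim: 3000 women, 36 regions, 288 clusters, 2518 households; prevalence 0.591

model <- sar_model("M3",
  fixed   = default_fixed_levels()[c("residence", "education", "wealth")],
  smooths = list(sar_smooth("age")))
fit <- fit_sar(sim$records, sim$graph, model, sar_engine(2000, 500, seed = 12))

dic(fit)
#> M3: DIC 3865.72 (Dbar 3562.46, Dhat 3259.20, pD 303.26)

or_table(fit)[4:7, ]
#>   covariate     level mean  q2.5 q97.5
#> 4 education      none 1.00 1.000  1.00
#> 5 education   primary 1.10 0.857  1.41
#> 6 education secondary 1.07 0.877  1.29
#> 7 education    higher 1.57 1.154  2.12

table(classify_regions(fit)$classification)
#>          higher           lower not_significant
#>               5               7              24

cur <- smooth_report(fit, "age")
cur$x[which.max(cur$mean)]
#> [1] 35
```

The odds-ratio rows are posterior means and 95% credible limits of
`exp(coefficient)` against each covariate's reference level (printed as
1/1/1); here higher education raises the odds of sufficient knowledge
by an estimated 57%.  The region classification feeds a choropleth
significance map (the CSV joins to any boundary file on `region`), and
the fitted age curve recovers the simulated peak at 35 years.

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/cli/sarlogit.R`, subcommands `simulate`, `tabulate`, `fit`,
`report`, all driven by one YAML config).

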
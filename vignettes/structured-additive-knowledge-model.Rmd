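---
title: "Structured additive spatial modelling of composite knowledge outcomes"
author: "sarlogit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured additive spatial modelling of composite knowledge outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

National household surveys ask women of reproductive age a battery of
questions about mother-to-child transmission of HIV (MTCT) and its
prevention (PMTCT).  A woman who answers all five core questions
affirmatively — having heard of HIV; transmission during pregnancy,
delivery and breastfeeding; awareness of preventive drugs — is scored
as having *sufficient knowledge* (a 5-of-5 composite).  Two features of
such data complicate a plain logistic regression: outcomes vary
smoothly across administrative regions in ways no measured covariate
explains, and the effects of metrical covariates such as age are
visibly nonlinear.  sarlogit addresses both with a structured additive
predictor estimated in a fully Bayesian way.

Records missing any of the five responses are excluded from scoring and
modelling (the complete-case rule); `filter_complete_cases()` reports
the number dropped, and the CLI writes it into every run record.
Percentages in descriptive tables are rounded half-up to one decimal at
presentation only; stored proportions are never rounded.

## Model and priors

For woman $i$ in household $h$, cluster (community) $c$ and region $s$,

$$\operatorname{logit}(p_i) = x_i'\beta + \sum_j f_j(z_{ij}) + f_s(s_i) + v_{c(i)} + u_{h(i)},$$

with $y_i \sim \text{Bernoulli}(p_i)$.

* **Fixed effects.**  Categorical covariates are dummy coded against a
  declared reference level; coefficients get independent vague normal
  priors with precision `fixed_prec` (default $10^{-6}$).  Doubling the
  prior variance moves posterior means by less than 0.01 at $n = 5000$
  (tested), so results are prior-insensitive at survey scale.
* **Smooths.**  Each metrical covariate enters through `k = 20` cubic
  B-splines on equidistant knots spanning its observed range (standard
  P-spline practice; the fit is insensitive to `k` because the penalty
  controls the effective dimension).  Coefficients follow a
  second-order random walk $\beta_t = 2\beta_{t-1} - \beta_{t-2} + u_t$,
  $u_t \sim N(0, \tau_j^2)$, equivalently a quadratic penalty
  $K = D_2'D_2$ of rank $k - 2$ that leaves constant and linear
  sequences unpenalized.  Antenatal-visit counts are integers but are
  treated as metrical on their observed range.
* **Spatial effect.**  The intrinsic CAR prior on the region graph:
  given its neighbours, a region's effect is normal with mean the
  neighbour average and variance $\tau_s^2 / N_s$.  The implied joint
  precision is the graph Laplacian $Q = \operatorname{diag}(N_s) - A$,
  improper with rank (regions − components).
* **Random effects.**  Household and community effects are iid normal
  with their own variances.
* **Hyperpriors.**  Every variance gets a weakly informative
  $IG(a, b)$ prior, default $a = b = 0.001$, overridable in the prior
  configuration.

The ladder **M1** (spatial only) ⊂ **M2** (+ fixed + smooths) ⊂ **M3**
(+ household + community) is compared by DIC.

### Identifiability

The intercept, the spatial field and every smooth are confounded up to
additive constants.  We impose a sum-to-zero constraint on the spatial
field over regions and on each smooth over the *observations* (which
orthogonalizes it against the intercept only, not against linear
trends — fitted curves deliberately retain their trends, and the RW2
null space leaves the linear direction flat a priori, informed by the
data alone).  Constraints are imposed by conditioning each Gaussian
block draw on the constraint ("conditioning by kriging"), which yields
exact draws from the constrained conditional.

## Posterior computation

The posterior is analytically intractable; any approximation meeting
the package's oracle-equivalence contract would do.  The implemented
engine is a blocked Gibbs sampler with Pólya-Gamma augmentation:
$\omega_i \sim PG(1, \eta_i)$ makes every latent Gaussian block
conditionally Gaussian (with pseudo-observations $\kappa_i = y_i - 1/2$)
and every variance conditionally inverse-gamma.  The PG(1, z) sampler
is implemented in C++ from the standard alternating-series
accept–reject construction and driven by R's RNG, so a single seed
reproduces a fit exactly.

Numerical choices worth knowing:

* Blocks are updated in the order ω, fixed effects, smooths, spatial
  field, community, household, variances.  All latent states start at
  zero and variances at 0.1; burn-in (default 1000 of 4000 iterations)
  absorbs the transient.
* Smooth and spatial updates aggregate sufficient statistics over
  unique covariate values / regions, so iteration cost is linear in
  $n$ with small dense solves per block.
* Variance updates use the constrained quadratic forms with shapes
  $a + \text{rank}/2$ (rank $k-2$ for RW2, regions − 1 for the
  connected ICAR, counts for iid effects).
* The variance hyperprior applies to $\tau^2$ exactly as specified and
  summaries are reported on the $\tau^2$ scale.
* Mixing is summarized by effective sample sizes (initial positive
  sequence estimator); a minimum ESS below 30 triggers a warning and a
  `converged = FALSE` diagnostic flag — never a silent result.
* Degenerate inputs fail fast with informative errors: asymmetric
  adjacency, self-loops, regions absent from the graph, non-binary or
  missing outcomes, constant covariates offered to a smooth,
  disconnected graphs offered to the ICAR field sampler.  The spatial
  fitting constraint is a single global sum-to-zero; the default and
  intended geographies are connected (per-component constraints would
  be the natural extension for archipelago-like maps).

### DIC convention

`DIC = Dbar + pD` with `pD = Dbar - Dhat`.  `Dhat` is evaluated at the
posterior mean of the *linear predictor*, not of the parameters: under
sum-to-zero constraints and latent Gaussian blocks this plug-in is
always well defined and is the common convention for latent Gaussian
models.  DIC variants differ in this choice, so comparisons should use
values computed by this package only.  Ties in DIC rank are broken
toward fewer effective parameters.  Models are only comparable when
fitted to identical data; a content fingerprint enforces this.

### Odds-ratio reporting

Posterior odds-ratio *quantiles* commute with exponentiation;
the *mean* does not.  Tables therefore exponentiate the retained
coefficient draws and average (`posterior_transform_or()`); when only
summaries are available the mean is `exp(posterior mean)` and flagged
approximate.  Reference levels print as 1/1/1.  Regional significance
is judged on the linear-predictor scale (95% interval excluding 0),
which is equivalent to thresholding odds ratios at 1.

## The synthetic-data generator

Real survey microdata are access-restricted, so the generator is a
first-class module: it emulates the survey's structure closely enough
that every downstream stage can be validated by recovery of known
truth.

* **Geography.**  Default 6×6 rook lattice (36 regions, near the 37
  states-plus-capital units of the motivating survey); any real
  contiguity map can be supplied as a plain-text neighbour list.
* **Hierarchy.**  Women are assigned uniformly to regions, then to 8
  clusters per region, then grouped into households of size 1 (80%) or
  2 — matching the survey reality that most households contribute a
  single eligible respondent.
* **Covariates.**  Categorical marginals default to the published
  national distributions (58.0% rural, ethnic shares 31.9/17.1/12.8%,
  75.9% ever married, 16.5% newspaper readership, …); ages follow the
  published age-group shares; age at first birth and ANC visit counts
  use plausible parametric laws.
* **Truth effects.**  Fixed-effect defaults are the logs of the
  published posterior odds ratios — realistic in sign and magnitude.
  The age effect is an asymmetric Gaussian peaking at 35 years with
  rise-side width 8y and fall-side width 5y: a gradual monotone rise
  from 15 to a clear peak followed by a steep decline, the shape the
  motivating analysis describes; the widths were chosen so the peak is
  actually localizable (a near-flat rise would make "peak at 35" an
  empty statement at any realistic sample size).  Age at first birth is
  flat below 20 then linear (slope 0.04/y); ANC visits act linearly
  (0.06/visit).  All smooth contributions are centred over the sampled
  values.  The spatial field is an ICAR draw with $\tau_s^2 = 0.5$
  (marginal region effects of a few tenths on the logit scale, matching
  the visible spatial contrasts in national maps); household and
  community effects default to sd 0.3 — small enough that fixed effects
  remain recoverable, large enough that the community term is
  detectable.
* **Outcome.**  The predictor is assembled exactly as in the model and
  `sufficient ~ Bernoulli(logit^{-1}(\eta))`; the five individual
  responses are then filled in consistently with the composite (all yes
  iff sufficient), with realistic per-question no-rates among the
  insufficient.  The intercept defaults to the value that yields a
  59.2% marginal prevalence under the configured marginals.

What the generator does **not** emulate: two-stage sampling weights and
stratification, non-response, missing-data patterns, real geographic
shapes and population sizes, or dependence between covariates (they are
drawn independently).  Passing recovery tests therefore demonstrates
correctness of the estimation machinery under the assumed model, not
robustness to design effects or confounding structures present in real
surveys.

## Validation design and problem sizes

The test suite validates each layer at the smallest size that makes the
check sharp:

* **Exact structure.**  Penalty and precision matrices against closed
  forms and brute-force recounts; B-splines against an independent de
  Boor recursion; the ICAR sampler's covariance against the
  pseudo-inverse of the Laplacian on a 2×3 grid.
* **Oracle equivalence of the sampler** on five small instances
  (≤ 200 observations): intercept-only and one-covariate fits against
  dense numerical integration; the spatial path-graph fit against 3-D
  quadrature with the variance integrated out analytically; the
  8-coefficient smooth and the combined fixed + spatial instance
  against long JAGS runs with the constrained priors reparameterized
  exactly.  Agreement is required within three combined Monte Carlo
  standard errors.
* **Recovery.**  Fixed effects at $n = 2000$ (within 3 posterior sd);
  interval coverage pooled over 100 replicates at $n = 2000$ (required
  within 90–99%); the age-curve peak within ±3 years at $n = 20{,}000$;
  a +1 spatial effect classified "higher" in ≥ 90% of 20 replicates at
  $n = 10{,}000$; and the DIC ladder ordering M3 < M2 < M1 in a
  majority of 20 replicates at $n = 2500$.  Replicate fits use
  shortened chains (400–600 iterations); the coverage and ordering
  properties are robust to chain length because they average over
  replicates.

## Limitations

* The sampler is single-chain; between-chain diagnostics are not
  computed.  ESS-based warnings are a weaker convergence check.
* DIC values depend on the plug-in convention above and are not
  comparable across software.
* The spatial term assumes a connected contiguity graph in the fitting
  constraint; isolated islands need a user-supplied pseudo-adjacency
  (standard practice in disease mapping).
* Survey design (weights, stratification) is intentionally out of
  scope; estimates are model-based.
* Published results from the motivating restricted-access survey are
  not numerically reproducible here by design; the package's claims are
  about the method, validated on synthetic ground truth.
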
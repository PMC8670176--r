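---
title: "Joint random-effects models for preterm birth and perinatal death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint random-effects models for preterm birth and perinatal death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perijoint)
```

## The problem

Preterm birth (delivery before 37 completed gestational weeks) and perinatal
death (stillbirth after seven months' gestation or death within the first
seven days of life) are strongly associated: they share risk factors, and the
same mother's repeated deliveries are correlated. Analyzing each outcome with
a separate logistic regression ignores both sources of dependence. This
package implements the joint analysis used for mother-clustered birth-registry
cohorts: random-effects models in which a latent, mother-level intercept
induces the correlation, estimated by maximum likelihood with adaptive
Gauss–Hermite quadrature, with cluster-robust standard errors and BIC model
comparison on top.

## The models

Let $Y_{jik}$ be the binary outcome $j$ ($j = 1$ preterm birth, $j = 2$
perinatal death) of delivery $k$ of mother $i$, with covariate vectors
$X_{1i}$, $X_{2i}$ and fixed effects $\beta_1$, $\beta_2$.

**Shared-parameter bivariate logit.** A single scalar intercept $b_i \sim
N(0, \sigma^2)$ enters both linear predictors:
$$\mathrm{logit}\,\Pr(Y_{jik} = 1 \mid b_i) = \beta_j^\top X_{jik} + b_i .$$
Outcomes are conditionally independent given $b_i$; their joint density is the
integral of the product of Bernoulli factors over the normal random-effect
distribution. All of a mother's deliveries and both outcomes sit inside one
integral — that is what makes the model *joint*.

**Separate-but-correlated intercepts.** Each outcome gets its own intercept,
$(b_{1i}, b_{2i}) \sim N(0, D)$ with free $2 \times 2$ covariance $D$. The
shared model is the boundary case $D = \sigma^2 J$ (perfect correlation with
equal variances), which the likelihood code reproduces exactly — a property
the test suite asserts.

**Co-occurrence multinomial.** The pair is recoded as one four-category
outcome: 0 = neither event (reference), 1 = both, 2 = death only, 3 = preterm
only. A mixed multinomial logit with linear predictors
$\eta_{ic} = \beta_c^\top X_i + z_c^\top b_i$ is fitted with either one scalar
random intercept shared across the three non-reference logits, or three
separate, correlated intercepts with full $3 \times 3$ covariance. The
reference category's predictor is identically zero.

Maximum likelihood uses $\theta = (\beta, \psi)$, with $\psi$ the
log-Cholesky encoding of the covariance (log standard deviations on the
diagonal, free off-diagonal entries), so the optimizer works on an
unconstrained space and every iterate decodes to a valid covariance.

## Numerical strategy

Each mother contributes $\log \int \exp\{g_i(b)\}\,\phi(b; 0, D)\,db$ with
$g_i$ her conditional log-likelihood. The integral is standardized to
$u$-space via $b = Lu$ ($D = LL^\top$) and evaluated by Gauss–Hermite
quadrature, adaptively recentred per cluster:

* the posterior mode of $u$ maximizes $h_i(u) = g_i(Lu) - \|u\|^2/2$, found by
  a safeguarded Newton iteration run on all clusters simultaneously
  (tolerance $10^{-8}$ on the gradient, at most 50 steps, step halving on
  overshoot). The curvature $L^\top W L + I$ is positive definite by
  construction, so the recentring never needs a fallback;
* nodes are shifted to the mode and scaled by the inverse Cholesky factor of
  the curvature; weights are adjusted by the Jacobian and density ratio and
  accumulated in log space (log-sum-exp), so large clusters cannot underflow;
* the default is 10 points per dimension, the order typically used for such
  fits. Correlated structures use the full tensor grid ($10^d$ nodes);
  `quad_points` is exposed because the three-dimensional multinomial grid is
  the one place where a lower order (4–5 points per dimension, still adaptive)
  buys a large constant-factor speedup at negligible accuracy cost. The test
  suite checks the adaptive likelihood against dense-grid integration (up to
  $41^3$ trapezoid nodes over $\pm 8$ SD) to within $10^{-5}$ relative error
  on randomized small clusters.

The outer fitting loop alternates refreshing the per-cluster modes with an
inner BFGS maximization of the fixed-node likelihood, for which the analytic
score is exact; convergence is declared when the refreshed log-likelihood
changes by less than $10^{-8}$ (relative). Fixed effects initialize from
outcome-wise (or category-wise) ordinary logistic fits and log-SDs at
$\log 0.3$; there are no random restarts, so a fit is a deterministic function
of data and options.

Inference follows standard likelihood theory: the model-based covariance is
the inverse observed information, computed by central finite differences of
the log-likelihood (relative step $10^{-5}$, Richardson option available).
The cluster-robust alternative is the sandwich $A^{-1} B A^{-1}$ with $B$ the
sum of per-mother score outer products (per-cluster finite differences) and a
$G/(G-1)$ small-sample factor — the standard construction for exchangeable
within-mother correlation with a robust variance estimator. BIC is
$-2\ell + p \log N$ with $N$ the number of delivery records in the fit; the
cluster-count convention is a documented alternative, and BIC for
random-effects structures should be read with the usual caution that
conditional information criteria would be preferable but are not implemented
here.

### Missing outcomes

Gestational age (hence the preterm indicator) is missing far more often than
perinatal status, so the two outcomes have different complete-case
denominators. In the bivariate models a delivery missing one outcome
contributes only the observed outcome's Bernoulli factor inside its mother's
integral; `complete_case = TRUE` switches to strict complete-case. The
multinomial models are complete-case on the co-occurrence category by
construction, since the category is undefined when either component is
missing.

## The synthetic registry generator

The real registry this methodology targets is restricted, so the package
ships a generator whose defaults emulate that setting: roughly 1.34
deliveries per mother on support 1–4 (matching 60,840 deliveries from 45,324
mothers), covariate marginals near the published distribution (inadequate ANC
31%, referral 24%, pre-eclampsia 4%), outcome marginals near 12.8% and 4.3%,
a mother-level variance of 0.18, calendar years 2000–2017 with a linear
logit-scale trend, and missingness of 12% (gestational age) and 0.3%
(perinatal status). True coefficients are round presets in the direction of
published registry effects (for example, a strong positive inadequate-ANC
effect on preterm birth); they are deliberately not anyone's estimates.

Covariates are drawn independently of each other and of the random effect:
the fitted models condition on $X$, so independence suffices for
parameter-recovery testing; `covariate_sampler` accepts a user-supplied joint
sampler for realism studies. The single seed drives one stream in a fixed
draw order (cluster sizes, random effects, years, outcome uniforms,
missingness, gestational-age noise, covariates last), so adding a covariate
never reshuffles outcomes. A gestational age consistent with the preterm
indicator is synthesized (uniform on 27–36.9 weeks for preterm, 37–42.5
otherwise) so records survive schema validation and CSV round-trips; it is
plumbing, not a model of gestational-age biology. Likewise the generator does
not model covariate evolution across a mother's pregnancies or gestational
age as a survival process — passing tests say the estimator recovers the
assumed data-generating process, not that real registries satisfy it.

A companion generator, `simulate_cooccurrence_registry()`, draws the
four-category outcome directly from the mixed multinomial logit; it exists so
model-comparison studies can simulate under exactly the model being compared.

## Study designs used in the validation suite

Problem sizes were chosen so each study is informative yet runs comfortably
on one CPU:

* **Parameter recovery.** 20 replicates of 2,000 mothers (up to 3 deliveries
  each, $\sigma^2 = 0.5$), with one Bernoulli(0.5) exposure and two
  standard-normal null covariates and outcome intercepts $-1.9$ and $-2.0$.
  Continuous covariates and non-rare outcomes give the per-replicate
  precision needed for the mean-bias bound (0.05) to be a sharp test of
  estimator bias rather than of Monte-Carlo noise; 95% Wald intervals on the
  null coefficients are checked for at-least-90% empirical coverage.
* **Model comparison.** 10 replicates of 2,000 mothers simulated from the
  shared multinomial model ($\sigma^2 = 0.3$, one binary covariate); shared
  and separate-correlated variants are fitted and BIC must prefer the
  generating structure in at least 8. The separate fit is warm-started from
  the nested shared optimum and run at 4 quadrature points per dimension;
  because the truth sits at the singular boundary $D = \sigma^2 J$ of the
  larger model, its optimizer can legitimately hit the iteration cap while
  the likelihood is flat — the suite therefore also asserts the nested-model
  inequality $\ell_{\text{sep}} \ge \ell_{\text{shared}} - 0.5$ so an
  under-fitted alternative cannot fake a BIC win.

## Descriptive layer

`proportion_table()` reproduces the stratified table style of registry
reports: complete-case within each outcome, a category with a missing
stratifier counts toward the grand total but not the test, and the Pearson
chi-square is computed without continuity correction (tables are
large-sample; a flag enables it). The chi-square deliberately ignores
mother-level clustering, exactly as the descriptive layer of such analyses
does — the model layer is where clustering belongs. `annual_trend()` regresses
unweighted per-year percentages on calendar year by OLS, reporting the slope
in percentage points per year with a normal-theory 95% CI
($z = \Phi^{-1}(0.975) = 1.959964$, printed at two decimals); slope magnitudes
in the published literature (0.33, 0.11 per year) imply the percentage scale,
and that is the scale implemented.

The maternal-age code book carries two partitions, because descriptive tables
in this literature bin 25–34 together while model tables use 25–29 as the
reference; neither is asserted as canonical and both validate.

## Degenerate inputs and edge cases

* $\sigma^2 \to 0$ (encoded log-SD $\approx -20$): every joint likelihood
  reduces to its independent fixed-effects counterpart to $10^{-8}$.
* A co-occurrence factor with only two observed categories collapses to a
  binary logit; a factor column may declare unobserved levels for evaluation
  on tiny clusters.
* Encoding a singular $D$ (e.g. $\sigma^2 J$) adds $10^{-10}$ jitter on the
  diagonal before the Cholesky; the likelihood effect is below $10^{-6}$.
* Fits that exhaust the iteration caps are returned flagged, never silently;
  coefficient magnitudes above 15 trigger a separation warning naming the
  term; exact ties in BIC break to the first model in input order.

## Known limitations

Stepwise covariate reduction, multiple imputation, conditional AIC,
likelihood-ratio tests on the variance boundary, random slopes, sparse-grid
quadrature and dimensions above three are out of scope. BIC comparisons
inherit the usual caveat for clustered data noted above. The chi-square layer
is intentionally naive to clustering. Synthetic-data realism is limited to the
structural features listed above.
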
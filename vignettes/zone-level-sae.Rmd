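---
title: "Hierarchical-Bayes small area estimation of zone-level proportions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical-Bayes small area estimation of zone-level proportions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zonesae)
```

## The problem

National household surveys such as the Demographic and Health Surveys are
designed to deliver reliable estimates at national and regional level.
Administrative zones — the layer below regions — are *unplanned domains*:
their survey sample sizes range from a couple of dozen households down to
zero, so the design-based direct estimator of a zone-level proportion (here,
enrolment in community-based health insurance, CBHI) is either very noisy
or simply unavailable. Small area estimation (SAE) repairs this by linking
the zones through census auxiliary information and "borrowing strength"
across areas.

`zonesae` implements the full area-level pipeline for a binary indicator:

1. design-based direct estimation per zone,
2. generalized variance function (GVF) smoothing of the design variances,
3. hierarchical-Bayes (HB) fitting of the Fay–Herriot model under three
   linking models (identity, log, logit) by MCMC,
4. DIC model comparison,
5. synthetic (posterior-predictive) estimation for non-sampled zones, and
6. the standard diagnostic battery: bias-diagnostic regression, residual
   normality, CV comparison with efficiency gains.

Because the motivating microdata (DHS recode files and census samples) are
access-restricted, the package ships a synthetic-data generator that
reproduces the *statistical structure* of those inputs, so every stage is
testable end to end.

## The model

Write $p_i$ for the direct survey proportion of area $i = 1, \dots, m$ and
$\theta_i$ for the true area proportion. All three model variants share
the **sampling model**

$$ p_i \mid \theta_i \sim N(\theta_i, \psi_i), $$

with $\psi_i$ the (assumed known) sampling variance, and differ only in
the **linking model**

$$ g(\theta_i) \mid \beta, \sigma^2_\nu \sim
   N(x_i^\top \beta, \sigma^2_\nu), $$

with $g$ the identity (the classical matched Fay–Herriot model), the log,
or the logit. The logit link is the natural choice for proportions: it
keeps $\theta_i \in (0,1)$ by construction. The covariates $x_i$ are
area-level census shares (an intercept plus $p$ proportions in $[0,1]$).

Priors follow the standard non-informative HB setup for this model class:
$f(\beta) \propto 1$ and $\sigma^2_\nu \sim \mathrm{Uniform}(0,
\mathrm{upper})$ *on the variance scale*, with `upper = 1` by default.
The bound is configurable (`prior_spec(upper = )`) because logit-scale
variances above 1 are plausible in very heterogeneous applications; with
the default generator settings the posterior stays well inside the bound.

### Direct estimates and the continuity correction

For sampled areas, $p_i = y_i / n_i$ with design variance $\psi_i =
\tilde p_i (1 - \tilde p_i) / n_i$ and percent CV $100\sqrt{\psi_i} /
\tilde p_i$. Boundary cells ($y_i \in \{0, n_i\}$) would give $\psi_i = 0$
and an infinite $\log$ downstream, so they are replaced by
$\tilde p_i = (y_i + 0.5)/(n_i + 1)$ *before* variances and CVs are
formed, and flagged in the output. The realized sample size $n_i$ — not
the area population size $N_i$ — is the variance denominator: $\psi_i$ is
the sampling variance of a survey proportion, and with $N_i$ in the tens
of thousands the variances would be vacuously near zero and the whole
smoothing/shrinkage machinery pointless.

### The GVF

Raw $\psi_i$ at $n_i$ of a few dozen are themselves noisy. The GVF
regresses $\log \psi_i$ on $\log \tilde p_i$ by OLS,

$$ \log \psi_i = \beta_0 + \beta_1 \log \tilde p_i + e_i, \qquad
   e_i \sim N(0, \sigma^2), $$

and back-transforms with the smearing factor:

$$ \widehat{\mathrm{GVF}}_i =
   e^{\hat\sigma^2 / 2}\, e^{\hat\beta_0 + \hat\beta_1 \log \tilde p_i}. $$

$\hat\sigma^2$ uses the residual-degrees-of-freedom divisor $n - 2$ (the
unbiased OLS convention). On a perfect log-linear relation the smearing
factor is 1 and the smoothed variances equal the raw ones exactly — a
useful exactness check that the tests exploit. The smoothed variances are
the default input to the HB stage (`select_variance(mode = "gvf")`);
`mode = "raw"` is retained for comparison, since which of the two the
motivating analysis fed its HB stage is not documented.

### The sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler on
$(\beta, \sigma^2_\nu, \mu_1, \dots, \mu_m)$ with $\mu_i = g(\theta_i)$:

* **$\beta$** — exact Gaussian full conditional. With a flat prior and
  equal linking variances, $\beta \mid \mu, \sigma^2_\nu \sim
  N\!\big((X^\top X)^{-1} X^\top \mu,\; \sigma^2_\nu (X^\top X)^{-1}\big)$.
* **$\mu_i$** — per-area random-walk Metropolis on the link scale. Given
  $(\beta, \sigma^2_\nu)$ the $\mu_i$ are conditionally independent, so
  all areas are proposed and accepted/rejected in one vectorized step.
  Proposal scales adapt during burn-in only (a Robbins–Monro drive toward
  0.44 acceptance, the scalar random-walk optimum) and are frozen
  afterwards, so the retained draws target the exact posterior.
* **$\sigma^2_\nu$** — the full conditional under the Uniform prior is an
  inverse-gamma shape truncated to $(0, \mathrm{upper})$; it is drawn by
  inverse-CDF in the precision parameterization (`qgamma` on a uniform
  restricted to the truncation region), which is exact and rejection-free.

Initialization: $\beta$ from the OLS fit of $g(\tilde p_i)$ on $x_i$,
$\mu_i = g(\tilde p_i)$, $\sigma^2_\nu$ at half the prior bound. Defaults
are 50,000 iterations, 5,000 burn-in, two chains with seeds derived
deterministically from one top-level seed. The unit and acceptance tests
run 1,500–22,000 iterations; at these problem sizes (under 100 areas) the
split-chain $\hat R$ of every coefficient is below 1.05 from a few
thousand iterations on, and an identity-link run with $\sigma^2_\nu$
fixed reproduces the closed-form GLS posterior of $\beta$ to Monte-Carlo
accuracy — the strongest correctness check available, since that special
case is exactly linear-Gaussian.

### DIC

Model comparison uses the deviance of the sampling model only,
$D(\theta) = -2 \sum_i \log N(p_i; \theta_i, \psi_i)$, with
$\bar D$ the posterior mean deviance, $\hat D$ the deviance at the
posterior mean of $\theta$ *on the proportion scale* (the scale the
deviance is defined on; a link-scale plug-in is the documented
alternative), $p_D = \bar D - \hat D$ and
$\mathrm{DIC} = \bar D + p_D = 2\bar D - \hat D$. The identity holds
exactly for every fit, by construction and by test.

A caution the simulations make quantitative: on data generated from the
logit linking model at the default scenario, the between-link DIC gaps
are only one or two units — the same order as the published three-model
comparison, where the spread over 77 zones is about three DIC units.
Link selection by DIC at this information level is directional, not
decisive; the acceptance suite checks a majority vote over 20 replicates
at a 20,000-iteration budget (Monte-Carlo noise in DIC must be pushed
well below the gap, or the vote degenerates toward a coin flip).

### Non-sampled areas

For an area with $n_i = 0$ there is no sampling model, only the linking
model. For each retained draw $(\beta^{(t)}, \sigma^{2(t)}_\nu)$ the
package draws a fresh area effect $\nu^* \sim N(0, \sigma^{2(t)}_\nu)$
and records $\theta^* = g^{-1}(x^\top \beta^{(t)} + \nu^*)$. The spread
of these posterior-predictive draws combines parameter and area-effect
uncertainty; omitting $\nu^*$ (i.e., reporting the synthetic mean alone)
would understate the CVs of non-sampled areas, which are reported
non-zero in this literature. A direct consequence, verified in the tests:
a non-sampled area sharing covariates with a sampled one always has
predictive SD at least as large as that area's posterior SD.

### Diagnostics

* **Bias diagnostic** — OLS of the direct estimates on the HB estimates;
  slope near 1 and intercept near 0 indicate the model-based estimates
  are consistent with the design-unbiased ones.
* **Residual normality** — $r_i = g(\hat\theta_i) - x_i^\top \hat\beta$
  at posterior means, Shapiro–Wilk test plus Q-Q coordinates.
* **CV comparison** — six location statistics (Minimum, 1st quartile,
  Median, Mean, 3rd quartile, Maximum) of the percent CVs of direct and
  HB estimates, with the efficiency gain
  $100(\mathrm{direct} - \mathrm{HB})/\mathrm{direct}$ applied *row-wise
  to the summary cells*. That row-wise convention is reverse-engineered
  from the published CBHI table shipped as `cbhi_cv_summary()`: its
  Median, Mean, 3rd-quartile and Maximum gains reproduce to the printed
  two decimals. Its Minimum row does not follow from its own CV cells
  under any convention we could find (the printed −6.03 against a
  computed −0.04), so that row is treated as unexplained rather than as
  ground truth. A per-area gain alternative is available via
  `per_area = TRUE`. Quartiles use linear interpolation between order
  statistics (R's default type 7) throughout.

## The synthetic-data generator

`emdhs_config()` fixes the default scenario to the scale of the
motivating analysis: $m = 83$ zones of which 6 are non-sampled, zone
sample sizes integer-uniform on $[15, 120]$, $p = 8$ auxiliary covariates
drawn i.i.d. uniform on $[0,1]$ and centered (matching the eight selected
census shares of the motivating analysis, and keeping the intercept
interpretable), a logit link with $\sigma^2_\nu = 0.3243$ (the fitted
area-effect variance reported for the CBHI analysis), and coefficients
placed so mean coverage is near the 28% national figure. The zone-level
sample-size distribution of the real survey is not published; the
integer-uniform rule is a stand-in, not a claim about the survey.

The generator draws $\nu_i \sim N(0, \sigma^2_\nu)$, sets $P_i =
g^{-1}(x_i^\top \beta + \nu_i)$ and $y_i \sim \mathrm{Binomial}(n_i,
P_i)$. Under the log or identity links a drawn linear predictor can leave
$(0,1)$; the generator then *fails listing the offending areas* instead of
truncating — silent truncation would corrupt parameter-recovery tests.

What it deliberately does **not** emulate: the two-stage cluster design
and survey weights (areas are simple random samples, as the area-level
model itself assumes), spatial correlation between zones, covariate
correlation structure, and the twelve-year gap between census and survey.
Passing tests therefore demonstrate correctness of the *method under its
own assumptions*, not robustness to design effects the model ignores.

## Calibration findings the tests encode

Two empirical facts about this model class, established with the package
itself and frozen into the expectations of the test suite:

* **Coverage** — 95% credible intervals for each $\beta$ component cover
  the generating values in roughly 90–97% of replicates at the default
  scenario (100 replicates, 5,000 iterations each). Recovery is assessed
  with the generator's true sampling variances $P_i(1-P_i)/n_i$: the
  Fay–Herriot model treats $\psi_i$ as known, and feeding estimated raw
  variances confounds recovery of $(\beta, \sigma^2_\nu)$ with variance
  estimation error.
* **The posterior mean of $\sigma^2_\nu$ is not an unbiased point
  estimator** at this information level. With $n_i \sim U[15,120]$ the
  link-scale measurement noise is comparable to $\sigma_\nu$, the
  posterior of $\sigma^2_\nu$ is strongly right-skewed, and its mean sits
  a few hundredths above the generating 0.3243 on average (≈ 0.36–0.42
  across replicate blocks; an independent Gibbs implementation of the
  same model reproduces our posterior draw for draw, so this is a
  property of the posterior, not of the sampler). The acceptance suite
  asserts the strict unbiasedness reading anyway and is allowed to fail
  there; the honest summary is "consistent with the truth given replicate
  spread, biased upward as a point estimator".

## Numerical choices, in one place

| Choice | Value | Why |
|---|---|---|
| Continuity correction | $(y+0.5)/(n+1)$, boundary cells only | finite logs for the GVF; flagged in output |
| $\psi_i$ denominator | realized $n_i$ | sampling variance of a survey proportion |
| GVF $\hat\sigma^2$ divisor | $n-2$ | unbiased OLS convention |
| Prior on $\sigma^2_\nu$ | Uniform(0, 1) on the variance | standard non-informative HB default for this model |
| Proposal adaptation | burn-in only, target 0.44 | preserves detailed balance after freezing |
| $\sigma^2_\nu$ update | truncated inverse-gamma, inverse-CDF | exact, rejection-free |
| DIC plug-in | posterior mean of $\theta$, proportion scale | the deviance is defined on that scale |
| Credible intervals | equal-tailed 2.5%/97.5% empirical quantiles | matches the significance convention (interval excludes 0) |
| Quantiles in summaries | type 7 (linear interpolation) | mainstream default, fixed for reproducibility |
| Sub-seeds | affine map of the top-level seed | bitwise reproducibility across stages and chains |

## Known limitations

* CVs of direct estimates are unstable for very small $\tilde p_i$; the
  GVF mitigates but does not remove this.
* DIC as implemented (sampling-model deviance, $\theta$-scale plug-in)
  discriminates weakly between linking models — see above.
* The posterior mean of $\sigma^2_\nu$ is upward-skewed at realistic
  information levels; report the full posterior, not the mean alone.
* No design weights, no spatial or temporal extensions, no benchmarking
  of zone estimates to regional totals.

## A complete run

```{r, eval = FALSE}
sim <- simulate_areas(emdhs_config(seed = 1))
res <- run_pipeline(sim$table, link = "all",
                    config = mcmc_config(n_iter = 20000, burn_in = 2000,
                                         n_chains = 2, seed = 1),
                    out_dir = "results/run1")
res$dic                    # three links ranked by DIC
head(res$estimates)        # all 83 zones, sampled and predicted
res$diagnostics$cv_table   # efficiency of HB over direct
```

The numbered scripts under `analysis/` run the same stages one at a time
with a fixed seed and narrate what they find.
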
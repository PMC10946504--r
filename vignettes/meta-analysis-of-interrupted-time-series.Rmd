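---
title: "Evaluating meta-analysis methods for interrupted time series studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating meta-analysis methods for interrupted time series studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An interrupted time series (ITS) study measures an outcome repeatedly before
and after an interruption — a policy change, an exposure, a natural
experiment — and asks what the interruption did to the level and the trend of
the series. When several ITS studies address the same question, their effect
estimates are combined by meta-analysis, and the conclusions of such
syntheses feed public-health and policy decisions. Two methodological layers
interact in that pipeline: the statistical method used to analyse each
series, and the meta-analysis method used to combine the study-level
estimates. `metaits` implements both layers and a Monte Carlo framework for
studying how they interact.

## The data model

Each series follows a segmented linear regression with a single
interruption at time $T_I$:

$$Y_t = \beta_0 + \beta_1 t + \beta_2 D_t + \beta_3 (t - T_I) D_t + e_t,
\qquad t = 1, \dots, T,$$

where $D_t = 1$ for $t \ge T_I$ and 0 before. $\beta_2$ is the immediate
level-change and $\beta_3$ the slope-change — the two interruption effects
of interest. The errors are a stationary AR(1) process,
$e_t = \rho e_{t-1} + w_t$ with $w_t \sim N(0, 1)$ i.i.d., so consecutive
points are correlated with lag-1 autocorrelation $\rho \in (-1, 1)$.

Between-study heterogeneity enters at the level of the true effects: study
$k$ in a meta-analysis has effects $\beta_{2k} = \beta_2 + \delta_{2k}$ and
$\beta_{3k} = \beta_3 + \delta_{3k}$ with
$\delta_{2k} \sim N(0, \tau^2_2)$ and $\delta_{3k} \sim N(0, \tau^2_3)$.
Setting both $\tau^2$ to zero generates under a fixed-effect (common-effect)
model.

Two generator choices deserve note:

* **Initial error state.** $e_1$ is drawn from the stationary distribution
  $N(0, 1/(1-\rho^2))$ rather than started at zero with a burn-in. The two
  are equivalent in distribution, but the stationary start removes start-up
  transients exactly, which matters for the 12-point series in the design.
* **Interruption indexing.** With $D_t = 1$ for $t \ge T_I$, the default
  $T_I = T/2 + 1$ puts exactly $T/2$ points in each segment. An equal
  pre/post split and "interruption at $T/2$" cannot both hold under this
  indicator convention; we prioritise the balanced split, which is the
  property the fitting methods are sensitive to.
* **Variable autocorrelation.** Besides fixed $\rho$ shared by all studies
  in a meta-analysis, a "variable" mode draws each study's $\rho$
  independently from $N(0.4, 0.15^2)$, resampling any draw outside
  $(-1, 1)$. The mean and spread are chosen to represent the magnitudes
  reported in surveys of real ITS data sets, where most estimated lag-1
  autocorrelations fall between roughly 0 and 0.6.

## Study-level estimation

Three estimators of the segmented regression are provided, and a cascade
that mirrors what a careful analyst does when the preferred method fails:

* `fit_ols()` — ordinary least squares. Unbiased for the coefficients even
  under autocorrelation, but its standard errors assume independent errors
  and are too small when $\rho > 0$.
* `fit_pw()` — Prais–Winsten iterative generalised least squares. Estimates
  $\rho$ from the residuals by the lag-1 moment estimator
  $r = \sum_{t \ge 2} \hat e_t \hat e_{t-1} / \sum \hat e_t^2$, whitens the
  data (first observation scaled by $\sqrt{1-\hat\rho^2}$, the rest
  quasi-differenced), refits, and iterates until $\hat\rho$ moves by less
  than $10^{-6}$ (cap 100 iterations). Standard errors come from the
  whitened regression.
* `fit_reml()` — restricted maximum likelihood for the linear model with
  AR(1) errors. The restricted likelihood is profiled over $\rho$: at each
  candidate value the GLS coefficients and the innovation variance have
  closed forms through the same whitening transform, leaving a
  one-dimensional minimisation of
  $(T-4)\log\hat\sigma^2 - \log(1-\rho^2) + \log|X_*'X_*|$
  over $\rho \in (-0.999, 0.999)$. A coarse scan (step 0.05, endpoints
  included) brackets the optimum before golden-section refinement, because
  the profile can be multimodal for short series. A fit is declared
  non-converged when the optimum sits at the $\rho$ boundary (within
  $10^{-4}$) or the objective is non-finite.
* `fit_cascade()` — REML, then Prais–Winsten if REML did not converge, then
  OLS (which cannot fail on an estimable design). The returned object
  records which method was used.

REML standard errors are the GLS standard errors at the REML estimates,
with no small-sample degrees-of-freedom correction: only the point estimate
and SE feed the meta-analysis stage, and the degrees-of-freedom adjustment
question belongs to single-study inference, which is not the target here.
The OLS residual variance uses the conventional unbiased denominator
$T - 4$.

Non-convergence of the profile REML is a boundary event rather than an
iteration failure, so its frequency is implementation-specific; what is
reproducible — and verified in the test suite — is the ordering: failures
concentrate heavily at $T = 12$ and essentially vanish by $T = 100$, and
Prais–Winsten converges on the fallback series.

## Meta-analysis

The second stage is standard two-stage univariate meta-analysis with the
within-study variances treated as known. Five method combinations are
implemented, the ones a practitioner is most likely to meet:

| Combination | Weights | $\tau^2$ | Interval |
|---|---|---|---|
| Fixed | $1/\sigma^2_k$ | — | Wald (normal) |
| DL+WT | $1/(\sigma^2_k+\hat\tau^2)$ | DerSimonian–Laird | Wald (normal) |
| DL+HKSJ | $1/(\sigma^2_k+\hat\tau^2)$ | DerSimonian–Laird | Hartung–Knapp/Sidik–Jonkman ($t_{K-1}$) |
| REML+WT | $1/(\sigma^2_k+\hat\tau^2)$ | iterative REML | Wald (normal) |
| REML+HKSJ | $1/(\sigma^2_k+\hat\tau^2)$ | iterative REML | Hartung–Knapp/Sidik–Jonkman ($t_{K-1}$) |

The DL estimator is the moment estimator from Cochran's $Q$, truncated at
zero. The REML estimator iterates
$\hat\tau^2 \leftarrow \max\!\big(0,\,
\sum W_k^2\{(y_k-\hat\mu)^2 - \sigma^2_k\}/\sum W_k^2 + 1/\sum W_k\big)$
with random-effects weights recomputed each pass, started from the
maximum-likelihood estimate (itself started at DL, capped at 20
iterations), and stops when successive values differ by less than
$10^{-8}$ (cap 100; hitting the cap flags non-convergence, which is
surfaced, never silently replaced — the simulation summaries exclude and
count such replicates).

The HKSJ variance rescaling $q = \sum W_k (y_k - \hat\mu)^2/(K-1)$ is used
**untruncated**, exactly as originally derived. The common "modified HKSJ"
($q \leftarrow \max(1, q)$) is deliberately not applied; the price is the
documented degeneracy that a meta-analysis of identical estimates yields a
zero-width interval.

Both estimators and the intervals are validated in the test suite against
`metafor` (an independent implementation) and against exhaustive
grid searches of the restricted likelihood — the package never calls
`metafor` in its own code paths.

## The simulation framework

`grid_config()` enumerates a fully factorial design; the defaults reproduce
the evaluation grid of 1620 scenarios: $T \in \{12, 48, 100\}$, $\rho \in
\{0, 0.2, 0.4, 0.6, \text{variable}\}$, $\beta_2 \in \{0, 1\}$, $\beta_3
\in \{0, 0.1\}$, $K \in \{3, 5, 20\}$, $\tau^2_2 \in \{0, 0.1^2, 0.3^2\}$,
$\tau^2_3 \in \{0, 0.01^2, 0.05^2\}$, with 1000 replicates per scenario and
$\beta_0 = \beta_1 = 0$ (performance of the methods does not depend on the
baseline level and trend, and location equivariance of all three fitters is
a tested property).

Each replicate draws one meta-analysis sample, analyses every study twice —
once with plain OLS and once with the REML cascade, on the *same* data, so
arm comparisons are paired — and applies all five meta-analysis methods to
both effect measures. Seeding is per (scenario, replicate) through a
Lehmer-style mix of the base seed, so results are independent of execution
order and safely parallelisable, and reruns are bit-for-bit identical.

`summarize_performance()` computes the usual simulation performance
measures: bias, empirical SE (SD of pooled estimates), model-based SE (root
mean square of the model SEs), their ratio, 95% CI coverage of the true
mean effect, the percentage of intervals excluding zero (power, or type I
error when the true effect is zero), and $\tau^2$ summaries, each with its
Monte Carlo standard error (binomial formula for percentages,
$\text{empSE}/\sqrt{n}$ for bias). Under random-effects generation the
coverage target is the mean of the effect distribution, not the replicate's
realised study effects — the estimand of a random-effects meta-analysis.
With 1000 replicates the MCSE of a 95% coverage estimate is
$\sqrt{95 \cdot 5/1000} \approx 0.69$ percentage points, which is why that
replicate count is the default.

### Problem sizes used by the shipped checks

The full 1620-scenario, 1000-replicate grid is a cluster-scale computation.
The package's own verification uses deliberately scaled-down designs,
chosen so each Monte Carlo check resolves the effect it targets:

* the 45-scenario no-heterogeneity sweep (`run_tau2_sweep()`) at 200
  replicates per scenario for $K = 3$ and 100 for $K = 20$ — the pooled
  percentage of replicates with $\hat\tau^2_2 > 0$ has MCSE well under one
  percentage point at these sizes;
* single-scenario bias/coverage checks at 500 replicates;
* the large-sample consistency check (`run_sanity()`) at $T = 10^5$,
  $K = 50$, averaged over 20 replicate meta-samples. The averaging is
  needed for the between-study variance: one 50-study sample estimates
  $\tau^2$ with relative error around $\sqrt{2/49} \approx 20\%$, so a
  single sample cannot verify 10%-level agreement; the mean of 20 can.

### What the generator does and does not emulate

The generator reproduces the design space of the evaluation: continuous
outcomes, equal pre/post segments, a common baseline across studies within
a meta-analysis, lag-1 autocorrelation only, and normal between-study
effect distributions. Real ITS meta-analyses routinely violate several of
these — count or rate outcomes, unequal and unbalanced series, seasonality,
higher-order correlation, studies analysed by different methods. Passing
the shipped checks therefore demonstrates correctness of the machinery and
reproduction of the published behaviour *within* this design space, not
robustness beyond it.

## Worked example

The packaged data set `traffic_fatality_estimates()` carries the published
state-level segmented-regression estimates (OLS and REML, with SEs, plus
the REML autocorrelation estimates) of the effect of legalising
recreational cannabis sales on monthly traffic fatality rates in 11 US
states, 96 monthly points per series. `fatality_meta_example()` pools them
with all five methods for both effect measures:

```{r example}
library(metaits)
ex <- fatality_meta_example()
subset(ex, its_method == "OLS" & effect == "level")
```

The reproduced values match the published meta-analysis to within the
rounding of the two-decimal inputs (about $\pm 0.01$ on estimates and
interval limits, $\pm 0.003$ on $\tau^2$). The qualitative pattern is
exact: DL estimates no heterogeneity in any of the four input sets, REML a
trace ($\approx 0.0065$) for the OLS level-change set only; HKSJ intervals
are wider than Wald for the OLS-analysed level-changes but narrower for
the REML-analysed ones.

## Known limitations

* The REML non-convergence *rate* is defined by the boundary criterion of
  this implementation and need not match rates reported from other
  software; only the qualitative dependence on series length is a stable
  target.
* One-stage (individual-data) meta-analysis, bivariate joint pooling of
  level- and slope-change, ARIMA study-level models, prediction intervals,
  and $\tau^2$ estimators or interval methods beyond the five combinations
  are out of scope.
* At design points where study-level SEs are underestimated (short series,
  or OLS in the presence of autocorrelation), Wald-type random-effects
  coverage runs one to two percentage points below nominal even at
  $K = 20$; the HKSJ variants sit closer to 95%. This is a property of the
  methods, reproduced — not corrected — by the package.
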
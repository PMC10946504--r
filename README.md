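# metaits

Two-stage meta-analysis of interrupted time series (ITS) studies, and a
Monte Carlo framework for evaluating how study-level estimation and
meta-analytic pooling interact.

ITS studies measure an outcome repeatedly before and after an interruption
(a policy change, an exposure) and estimate its impact from a segmented
linear regression

> Y_t = β₀ + β₁·t + β₂·D_t + β₃·(t − T_I)·D_t + e_t,  e_t = ρ·e_{t−1} + w_t,

where D_t indicates the post-interruption period, β₂ is the immediate
level-change, β₃ the slope-change, and the errors carry lag-1 (AR(1))
autocorrelation ρ. Estimates from several such studies are combined by
inverse-variance meta-analysis. The catch: study-level standard errors are
systematically underestimated for short series or when the analysis ignores
autocorrelation, and that bias propagates into the meta-analysis — deflating
fixed-effect interval coverage and inflating estimated between-study
heterogeneity. `metaits` implements the full pipeline so those interactions
can be quantified:

* **Data generation** — segmented-regression series with stationary AR(1)
  errors, and meta-analytic collections with normal between-study
  heterogeneity in both interruption effects (`generate_its_series()`,
  `generate_meta_sample()`).
* **Study-level fitting** — OLS, iterative Prais–Winsten, and profile-REML
  for the AR(1) model, plus the REML → PW → OLS fallback cascade
  (`fit_ols()`, `fit_pw()`, `fit_reml()`, `fit_cascade()`).
* **Meta-analysis** — fixed-effect and random-effects pooling with
  DerSimonian–Laird and iterative REML τ² estimators, Wald-type and
  Hartung–Knapp/Sidik–Jonkman intervals (`meta_analyse()` and friends).
* **Simulation engine** — factorial scenario grids (the default reproduces
  the 1620-cell evaluation design), per-replicate reproducible seeding,
  paired analysis arms, performance summaries (bias, coverage, empirical
  and model SE, power) with Monte Carlo standard errors
  (`grid_config()`, `run_grid()`, `summarize_performance()`).
* **Worked example** — the published state-level traffic-fatality estimates
  (11 US states, effect of recreational-cannabis legalisation), pooled by
  all five method combinations (`fatality_meta_example()`).

## Worked example

```r
library(metaits)
ex <- fatality_meta_example()
subset(ex, its_method == "OLS" & effect == "level")
#>   its_method effect meta_method    pooled se_pooled      ci_low   ci_high
#> 1        OLS  level       Fixed 0.2106134 0.1346952 -0.05338429 0.4746110
#> 2        OLS  level       DL+WT 0.2106134 0.1346952 -0.05338429 0.4746110
#> 3        OLS  level     DL+HKSJ 0.2106134 0.1342222 -0.08845243 0.5096792
#> 4        OLS  level     REML+WT 0.2116189 0.1369576 -0.05681296 0.4800508
#> 5        OLS  level   REML+HKSJ 0.2116189 0.1342193 -0.08744038 0.5106782
#>     p_value        tau2
#> 1 0.1179045 0.000000000
#> 2 0.1179045 0.000000000
#> 3 0.1476875 0.000000000
#> 4 0.1223118 0.006520555
#> 5 0.1459512 0.006520555
```

Pooling the 11 OLS level-change estimates gives a combined increase of
about 0.21 traffic fatalities per million residents with a 95% CI spanning
zero; DL finds no between-study heterogeneity (τ̂² = 0, so the fixed and
DL rows coincide), REML a trace (τ̂² ≈ 0.0065), and the HKSJ interval is
wider than the Wald interval for these inputs. A small simulation:

```r
cfg <- grid_config(n_obs = c(12, 100), rho = list(0.6), beta2 = 1,
                   beta3 = 0.1, K = 3, tau2_level = 0, tau2_slope = 0,
                   n_reps = 200, seed = 1)
res <- run_grid(cfg, out_dir = NULL, verbose = FALSE)
subset(res$summary, effect == "level" & meta_method == "Fixed",
       select = c(scenario_id, its_method, coverage, mod_to_emp))
#>    scenario_id its_method coverage mod_to_emp
#> 5        S0001        OLS     83.0  0.6413541
#> 15       S0001       REML     75.5  0.5816946
#> 25       S0002        OLS     67.5  0.5000901
#> 35       S0002       REML     93.0  0.9503208
```

Fixed-effect coverage collapses when autocorrelation is ignored at the
study level (OLS at T = 100: 67.5%) or when the series are too short for
REML to estimate it reliably (T = 12: 75.5%), while REML on long series
restores near-nominal coverage (93%) — exactly the interaction the
framework is built to expose.

A thin command-line front end ships in `inst/cli/metaits`
(subcommands `fit`, `meta`, `example`, `run-grid`, `sanity`).

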
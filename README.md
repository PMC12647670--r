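# descurves

Tools for analysing **taxonomic description curves**: the cumulative number
of validly described species of a taxonomic group plotted against
publication year, from 1753 (the start of modern nomenclature) to a
configurable end year (2017 by default). Description curves condense two
and a half centuries of taxonomic effort into one trajectory per group, and
their shape is informative: groups saturate early or late, grow smoothly or
in bursts, and may be far from complete. `descurves` is aimed at
biodiversity informaticians and macroecologists who want to fit, compare
and explain such curves across many groups at once.

The package covers four connected analyses:

1. **Curve fitting.** A left-sided half-normal cumulative model is fitted
   to each group's `[0,1]`-scaled cumulative series by MCMC:

   D(Y) = (k/(a·√(2π)) + 1) · exp(−½((Y−b)/a)²) for Y ≤ b, and
   D(Y) = k/(a·√(2π)) + 1 for Y > b,

   where `b` is the mean year, `a` the standard deviation (years) and `k`
   the scale parameter. The `+1` term keeps the fitted asymptote at or
   above the observed maximum. Gompertz and von Bertalanffy alternatives
   are included.
2. **Curve parameters.** From each fit: the *initial description time*
   (years since 1753 until the curve reaches 10% of current descriptions),
   the *future descriptions ratio* (fitted asymptote over current
   descriptions; 1.00 means the group is essentially fully described) and
   the *curve residual sum of squares* (a roughness measure, scaled
   units²).
3. **Rate anomalies.** A five-year moving-window rule flags years whose
   description rate collapsed (e.g. the world wars) or surged (landmark
   publications), with suppression of the mechanical rebound signal.
4. **Path model.** A Bayesian structural equation model links societal
   (public interest, author numbers) and biological (body size, habitat,
   range) predictors to the three curve parameters across groups, with a
   residual covariance between initial description time and future
   descriptions ratio, and a posterior predictive p-value (PPP) for fit.

A synthetic-data generator with known ground truth
(`simulate_description_history()`, `simulate_predictor_system()`) makes
every stage testable end to end, and a packaged 47-group predictor and
curve-parameter table (`description_curve_fixture()`) supports the
group-level path analysis out of the box.

## Worked example

Simulate a group of 25,000 species whose description activity peaks around
1995, with a war-time collapse (rates × 0.3 in 1914–1918), then fit the
curve and scan for anomalies:

```r
library(descurves)

h <- simulate_description_history(
  sim_spec("demo", richness_total = 25000, k = 0.5, a = 45, b = 1995,
           noise_sd = 0.005,
           shocks = data.frame(start_year = 1914, length_years = 5,
                               rate_multiplier = 0.3),
           seed = 42)
)

fit <- fit_curve(h, mcmc = mcmc_config(seed = 42))
tidy(fit)
#> # A tibble: 4 × 7
#>   term    estimate std.error   conf.low  conf.high  rhat   ess
#>   <chr>      <dbl>     <dbl>      <dbl>      <dbl> <dbl> <dbl>
#> 1 a       46.7      0.170      46.3       47.0      1.02  212.
#> 2 b     1998.       0.238    1997.      1998.       1.02  180.
#> 3 k        0.287    0.149       0.0294     0.599    1.00  662.
#> 4 sigma    0.00742  0.000319    0.00683    0.00807  1.00 2568.

extract_curve_parameters(fit)
#> # A tibble: 1 × 5
#>   group model      initial_description_time future_descriptions_ratio residual_ss
#>   <chr> <chr>                         <dbl>                     <dbl>       <dbl>
#> 1 demo  halfnormal                      144                      1.00      0.0143
```

The recovered mean year (1998 ± 0.2) and spread (46.7 years) sit next to
the generating truth (1995, 45; the injected shock distorts the curve
slightly). The initial description time of 144 years says the simulated
group needed until the late 1890s to reach 10% of its eventual description
count, and the ratio of 1.00 says the curve has effectively saturated —
few further descriptions are projected. The anomaly scan finds the
injected collapse and its rebound:

```r
dplyr::filter(detect_anomalies(h), label != "none", year >= 1900, year <= 1935)
#> # A tibble: 3 × 5
#>   group  year label pre_mean window_mean
#>   <chr> <int> <chr>    <dbl>       <dbl>
#> 1 demo   1913 low      179          81.4
#> 2 demo   1914 low      185.         58
#> 3 demo   1920 high      92.4       236.
```

(The 1913 call is the forward-looking window already absorbing the 1914
collapse; the 1920 "high" is the recovery.)

The group-level path analysis runs on the packaged 47-group table:

```r
fx <- description_curve_fixture()
scaled <- scale_unit_interval(fx, cols = setdiff(names(fx), "group"))
pf <- fit_path_model(scaled, mcmc = mcmc_config(chains = 4, draws = 2000,
                                                warmup = 2000, seed = 1))
glance(pf)
#> # A tibble: 1 × 7
#>       n   ppp endo_covariance endo_covariance_std   rho max_rhat converged
#>   <int> <dbl>           <dbl>               <dbl> <dbl>    <dbl> <lgl>
#> 1    47 0.479          0.0104               0.204 0.364     1.05 TRUE
```

A PPP near 0.5 indicates the hypothesis graph reproduces the observed
covariance structure well; `endo_covariance_std` is the standardized
residual covariance between initial description time and future
descriptions ratio (groups that started late also tend to hold more
undescribed species, beyond what the shared predictors explain).
`tidy(pf)` returns the full coefficient table and `autoplot(pf)` a forest
plot of the edges.

Whole runs (ingest → curve fits → anomalies → path model → report tables)
are orchestrated by `run_pipeline()` from a `run_config()` or YAML file; a
thin command-line wrapper with per-stage subcommands lives at
`inst/cli/descurves.R`.

## Package layout

* `R/` — simulation (`simulate.R`), ingest and scaling (`ingest.R`), curve
  models and fitting (`curve-functions.R`, `curve-fit.R`), the
  moving-window anomaly rule (`anomalies.R`), the Bayesian path model and
  PPP (`path-model.R`), and the pipeline orchestrator (`pipeline.R`).
* `inst/extdata/tables_2_3_fixture.csv` — the packaged 47-group table.
* `vignettes/description-curves.Rmd` — models, priors, numerical choices
  and design decisions, in detail.
* `tests/testthat/` — unit, property and acceptance tests, built on
  independent brute-force and closed-form oracles.
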
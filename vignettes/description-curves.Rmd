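---
title: "Modelling taxonomic description curves: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling taxonomic description curves: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`descurves` analyses when the species of a taxonomic group were described,
and why groups differ. The data are simple: one dated description record per
species, from 1753 (the starting point of modern nomenclature) to a
configurable end year (2017 by default, giving a 265-year grid with
zero-count years kept explicit). From these the package builds cumulative
description curves, fits a saturating growth model to each, derives three
interpretable curve parameters per group, flags years in which description
rates jumped or collapsed, and fits a Bayesian path model that relates the
curve parameters to biological and societal predictors. This vignette
explains each model, the choices behind the defaults, and what the test
suite does and does not establish.

## The cumulative curve model

Cumulative descriptions of a group must eventually saturate — there is a
finite number of species to describe. The default model is a left-sided
half-normal: with calendar year $Y$,

$$D(Y) \;=\; \Big(\tfrac{k}{a\sqrt{2\pi}} + 1\Big)\,
  \exp\!\Big(-\tfrac12\big(\tfrac{Y-b}{a}\big)^2\Big)
  \quad (Y \le b), \qquad
  D(Y) = \tfrac{k}{a\sqrt{2\pi}} + 1 \quad (Y > b).$$

The curve rises like the left half of a Gaussian bump integrated in place,
reaches its maximum at the mean year $b$, and stays flat afterwards. Two
properties matter. First, the $+1$ in the scale term forces the asymptote to
be at least 1, so on a $[0,1]$-scaled series the fitted maximum can never
undercut the observed maximum; the *future descriptions ratio* (asymptote
divided by the observed current value) is therefore always $\ge 1$. Second,
ratios of pre-saturation values do not depend on $k$ at all — $k$ only moves
the asymptote — which is why the synthetic truth curves below are fully
determined by $(a, b)$ once renormalised.

Two alternative saturating forms, Gompertz
($K e^{-e^{-c(Y-m)}}$) and a von Bertalanffy-type curve
($K\,\max(0, 1-e^{-r(Y-t_0)})$), are provided for comparison. Model choice
is deliberately *not* automated: the half-normal is the default, and the
alternatives are fitted only when asked. The Bertalanffy variant is the
standard von Bertalanffy saturation curve; where external analyses used a
customised variant whose exact form is unpublished, results for that model
should be compared with care.

Fitting is Bayesian (JAGS, 4 chains × 1000 draws after 1000 warm-up
iterations by default), with a Gaussian observation model on the
$[0,1]$-scaled cumulative values. Fitting on the scaled series rather than
raw counts keeps one set of priors sensible for groups whose richness spans
432 to 421,378, and makes residual sums of squares comparable across groups
(they land around $10^{-4}$–$10^{-3}$ in scaled units²). Default priors:

* $b \sim \mathrm{Normal}(1950, 100)$ years — description activity for most
  groups peaks in the 19th–21st centuries;
* $a \sim \mathrm{half\text{-}Normal}(0, 100)$ years;
* $k \sim \mathrm{half\text{-}Cauchy}(0, 10)$ in scaled units;
* $\sigma \sim \mathrm{half\text{-}Normal}(0, 0.1)$ for the observation SD.

The half-Cauchy on $k$ deserves a note. A strongly unsaturated group — one
whose underlying mean year lies decades past the end of the data — needs an
asymptote $k/(a\sqrt{2\pi}) + 1$ that can be orders of magnitude above 1,
i.e. $k$ in the thousands. A light-tailed prior on $k$ would silently cap
the future descriptions ratio; the half-Cauchy keeps the same weak shrinkage
near zero while leaving the tail open. Initial values are data-driven (rough
quantile-based guesses for $a$ and $b$, jittered across chains); convergence
is summarised by split-chain R-hat and any fit with R-hat > 1.1 is flagged
with a warning rather than silently returned.

From the posterior-mean curve, `extract_curve_parameters()` derives:

* **initial description time** — years since 1753 until the fitted curve
  reaches 10% of the observed current (scaled) value, solved in closed form
  on the continuous curve and rounded to an integer (the convention used in
  group-level summary tables);
* **future descriptions ratio** — fitted asymptote over the observed scaled
  current value. The observed value (not the fitted value at the end year)
  is the denominator: it is the quantity the ratio is meant to project from;
* **curve residual SS** — $\sum_{Y} (\text{observed} - \text{fitted})^2$
  over the year grid, in scaled units².

## Description-rate anomalies

A year $t$ is compared through two five-year windows of the raw yearly
counts: the preceding window ($t-5..t-1$) and the focal window ($t..t+4$).
The year is a *low* candidate when the preceding mean is at least double the
focal mean, a *high* candidate when it is less than half. Because every
genuine shock mechanically produces an opposite signal when rates return to
normal, a candidate is suppressed when any of its five preceding years
already carries the opposite label (processing in ascending year order) —
rebound suppression. The suppression window equals the preceding
comparison window; nothing in the verbal rule fixes it more precisely, and
this is the smallest window consistent with "the preceding five years".

Numerical choices: comparisons use window *sums* rather than means, so
threshold boundaries ("at least double") are exact in integer arithmetic;
the thresholds follow the rule's wording literally ($\ge$ on the low side,
$<$ on the high side); a year with both windows all-zero carries no signal
and is unlabelled; zero preceding activity followed by positive activity is
*high* (the inequalities decide this without any division); the first five
and last four grid years are unclassifiable by contract, since both windows
must exist. The rule compares ratios, so labels are invariant to positive
scaling of counts — raw counts are used, and scaling would change nothing.
One consequence worth knowing when reading the output: because the focal
window looks forward, the run of labelled years often starts a few years
*before* a visually obvious break, as soon as the forward window absorbs it.

The suite checks the implementation against an independent brute-force
re-implementation (integer window sums, no shared code) on 1000 random
265-year series, including injected regime changes.

## The path model

The structural model is a fixed, recursive (acyclic) system over ten
observed per-group variables. Exogenous: current descriptions, body-size
class, region-occurrence fraction, soil-dwelling/endoparasitic ordinal,
aquatic ordinal. Endogenous: public interest, mean authors per year, and
the three curve parameters. The twenty directed edges encode the a-priori
hypotheses (e.g. current descriptions drive public interest and author
numbers; accessible regions reduce curve residuals; hidden habitats delay
initial description), and one residual covariance links initial description
time and future descriptions ratio. All variables are min-max scaled to
$[0,1]$ first (`scale_unit_interval()` retains the inverse transform); the
ordinal predictors enter as scaled numeric covariates, consistent with that
blanket scaling, and current descriptions is not log-transformed by default
(only min-max scaling is applied; a user can transform before scaling).

Priors mirror common Bayesian-SEM defaults: Normal(0, 10) on intercepts and
coefficients, half-Cauchy(0, 2.5) on residual SDs, uniform on the residual
correlation of the endogenous pair (the two-dimensional analogue of an LKJ
prior with shape 1). Exogenous variables are conditioned on, not modelled.
Because every variable is observed and the graph is recursive, the joint
likelihood factorises into three univariate regressions plus one bivariate
(seemingly-unrelated) pair, which is exactly how the JAGS model is
generated from the specification object.

**Fit assessment.** The posterior predictive p-value uses the conventional
likelihood-ratio discrepancy for covariance-structure models:
$D(y,\theta) = -2(\ell_{\text{model}} - \ell_{\text{saturated}})$,
conditional on the exogenous block, where the saturated reference is the
unrestricted multivariate regression of the five endogenous variables with
unrestricted residual covariance. For each draw, endogenous data are
replicated from the implied moments and the saturated reference is refitted
to the replicate; the PPP is the fraction of draws where the replicated
discrepancy reaches the observed one. Calibration on self-generated data
(PPP well inside $[0.2, 0.8]$) and power against an omitted strong edge
(PPP $< 0.05$ at $n = 470$) are both part of the suite.

**Reporting the endogenous covariance.** On $[0,1]$-scaled data the raw
residual covariance of the pair is bounded by the residual variances (of
order $10^{-2}$ here), so the interpretable summary is the *standardized*
residual covariance: per posterior draw, the covariance divided by the
model-implied total SDs of the two variables, averaged over draws — the
convention Bayesian-SEM software uses for standardized solutions. The
fitted object carries both (`endo_covariance`, `endo_covariance_std`).
Standardizing instead by the sample SDs of the observed pair, or
standardizing once at the posterior means, gives values a few hundredths
higher; the per-draw model-implied convention was fixed in advance as the
field-standard choice.

## The synthetic generator

`simulate_description_history()` draws yearly counts whose noiseless scaled
cumulative equals a known half-normal truth, renormalised so the final-year
cumulative equals the target richness (mass before 1753 is assigned to the
first grid year). Shocks multiply the expected rate inside their windows —
emulating wars and landmark publications. Noise is applied at the *rate*
level, never to the cumulative directly, so monotonicity is preserved by
construction: each scaled yearly increment receives Gaussian noise with
per-year SD `noise_sd` $/\sqrt{265}$ (so the accumulated random-walk SD at
the final year is `noise_sd`, the natural scale for a quantity quoted in
scaled-cumulative units), rates are truncated at zero, and counts are
Poisson draws around the resulting expectations. With `noise_sd = 0` the
generator switches to deterministic largest-remainder rounding of the
expected cumulative, so the final cumulative equals the target richness
*exactly* — a useful property for invariant tests that a Poisson scheme
cannot provide. The truncation at zero adds a small positive bias in years
whose expected rate is near zero; at the default noise level this is
well under the tolerances used anywhere in the suite.

`simulate_predictor_system()` generates group-level predictor tables from
the path graph with known coefficients: exogenous predictors from
Beta(2, 2) (interior support keeps the min-max scaling non-degenerate),
endogenous variables from the linear equations plus Gaussian residuals,
with a correlated bivariate residual for the endogenous pair and
intercepts chosen to centre each variable near 0.5. Gaussian residuals can
leave $[0,1]$; recovery studies therefore fit with the unit-interval check
disabled rather than re-scaling, because re-scaling by the sample range
would rescale the very coefficients under test.

What the generator does *not* emulate: real taxonomy (no synonymy, no
author-name disambiguation problems, no database duplication), heavy-tailed
or temporally autocorrelated description noise, and any feedback from curve
shape to predictors. Passing recovery tests therefore demonstrates that the
estimators are correct and well calibrated under the stated model, not that
the model is true of any particular database export.

## Problem sizes and runtimes

The suite fits real MCMC throughout, sized to run on a single CPU in
minutes: curve-parameter recovery uses 20 synthetic groups (richness
20,000; noise 0.005; $a \in [20, 80]$, $b \in [1850, 2100]$ — the last
range deliberately includes strongly unsaturated groups, where the future
ratio is an extrapolation and only *median* accuracy across groups is a
meaningful target: median absolute error ≤ 3 years for initial description
time and ≤ 5% for the ratio); path-model recovery and null-calibration use
$n = 470$ (ten times the 47-group table); anomaly checks use 1000 random
265-year series. The 47-group analysis itself takes well under a minute.

## Known limitations

* The per-year reading of "mean unique author names per year" is the
  default; a pooled reading (distinct names over the whole period divided
  by 265) is available via `method = "pooled"`. The two differ whenever
  authors publish in several years.
* Author-name equality is exact string match after trimming and case
  folding; no disambiguation of homonymous taxonomists is attempted.
* The future descriptions ratio of a strongly unsaturated group is an
  extrapolation; its posterior uncertainty (available from the draws) is
  large even when the point estimate is accurate.
* Exact reproduction of published coefficient values from the packaged
  47-group table depends on unreported prior choices in the original
  software; fit quality (PPP) is insensitive to this, standardized
  quantities move by a few hundredths.
* The insect-aggregation variant changes only the input table; the graph is
  fixed by design, so structural sensitivity analyses require editing the
  specification object directly.
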
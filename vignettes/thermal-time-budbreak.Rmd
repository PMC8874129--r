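---
title: "Thermal-time estimation and bud-break simulation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time estimation and bud-break simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budforce)
```

## The model

Dormant floral buds of temperate fruit trees respond to warmth only after
their chilling requirement is satisfied. `budforce` treats the post-chilling
phase with the classical linear thermal-time model: at a constant forcing
temperature $T$ above a base temperature $T_b$, the development rate toward
bud break is

$$D(T) = \frac{T - T_b}{\theta},$$

where $\theta$ (°C·h) is the thermal-time requirement and $D$ is measured as
the reciprocal of the hours needed to reach a bud-break fraction of 0.5.
Regressing observed rates on forcing temperature, $D = mT + b$, inverts the
model: the x-intercept $-b/m$ estimates $T_b$ and the reciprocal slope
$1/m$ estimates $\theta$. Both are *derived, nonlinear* functions of the
regression coefficients, which drives two choices below (intervals and
validity flags). $T_b$ is reported as "apparent" because chambers cold
enough to observe the intercept directly are impractical — cuttings die
before completing bud break — so the intercept is always an extrapolation
below the coldest chamber.

### Assumptions

* Linearity of $D(T)$ between the coldest chamber and the optimum; the model
  is fitted inside roughly 12–20 °C and extrapolated below it.
* Chilling is fully satisfied before forcing, so rates reflect heat response
  alone.
* The 0.5-fraction crossing is a representative developmental milestone; no
  sigmoid is fitted to the time course (the crossing is located by linear
  interpolation between the two bracketing observations, which is robust to
  the shape of the curve around the median bud).

## Estimation: parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_temps` | 3 | fewest rate points accepted for a fit. Two points determine a line exactly; three leave one residual degree of freedom so that R² and intervals are meaningful. Combinations that never reach a 0.5 fraction are excluded with a reason, and accessions with fewer than `min_temps` surviving temperatures are reported, not fitted. |
| `n_boot` | 1000 | residual-bootstrap resamples behind the 95% CIs of $T_b$ and $\theta$. Both are ratios of coefficients, so a Wald interval on $(m,b)$ does not transfer; the parametric bootstrap (resample residuals, refit, recompute $-b/m$ and $1/m$, take quantiles) respects the nonlinearity. A delta-method variant (`ci_method = "delta"`) is provided as a cross-check; the two agree closely when the rate noise is small. |
| `boot_seed` | 1 | makes interval estimation reproducible run to run. |

Temperatures entering the regression should be *measured* chamber means, not
set points: a 0.2 °C bias in the regressor moves the extrapolated intercept
by much more than it moves the slope.

A fitted slope $m \le 0$ cannot be inverted into a positive thermal time;
such fits are flagged `invalid_slope` rather than reported.

Across accessions, apparent $T_b$ declines with $\ln\theta$;
`fit_tb_theta_curve()` fits $T_b = a + c\ln\theta$ by OLS. The orientation
($T_b$ on $\ln\theta$ rather than the reverse) was a genuinely open choice;
it was selected because trait scenarios are naturally indexed by $\theta$,
and because the line fitted to the five reference trait combinations in
`peach_hr_scenarios()` reproduces the reference pair (2.2 °C at
7000 °C·h) to within 0.1 °C, which the acceptance script recomputes.

## Simulation: parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| chill base | 7.2 °C | an hour counts as chilling iff its mean temperature is *strictly* below 7.2 °C; the boundary hour contributes nothing (it has measure zero in real records). |
| season window | 01 Oct – 30 Jun | chill accumulation is anchored at 01 October; a season that has not completed bud break by 30 June is reported as non-completing, never extrapolated. |
| `thresholds` | 500, 750, 1000 h | chilling levels at which heat accumulation is switched on, bracketing the chilling requirements typical of commercial germplasm. Warm seasons may never reach a threshold; they are omitted from that cell. |
| `gdh_start` | `"hour"` | heat accumulation starts at the exact threshold-crossing instant. The alternative `"midnight"` dialect starts at 00:00 of the crossing day; the two differ by less than a day and the flag makes the convention explicit. |
| reference | 2.2 °C, 7000 °C·h | the trait combination against which delays are measured (the cross-accession average of the measured germplasm). |

The engine is strictly sequential: warmth before chilling satisfaction
contributes nothing, and chilling is ignored after its threshold is crossed.
No chill negation, Utah/Dynamic chill models, photoperiod or frost-risk
scoring is attempted.

Two timestamp conventions remove all ambiguity at hour resolution. First,
all instants are hour boundaries in local standard time (no daylight-saving
shifts: accumulations are sums, so a fixed 1-h offset is immaterial, but
mixed conventions would corrupt season boundaries). Second, crossing
instants — chilling thresholds and bud break — are reported at the *end* of
the hour that completes the requirement. Under a constant temperature
$T > T_b$ this makes the closed form exact to the grid:
$t_{\text{break}} - t_{\text{start}} = \lceil \theta / (T - T_b) \rceil$
hours, which the test suite checks against 50 random trait draws.

Scenario-versus-reference shifts are reported as signed fractional days at
hourly resolution. Where a significance statement is wanted,
`test_trait_delays()` applies a two-sided Wilcoxon signed-rank test to the
per-season paired delays; the choice of a rank test is a package assumption
(delays are paired by season, few in number, and not plausibly Gaussian).

## Weather regularization

Raw station records are irregular. `regularize_hourly()` assigns each
reading to the clock hour containing it, averages within-hour readings,
fills gaps of at most `max_gap_h = 6` consecutive hours by linear
interpolation (flagged `imputed`), and invalidates any season with a longer
gap or more than 5% imputed hours — invalid seasons are refused by the
simulator rather than silently degraded. The operation is idempotent.
The NOAA ISD-Lite fixed-width dialect (temperatures in tenths of °C,
−9999 missing) and a `timestamp,temp_c` CSV are both read natively; gap
policy for external records is the package's own, since archival records do
not document theirs.

## What the synthetic generators emulate — and what they do not

`gen_forcing_experiment()` inverts the thermal-time model: each bud carries
a personal threshold $\theta_i$, log-normal with median $\theta$ and
coefficient of variation `theta_cv` (default 0.15), and opens at
$t_i = \theta_i / (T - T_b)$. Any smooth positive threshold distribution
produces the sigmoidal cumulative curves seen in real forcing experiments;
log-normal is chosen because it keeps thresholds positive and has a
convenient median parameterization. Defaults mirror a realistic bench
protocol: 125 buds per combination (real counts run 100–150), five chambers
at measured means 11.8–20.1 °C, first scoring at 24 h then a 48/48/72-h
Monday/Wednesday/Friday cadence, and series ending three unchanged
observations after the last count change.

The generator does *not* emulate: bud mortality or stem desiccation during
long forcing (the mechanism suspected when real accessions plateau below
0.5), partial chilling carry-over, within-stem position effects, or
observation miscounts. Passing parameter-recovery tests therefore shows the
estimator is consistent under the stated noise model — per-bud threshold
heterogeneity plus grid censoring — not that it is robust to every failure
mode of real cuttings.

`gen_weather()` builds hourly temperature as annual sinusoid (minimum
mid-January) + diurnal sinusoid (minimum 05:00) + stationary AR(1) noise.
Defaults (annual mean 15.5 °C, half-amplitude 10.5 °C, diurnal
half-amplitude 4 °C, AR(1) 0.8, sd 2 °C) match piedmont stations of the
southeastern United States — January means near 5 °C, July near 26 °C —
giving seasonal chill totals of order 1000–1500 h, so the 500/750/1000-h
thresholds are usually but not always reached, as in real southeastern
winters. Not emulated: synoptic cold fronts and multi-day warm spells
beyond what AR(1) produces, long-term warming trends, and station-specific
microclimate; simulated delay distributions are therefore
qualitatively, not station-quantitatively, comparable to results driven by
archival records.

## Numerical choices and degenerate inputs

* First-crossing rule: cumulative fractions are non-decreasing by
  construction (opened buds are removed at each scoring), so the 0.5
  crossing is unique; the first bracketing pair is used regardless, for
  robustness to malformed input. An exact 0.5 at an observation returns
  that time; a first observation already above 0.5 interpolates from the
  origin (0 h, fraction 0).
* `theta_cv = 0` produces a step time course — a legitimate degenerate case
  used to test grid censoring (the crossing is recovered to within one
  observation interval).
* Forcing temperatures at or below the true base never open; they exercise
  the exclusion path rather than erroring.
* All generators draw through `withr::with_seed()`, so identical seeds give
  identical output without disturbing the caller's RNG state; cohort
  generation derives independent sub-seeds from the top-level seed.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
parameter recovery uses 200 replicate experiments of 125 buds at 5
temperatures; simulator checks use 8–30 synthetic seasons (roughly
6550 hourly values each); oracle comparisons (normal-equations least
squares, per-hour accumulation loops) run on the same inputs as the
implementation they check. These sizes were chosen to estimate medians
stably while keeping a full run in tens of seconds.

## Known limitations

* Apparent $T_b$ is an extrapolation; if the true rate response bends below
  the coldest chamber, both traits are biased, and thermal times of
  low-$T_b$ accessions are best read as minimums.
* The chill-hour model ignores negation by warm spells and is least
  appropriate at warm sites; it is retained because chilling requirements
  of commercial cultivars are published in chill hours.
* The $T_b$–$\ln\theta$ line is fitted across accessions that share an
  experiment; it is a descriptive trade-off surface, not a causal or
  genetic claim.
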
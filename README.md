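# budforce

Estimation of heat-requirement traits for floral bud break in temperate
fruit trees, and weather-driven simulation of how changing those traits
shifts bud-break dates.

## The problem

Bud break in peach (and other *Prunus*) follows the sequential fulfilment of
a chilling requirement (CR: hours of cold that release endodormancy) and a
heat requirement (HR: accumulated warmth that drives development afterwards).
The HR has two trait dimensions: the **base temperature** Tb at which
development stalls, and the **thermal time** θ (in °C·h, growing degree
hours) that must accumulate above Tb. Breeders who want later bloom — to dodge
spring frosts — need to know which of the two is the safer lever.

`budforce` is for phenologists and breeders working with constant-temperature
forcing experiments on dormant cuttings. It implements:

1. **Trait estimation.** At each constant forcing temperature `T`, the
   development rate is `D = 1 / t(0.5)`, the reciprocal of hours to reach a
   0.5 bud-break fraction (found by linear interpolation of the cumulative
   bud-break time course). Under the linear thermal-time model

   ```
   D = (T − Tb) / θ
   ```

   the OLS regression `D = m·T + b` across forcing temperatures yields

   ```
   apparent Tb = −b / m          (x-intercept, °C)
   θ           = 1 / m           (°C·h)
   ```

   with R², and bootstrap confidence intervals for both derived quantities.
   "Apparent" because Tb lies below the coldest chamber and is reached only
   by extrapolation. Accessions whose curves never reach 0.5 are excluded,
   with a machine-readable report.

2. **Trait-line construction.** Across accessions, apparent Tb falls with
   thermal time roughly as `Tb = a + c·ln(θ)`; the fitted line is used to
   build realistic trait combinations that trade Tb against θ.

3. **Phenology simulation.** From hourly winter temperatures, chill hours
   (hours strictly below 7.2 °C) accumulate from 01 October; once a chilling
   threshold (e.g. 500/750/1000 h) is crossed, GDH accumulate as
   `max(T − Tb, 0)` per hour, and bud break is predicted when GDH reaches θ.
   Trait combinations are compared against a reference (2.2 °C, 7000 °C·h)
   as signed bud-break delays in days, per season and station.

4. **Synthetic data.** Seeded generators for forcing experiments with known
   true traits (log-normal per-bud thresholds produce the observed sigmoidal
   curves) and for hourly winter weather (annual + diurnal sinusoids with
   AR(1) noise), so the whole pipeline is testable offline.

## Worked example

```r
library(budforce)

# a synthetic forcing experiment with known truth: Tb = 4 °C, θ = 5000 °C·h
forcing <- gen_forcing_experiment(true_tb_c = 4, true_theta_ch = 5000,
                                  theta_cv = 0.15, seed = 11)
fit <- estimate_accession(forcing)
fit[, c("n_points", "tb_c", "theta_ch", "r_squared")]
#>   n_points  tb_c theta_ch r_squared
#> 1        5 3.471     5245    0.9989
```

The five rate points recover the generating traits to ~0.5 °C and ~5%:
the estimated apparent Tb is 3.47 °C (95% bootstrap CI 3.06–3.80) and
θ is 5245 °C·h (CI 5098–5400), with the near-unity R² typical of
rate–temperature regressions in forcing experiments.

```r
# trait line through the five reference HR combinations
curve <- fit_tb_theta_curve(peach_hr_scenarios()$tb_c,
                            peach_hr_scenarios()$theta_ch)
curve
#> Tb = 56.017 -6.084 * ln(theta)   (R^2 = 1.000, n = 5)

# simulate bud-break shifts over ten synthetic winters
weather <- regularize_hourly(gen_weather(n_seasons = 10, seed = 3))
res <- compare_traits(weather, scenarios = peach_hr_scenarios())
summarise_trait_delays(res)
#>   station_id chill_threshold_h tb_c theta_ch n_seasons median_delay_days
#> 1      SYNTH               500 -0.6    11000        10             -1.75
#> 2      SYNTH               500  0.6     9000        10             -2.17
#> 3      SYNTH               500  2.2     7000        10              0.00
#> 4      SYNTH               500  4.2     5000        10              5.08
#> 5      SYNTH               500  7.3     3000        10             17.67
#> ...
```

`delay_days` is signed: positive means bud break later than the reference
combination in that season. The reference compared with itself is exactly
zero everywhere; the high-Tb/low-θ corner of the trait line is by far the
most volatile, swinging by weeks between winters.

A thin command-line dispatcher over the same functions ships at
`inst/cli/budforce.R` (subcommands `generate-forcing`, `generate-weather`,
`estimate`, `scenarios`, `simulate`, `bloomtrend`).

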
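# Seeded synthetic data: forcing-experiment time courses with known true
# traits, and hourly winter weather with controllable chill/heat structure.
# Both are first-class, reproducible generators so that estimation and
# simulation can be exercised end to end without any external download.

#' Generate a synthetic forcing experiment for one accession
#'
#' Simulates cuttings held at constant forcing temperatures. Each bud `i`
#' carries a personal thermal-time threshold `theta_i`, drawn log-normal with
#' median `true_theta_ch` and coefficient of variation `theta_cv` (log-normal
#' keeps thresholds positive, and any smooth positive threshold distribution
#' yields the sigmoidal cumulative bud-break curves seen in forcing
#' experiments). At constant temperature `T > true_tb_c` the bud opens when
#' elapsed GDH `(T - true_tb_c) * t` reaches `theta_i`, i.e. at
#' `t_i = theta_i / (T - true_tb_c)`; temperatures at or below the base never
#' open (exercising the exclusion path). Cumulative open counts are evaluated
#' on an observation grid starting `first_obs_h` after setup with spacings
#' cycling through `obs_pattern` (the default 48/48/72 h mimics
#' Monday/Wednesday/Friday scoring), and each series stops after the counts
#' are unchanged for three consecutive observations.
#'
#' @param true_tb_c True base temperature (degrees C).
#' @param true_theta_ch True (median) thermal-time requirement (degree C h).
#' @param theta_cv Coefficient of variation of per-bud thresholds (default
#'   0.15); `0` gives a degenerate step time course.
#' @param n_buds Initial floral bud count (default 125, within the typical
#'   100--150 per combination).
#' @param temps_c Constant forcing temperatures; the defaults are measured
#'   chamber means near set points of 12--20 C.
#' @param obs_pattern Observation spacings in hours, recycled (default
#'   `c(48, 48, 72)`).
#' @param first_obs_h First observation time (default 24 h).
#' @param max_hours Horizon after which a never-completing series is
#'   truncated (default 2400 h).
#' @param accession Accession label.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Long-format tibble with columns `accession`, `temp_c`, `obs_hour`,
#'   `cum_open`, `n_initial` (one block per forcing temperature).
#' @export
#' @examples
#' gen_forcing_experiment(4, 5000, theta_cv = 0.15, seed = 11)
gen_forcing_experiment <- function(true_tb_c, true_theta_ch, theta_cv = 0.15,
                                   n_buds = 125L,
                                   temps_c = c(11.8, 13.6, 15.9, 17.8, 20.1),
                                   obs_pattern = c(48, 48, 72),
                                   first_obs_h = 24, max_hours = 2400,
                                   accession = "SYN1", seed = 1L) {
  stopifnot(theta_cv >= 0, n_buds >= 1, true_theta_ch > 0,
            all(obs_pattern > 0))
  sdlog <- sqrt(log(1 + theta_cv^2))
  blocks <- withr::with_seed(seed, {
    lapply(temps_c, function(tt) {
      theta_i <- if (theta_cv == 0) rep(true_theta_ch, n_buds) else
        stats::rlnorm(n_buds, meanlog = log(true_theta_ch), sdlog = sdlog)
      open_t <- if (tt > true_tb_c) theta_i / (tt - true_tb_c) else
        rep(Inf, n_buds)

      horizon <- if (any(is.finite(open_t)))
        min(max(open_t[is.finite(open_t)]), max_hours) else max_hours
      times <- first_obs_h
      k <- 1L
      while (times[length(times)] <= horizon) {
        times <- c(times, times[length(times)] +
                     obs_pattern[(k - 1L) %% length(obs_pattern) + 1L])
        k <- k + 1L
      }
      cum <- vapply(times, function(t) sum(open_t <= t), integer(1))
      # stopping rule: once bud break has plateaued, three consecutive
      # unchanged observations end the series (scoring continues through the
      # initial zero-count phase before the first bud opens)
      changes <- which(diff(cum) != 0)
      last_change <- if (length(changes) == 0L) length(cum) else
        changes[length(changes)] + 1L
      idx <- seq_len(min(length(cum), last_change + 3L))
      tibble::tibble(accession = accession, temp_c = tt,
                     obs_hour = times[idx], cum_open = cum[idx],
                     n_initial = n_buds)
    })
  })
  dplyr::bind_rows(blocks)
}

#' Generate a synthetic cohort of accessions
#'
#' Draws per-accession true traits along a base-temperature/thermal-time
#' line `Tb = a + c * ln(theta)` with Gaussian scatter, then generates a
#' forcing experiment per accession. Useful for end-to-end pipeline tests.
#'
#' @param n_accessions Number of accessions.
#' @param theta_range Range of true thermal times (degree C h) sampled
#'   log-uniformly (default 2000--12000, spanning observed germplasm).
#' @param curve_a,curve_c Tb--ln(theta) line parameters (defaults fit the
#'   span of apparent Tb roughly 8 C at theta 3000 down to -1 C at 11000).
#' @param tb_sd Gaussian scatter of true Tb about the line (default 0.5 C).
#' @param seed Integer seed.
#' @param ... Passed to [gen_forcing_experiment()] (e.g. `theta_cv`, `n_buds`).
#' @return List with `truth` (tibble `accession`, `true_tb_c`,
#'   `true_theta_ch`) and `forcing` (long-format tibble for the whole cohort).
#' @export
gen_forcing_cohort <- function(n_accessions = 10L,
                               theta_range = c(2000, 12000),
                               curve_a = 56, curve_c = -6,
                               tb_sd = 0.5, seed = 1L, ...) {
  par <- withr::with_seed(seed, {
    theta <- exp(stats::runif(n_accessions, log(theta_range[1L]),
                              log(theta_range[2L])))
    tb <- curve_a + curve_c * log(theta) + stats::rnorm(n_accessions, 0, tb_sd)
    list(theta = theta, tb = tb,
         sub_seeds = sample.int(.Machine$integer.max, n_accessions))
  })
  ids <- sprintf("A%03d", seq_len(n_accessions))
  forcing <- dplyr::bind_rows(lapply(seq_len(n_accessions), function(i) {
    gen_forcing_experiment(par$tb[i], par$theta[i], accession = ids[i],
                           seed = par$sub_seeds[i], ...)
  }))
  list(
    truth = tibble::tibble(accession = ids, true_tb_c = par$tb,
                           true_theta_ch = par$theta),
    forcing = forcing)
}

#' Generate synthetic hourly winter weather
#'
#' Hourly temperature for `n_seasons` dormant seasons (01 Oct--30 Jun) as the
#' sum of an annual sinusoid with its minimum in mid-January, a diurnal
#' sinusoid with its minimum pre-dawn (05:00), and stationary AR(1) Gaussian
#' noise. Defaults emulate a humid-subtropical winter of the southeastern
#' United States piedmont (annual mean 15.5 C with a 10.5 C half-amplitude,
#' i.e. January means near 5 C and July means near 26 C), which yields
#' chill totals on the order of 1000--1500 h per season.
#'
#' @param n_seasons Number of seasons (default 10).
#' @param start_year First season start year (default 1990).
#' @param annual_mean_c Annual mean temperature (degrees C).
#' @param annual_amplitude_c Half-amplitude of the annual cycle (degrees C).
#' @param diurnal_amplitude_c Half-amplitude of the diurnal cycle (degrees C).
#' @param ar1_coef AR(1) coefficient of the hourly noise, in `[0, 1)`.
#' @param noise_sd_c Stationary standard deviation of the noise (degrees C).
#' @param station_id Station label.
#' @param seed Integer seed.
#' @return Tibble `station_id`, `time`, `temp_c` (raw-series layout; pass
#'   through [regularize_hourly()] before simulation).
#' @export
gen_weather <- function(n_seasons = 10L, start_year = 1990L,
                        annual_mean_c = 15.5, annual_amplitude_c = 10.5,
                        diurnal_amplitude_c = 4, ar1_coef = 0.8,
                        noise_sd_c = 2, station_id = "SYNTH", seed = 1L) {
  stopifnot(ar1_coef >= 0, ar1_coef < 1, noise_sd_c >= 0, n_seasons >= 1)
  seasons <- withr::with_seed(seed, {
    lapply(seq_len(n_seasons), function(k) {
      sy <- start_year + k - 1L
      sb <- season_bounds(sy)
      grid <- seq(sb$start, sb$end, by = 3600)
      lt <- as.POSIXlt(grid, tz = "UTC")
      doy <- lt$yday + 1L + lt$hour / 24
      hod <- lt$hour
      base <- annual_mean_c -
        annual_amplitude_c * cos(2 * pi * (doy - 15) / 365.25) -
        diurnal_amplitude_c * cos(2 * pi * (hod - 5) / 24)
      n <- length(grid)
      eps <- numeric(n)
      if (noise_sd_c > 0) {
        innov_sd <- noise_sd_c * sqrt(1 - ar1_coef^2)
        z <- stats::rnorm(n, 0, innov_sd)
        eps[1L] <- stats::rnorm(1L, 0, noise_sd_c)
        for (t in 2:n) eps[t] <- ar1_coef * eps[t - 1L] + z[t]
      }
      tibble::tibble(station_id = station_id, time = grid,
                     temp_c = base + eps)
    })
  })
  dplyr::bind_rows(seasons)
}
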
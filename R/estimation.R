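# Estimation of apparent base temperature and thermal time from
# constant-temperature forcing experiments.
#
# At each forcing temperature T the development rate is D = 1 / (hours to
# reach 0.5 bud-break fraction). Under the linear thermal-time model
#   D = (T - Tb) / theta
# the OLS regression D = m*T + b yields
#   apparent Tb = -b/m        (x-intercept, degrees C)
#   theta       = 1/m         (thermal time, degree C hours).
# Tb is "apparent" because it lies below the lowest forcing temperature and
# is reached only by extrapolation.

#' Bud-break fraction of a forcing time course
#'
#' Cumulative opened floral buds divided by the initial floral bud count.
#'
#' @param cum_open Non-decreasing cumulative counts of opened buds.
#' @param n_initial Initial floral bud count (single positive integer).
#' @return Numeric vector of fractions in `[0, 1]`, same length as `cum_open`.
#' @export
#' @examples
#' bud_break_fraction(c(10, 60, 100), 100)
bud_break_fraction <- function(cum_open, n_initial) {
  if (length(n_initial) != 1L || is.na(n_initial) || n_initial < 1) {
    stop("n_initial must be a single count >= 1")
  }
  if (any(diff(cum_open) < 0)) stop("cum_open must be non-decreasing")
  if (any(cum_open > n_initial)) stop("cum_open exceeds n_initial")
  cum_open / n_initial
}

#' Hours of forcing to reach 0.5 bud-break fraction
#'
#' Linear interpolation between the two observations bracketing the 0.5
#' fraction, using the first bracketing pair. An exact hit at an observation
#' returns that observation time. If the first observation already exceeds
#' 0.5 the crossing is interpolated from an implicit origin (0 h, fraction 0).
#' If the series never reaches 0.5, `NA` is returned: that temperature is
#' excluded from the rate regression, mirroring experimental combinations in
#' which bud break stalled below half.
#'
#' @param obs_hours Strictly increasing observation times (h since forcing start).
#' @param fraction Bud-break fractions at those times (non-decreasing).
#' @return Hours to 0.5 fraction, or `NA_real_` if never reached.
#' @export
#' @examples
#' hours_to_half(c(96, 120), c(0.4, 0.6)) # 108
hours_to_half <- function(obs_hours, fraction) {
  stopifnot(length(obs_hours) == length(fraction))
  if (length(obs_hours) == 0L) return(NA_real_)
  if (any(diff(obs_hours) <= 0)) stop("obs_hours must be strictly increasing")
  i <- which(fraction >= 0.5)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  if (fraction[i] == 0.5) return(obs_hours[i])
  if (i == 1L) {
    t_lo <- 0; f_lo <- 0
  } else {
    t_lo <- obs_hours[i - 1L]; f_lo <- fraction[i - 1L]
  }
  t_lo + (0.5 - f_lo) * (obs_hours[i] - t_lo) / (fraction[i] - f_lo)
}

#' Development-rate points for one accession
#'
#' Computes, per forcing temperature, the hours to 0.5 bud-break fraction and
#' the development rate `1/hours`. Temperatures whose time course never
#' reached 0.5 are retained with `included = FALSE`.
#'
#' @param tc Long-format data frame for one accession with columns `temp_c`,
#'   `obs_hour`, `cum_open`, `n_initial`.
#' @return Tibble with columns `temp_c`, `hours_to_half`, `rate`, `included`.
#' @export
rate_points <- function(tc) {
  stopifnot(all(c("temp_c", "obs_hour", "cum_open", "n_initial") %in% names(tc)))
  tc |>
    dplyr::group_by(.data$temp_c) |>
    dplyr::arrange(.data$obs_hour, .by_group = TRUE) |>
    dplyr::summarise(
      hours_to_half = hours_to_half(
        .data$obs_hour,
        bud_break_fraction(.data$cum_open, .data$n_initial[1L])),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate = 1 / .data$hours_to_half,
      included = !is.na(.data$hours_to_half)
    )
}

# Closed-form OLS of y on x; returns c(intercept, slope).
ols_coef <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  m <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(b = my - m * mx, m = m)
}

#' Fit the development-rate response to forcing temperature
#'
#' Ordinary least squares of development rate on temperature. The x-intercept
#' `-b/m` is the apparent base temperature and the reciprocal slope `1/m` the
#' thermal-time requirement in degree C hours. Confidence intervals for both,
#' which are nonlinear in the regression coefficients, are obtained by a
#' seeded parametric bootstrap that resamples regression residuals; a
#' delta-method variant is available for cross-checking.
#'
#' @param temp_c Measured mean chamber temperatures (degrees C), length >= 3.
#' @param rate Development rates (per hour) at those temperatures.
#' @param n_boot Bootstrap resamples for the confidence intervals (default
#'   1000); `0` skips interval estimation.
#' @param boot_seed Seed for the bootstrap resampling.
#' @param conf Confidence level (default 0.95).
#' @param ci_method `"bootstrap"` (default) or `"delta"`.
#' @return One-row tibble: `n_points`, `m`, `b`, `tb_c`, `theta_ch`,
#'   `r_squared`, `tb_lo`, `tb_hi`, `theta_lo`, `theta_hi`, `status`
#'   (`"ok"` or `"invalid_slope"` when the slope is not positive).
#' @export
fit_rate_response <- function(temp_c, rate, n_boot = 1000L, boot_seed = 1L,
                              conf = 0.95, ci_method = c("bootstrap", "delta")) {
  ci_method <- match.arg(ci_method)
  keep <- is.finite(temp_c) & is.finite(rate)
  temp_c <- temp_c[keep]; rate <- rate[keep]
  n <- length(temp_c)
  if (n < 3L) stop("insufficient temperatures: need >= 3 rate points, have ", n)

  fit <- stats::lm(rate ~ temp_c)
  b <- unname(stats::coef(fit)[1L])
  m <- unname(stats::coef(fit)[2L])
  # summary.lm warns on numerically perfect fits, a legitimate input here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  tb <- -b / m
  theta <- 1 / m
  status <- if (is.finite(m) && m > 0) "ok" else "invalid_slope"

  tb_lo <- tb_hi <- theta_lo <- theta_hi <- NA_real_
  alpha <- (1 - conf) / 2
  if (status == "ok" && n_boot > 0L) {
    if (ci_method == "bootstrap") {
      res <- stats::residuals(fit)
      fitted <- stats::fitted(fit)
      draws <- withr::with_seed(boot_seed, {
        vapply(seq_len(n_boot), function(i) {
          y_star <- fitted + sample(res, n, replace = TRUE)
          cf <- ols_coef(temp_c, y_star)
          c(-cf[["b"]] / cf[["m"]], 1 / cf[["m"]])
        }, numeric(2))
      })
      tb_q <- stats::quantile(draws[1L, ], c(alpha, 1 - alpha), names = FALSE)
      th_q <- stats::quantile(draws[2L, ], c(alpha, 1 - alpha), names = FALSE)
      tb_lo <- tb_q[1L]; tb_hi <- tb_q[2L]
      theta_lo <- th_q[1L]; theta_hi <- th_q[2L]
    } else {
      V <- stats::vcov(fit)
      g_tb <- c(-1 / m, b / m^2)        # d(-b/m)/d(b, m)
      g_th <- c(0, -1 / m^2)            # d(1/m)/d(b, m)
      se_tb <- sqrt(drop(t(g_tb) %*% V %*% g_tb))
      se_th <- sqrt(drop(t(g_th) %*% V %*% g_th))
      z <- stats::qt(1 - alpha, df = n - 2L)
      tb_lo <- tb - z * se_tb; tb_hi <- tb + z * se_tb
      theta_lo <- theta - z * se_th; theta_hi <- theta + z * se_th
    }
  }

  tibble::tibble(
    n_points = n, m = m, b = b, tb_c = tb, theta_ch = theta, r_squared = r2,
    tb_lo = tb_lo, tb_hi = tb_hi, theta_lo = theta_lo, theta_hi = theta_hi,
    status = status
  )
}

#' Estimate apparent Tb and thermal time for one accession
#'
#' Applies [hours_to_half()] per forcing temperature, drops temperatures that
#' never reached 0.5 fraction, and fits the rate--temperature regression when
#' at least `min_temps` rate points remain. Otherwise returns an exclusion
#' record: accessions that reach 0.5 at too few (or no) temperatures are not
#' carried into further analysis.
#'
#' @param tc Long-format data frame for one accession: columns `accession`,
#'   `temp_c`, `obs_hour`, `cum_open`, `n_initial`.
#' @param min_temps Minimum rate points required for a fit (default 3, which
#'   leaves a residual degree of freedom for R-squared and intervals).
#' @param ... Passed to [fit_rate_response()] (e.g. `n_boot`).
#' @return One-row tibble as from [fit_rate_response()] plus `accession` and,
#'   for exclusions, `status` of `"excluded_below_half"` (no temperature
#'   reached 0.5) or `"insufficient_temperatures"`.
#' @export
estimate_accession <- function(tc, min_temps = 3L, ...) {
  acc <- unique(tc$accession)
  if (length(acc) != 1L) stop("estimate_accession expects a single accession")
  rp <- rate_points(tc)
  inc <- rp[rp$included, , drop = FALSE]
  empty <- tibble::tibble(
    n_points = nrow(inc), m = NA_real_, b = NA_real_, tb_c = NA_real_,
    theta_ch = NA_real_, r_squared = NA_real_, tb_lo = NA_real_,
    tb_hi = NA_real_, theta_lo = NA_real_, theta_hi = NA_real_,
    status = NA_character_)
  if (nrow(inc) == 0L) {
    out <- empty; out$status <- "excluded_below_half"
  } else if (nrow(inc) < min_temps) {
    out <- empty; out$status <- "insufficient_temperatures"
  } else {
    out <- fit_rate_response(inc$temp_c, inc$rate, ...)
  }
  dplyr::bind_cols(tibble::tibble(accession = acc), out)
}

#' Estimate a cohort of accessions
#'
#' Runs [estimate_accession()] for every accession in a long-format forcing
#' table and separates successful fits from exclusions, so that every input
#' accession appears exactly once across the two tables.
#'
#' @param forcing Long-format data frame: `accession`, `temp_c`, `obs_hour`,
#'   `cum_open`, `n_initial`.
#' @param ... Passed to [estimate_accession()].
#' @return List with tibbles `fits` (status `"ok"`) and `exclusions`
#'   (all other statuses, with reasons).
#' @export
estimate_cohort <- function(forcing, ...) {
  if (nrow(forcing) == 0L) stop("empty forcing table")
  rows <- lapply(split(forcing, forcing$accession), estimate_accession, ...)
  all <- dplyr::bind_rows(rows)
  list(
    fits = all[all$status == "ok", , drop = FALSE],
    exclusions = all[all$status != "ok", , drop = FALSE]
  )
}

#' Fit the base-temperature / thermal-time relationship
#'
#' Across accessions, apparent base temperature falls with thermal time in a
#' logarithmic fashion. This fits `Tb = a + c * ln(theta)` by OLS; the fitted
#' line is used to build heat-requirement trait combinations lying on the
#' observed Tb--theta relationship.
#'
#' @param tb_c Apparent base temperatures (degrees C), length >= 3.
#' @param theta_ch Thermal times (degree C hours), all positive.
#' @return List of class `tb_theta_curve`: `a` (intercept, degrees C),
#'   `c` (slope per ln(degree C h)), `r_squared`, `n`.
#' @export
fit_tb_theta_curve <- function(tb_c, theta_ch) {
  stopifnot(length(tb_c) == length(theta_ch))
  if (length(tb_c) < 3L) stop("need >= 3 accessions to fit the Tb-theta curve")
  if (any(theta_ch <= 0)) stop("thermal time must be positive")
  fit <- stats::lm(tb_c ~ log(theta_ch))
  structure(
    list(a = unname(stats::coef(fit)[1L]), c = unname(stats::coef(fit)[2L]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n = length(tb_c)),
    class = "tb_theta_curve")
}

#' @export
print.tb_theta_curve <- function(x, ...) {
  cat(sprintf("Tb = %.3f %+.3f * ln(theta)   (R^2 = %.3f, n = %d)\n",
              x$a, x$c, x$r_squared, x$n))
  invisible(x)
}

#' Predict apparent Tb from thermal time on a fitted curve
#'
#' @param object A `tb_theta_curve` from [fit_tb_theta_curve()].
#' @param theta_ch Thermal times (degree C hours), positive.
#' @param ... Unused.
#' @return Predicted base temperatures (degrees C).
#' @export
predict.tb_theta_curve <- function(object, theta_ch, ...) {
  if (any(theta_ch <= 0)) stop("thermal time must be positive")
  object$a + object$c * log(theta_ch)
}

#' Pearson correlation with a two-sided test
#'
#' Thin wrapper around [stats::cor.test()] used for cross-trait checks such
#' as chilling requirement against apparent Tb or thermal time.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
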
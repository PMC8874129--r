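# Orchestration: file IO for the long-format forcing table and fits table,
# cohort estimation with an exclusion report, scenario construction on the
# fitted Tb-theta line, and the auxiliary field-bloom regression.

#' Reference heat-requirement trait combinations
#'
#' Five base-temperature / thermal-time combinations lying on the line fitted
#' to the apparent Tb and thermal time of measured peach accessions, used to
#' probe whether shifting the heat requirement along that line advances or
#' delays simulated bud break. The middle row (2.2 C, 7000 C h) is the
#' cross-accession average and serves as the reference combination.
#'
#' @return Tibble with columns `tb_c`, `theta_ch`.
#' @export
#' @examples
#' peach_hr_scenarios()
peach_hr_scenarios <- function() {
  tibble::tibble(
    tb_c     = c(7.3, 4.2, 2.2, 0.6, -0.6),
    theta_ch = c(3000, 5000, 7000, 9000, 11000))
}

#' Read a long-format forcing table
#'
#' @param path CSV with header `accession,temp_c,obs_hour,cum_open,n_initial`.
#' @return Tibble in the same layout.
#' @export
read_forcing_csv <- function(path) {
  if (!file.exists(path)) stop("forcing file not found: ", path)
  out <- readr::read_csv(path, col_types = readr::cols(
    accession = readr::col_character(),
    temp_c = readr::col_double(),
    obs_hour = readr::col_double(),
    cum_open = readr::col_double(),
    n_initial = readr::col_double()), progress = FALSE)
  if (nrow(out) == 0L) stop("empty forcing table: ", path)
  out
}

#' Run cohort estimation and write fits plus an exclusion report
#'
#' Reads (or accepts) a long-format forcing table, estimates every accession,
#' and optionally writes two CSVs: the per-accession fits
#' (`accession,n_points,m,b,tb_c,theta_ch,r2,tb_lo,tb_hi,theta_lo,theta_hi,status`)
#' and an exclusion report listing every accession dropped, with its reason.
#' Every input accession appears exactly once across the two tables.
#'
#' @param forcing Data frame or path to a forcing CSV.
#' @param fits_path,exclusions_path Optional output CSV paths.
#' @param ... Passed to [estimate_cohort()] (e.g. `n_boot`, `min_temps`).
#' @return Invisibly, the list from [estimate_cohort()].
#' @export
run_estimate <- function(forcing, fits_path = NULL, exclusions_path = NULL,
                         ...) {
  if (is.character(forcing)) forcing <- read_forcing_csv(forcing)
  res <- estimate_cohort(forcing, ...)
  if (!is.null(fits_path)) {
    fits_out <- res$fits
    names(fits_out)[names(fits_out) == "r_squared"] <- "r2"
    readr::write_csv(fits_out, fits_path)
  }
  if (!is.null(exclusions_path)) {
    readr::write_csv(
      res$exclusions[, c("accession", "n_points", "status")], exclusions_path)
  }
  invisible(res)
}

#' Build trait scenarios on a fitted Tb--theta curve
#'
#' For each requested thermal time, emits the trait combination lying on the
#' fitted line `Tb = a + c * ln(theta)`.
#'
#' @param curve A [fit_tb_theta_curve()] result.
#' @param thetas Thermal times (degree C hours), positive.
#' @return Tibble with columns `tb_c`, `theta_ch`.
#' @export
build_scenarios <- function(curve, thetas) {
  stopifnot(inherits(curve, "tb_theta_curve"))
  if (length(thetas) == 0L) {
    return(tibble::tibble(tb_c = numeric(0), theta_ch = numeric(0)))
  }
  if (any(thetas <= 0)) stop("thermal time must be positive")
  tibble::tibble(tb_c = predict(curve, thetas), theta_ch = thetas)
}

#' Field bloom-day trend on thermal time, per year
#'
#' For each year, OLS of day-of-year of 50% bloom on accession thermal time,
#' with the two-sided t-test on the slope. A flat slope means heat-requirement
#' variation did not shift field bloom dates that year.
#'
#' @param bloom Data frame with columns `year`, `bloom_doy`, `theta_ch`
#'   (one row per accession x year); >= 3 accessions per year.
#' @return Tibble with `year`, `n`, `slope` (days per degree C h),
#'   `intercept`, `p_value`, `r_squared`.
#' @export
bloom_trend_regression <- function(bloom) {
  stopifnot(all(c("year", "bloom_doy", "theta_ch") %in% names(bloom)))
  res <- lapply(split(bloom, bloom$year), function(d) {
    if (nrow(d) < 3L) stop("year ", d$year[1L], ": need >= 3 accessions")
    if (stats::sd(d$theta_ch) == 0) stop("year ", d$year[1L],
                                         ": zero variance in theta")
    fit <- stats::lm(bloom_doy ~ theta_ch, data = d)
    sm <- suppressWarnings(summary(fit))
    tibble::tibble(
      year = d$year[1L], n = nrow(d),
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      p_value = sm$coefficients[2L, 4L],
      r_squared = sm$r.squared)
  })
  dplyr::bind_rows(res)
}

#' Write compare_traits results to CSV
#'
#' @param results Output of [compare_traits()].
#' @param path Output CSV path.
#' @return Invisibly, `results`.
#' @export
write_results_csv <- function(results, path) {
  out <- results
  out$chill_reached_at <- format(out$chill_reached_at, "%Y-%m-%dT%H:%M:%S")
  out$budbreak_at <- format(out$budbreak_at, "%Y-%m-%dT%H:%M:%S")
  out$reference_budbreak_at <- format(out$reference_budbreak_at,
                                      "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(out, path)
  invisible(results)
}
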
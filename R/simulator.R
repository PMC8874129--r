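# Weather-driven phenology engine.
#
# Chilling is accumulated from the season start (01 October) as hours with
# mean temperature strictly below 7.2 C (simple chill-hour model). Once a
# stated chilling threshold is reached, growing degree hours (GDH) accumulate
# as max(T - Tb, 0) per hour, and bud break is predicted at the instant the
# trait-specific thermal-time requirement theta is completed. The model is
# strictly sequential: warmth before chilling satisfaction contributes
# nothing, and chilling is ignored after its threshold is crossed.

CHILL_BASE_C <- 7.2

#' Heat-requirement trait combination
#'
#' @param tb_c Base temperature for GDH accumulation (degrees C).
#' @param theta_ch Thermal-time requirement (degree C hours), positive.
#' @return List of class `hr_traits`.
#' @export
#' @examples
#' hr_traits(2.2, 7000)
hr_traits <- function(tb_c, theta_ch) {
  stopifnot(is.finite(tb_c), is.finite(theta_ch), theta_ch > 0)
  structure(list(tb_c = tb_c, theta_ch = theta_ch), class = "hr_traits")
}

#' Running chill-hour accumulation for one season
#'
#' Cumulative count of hours with temperature strictly below 7.2 C, starting
#' at the season anchor of 01 October.
#'
#' @param w Regularized weather series from [regularize_hourly()].
#' @param season_year Season start year.
#' @param station_id Station label; may be omitted for single-station series.
#' @return Tibble with `time` (hour start), `temp_c`, `chill_h` (cumulative
#'   chill hours at the end of that hour).
#' @export
chill_hours <- function(w, season_year, station_id = NULL) {
  s <- season_slice(w, season_year, station_id)
  tibble::tibble(
    time = s$time, temp_c = s$temp_c,
    chill_h = cumsum(as.integer(s$temp_c < CHILL_BASE_C)))
}

#' Instant at which a chilling threshold is reached
#'
#' Returns the end of the hour during which the running chill total first
#' reaches `threshold_h`, or `NA` if the season never accumulates that much
#' chilling (warm seasons may not; such seasons are skipped downstream).
#'
#' @inheritParams chill_hours
#' @param threshold_h Chilling threshold in hours (e.g. 500, 750, 1000).
#' @return POSIXct instant, or `NA` if the threshold is not reached.
#' @export
chill_threshold_time <- function(w, season_year, threshold_h,
                                 station_id = NULL) {
  ch <- chill_hours(w, season_year, station_id)
  i <- which(ch$chill_h >= threshold_h)
  if (length(i) == 0L) return(as.POSIXct(NA, tz = "UTC"))
  ch$time[i[1L]] + 3600
}

#' Running growing-degree-hour accumulation
#'
#' Sums `max(T - tb_c, 0)` over the hours of the season beginning at or after
#' `start`. The accumulated total is reported at the end of each hour.
#'
#' @inheritParams chill_hours
#' @param start POSIXct instant within the season at which GDH accumulation
#'   begins (typically a chilling-threshold crossing).
#' @param tb_c Base temperature (degrees C).
#' @return Tibble with `time_end` (end of each hour) and `gdh` (cumulative
#'   degree C hours at that instant); non-decreasing.
#' @export
accumulate_gdh <- function(w, season_year, start, tb_c, station_id = NULL) {
  s <- season_slice(w, season_year, station_id)
  s <- s[s$time >= start, , drop = FALSE]
  tibble::tibble(
    time_end = s$time + 3600,
    gdh = cumsum(pmax(s$temp_c - tb_c, 0)))
}

#' Predicted bud-break instant for a trait combination
#'
#' The end of the first hour at which accumulated GDH reaches the
#' thermal-time requirement, or `NA` if the season ends first (bud break is
#' reported, never extrapolated beyond 30 June).
#'
#' @inheritParams accumulate_gdh
#' @param traits An [hr_traits()] combination.
#' @return POSIXct instant or `NA`.
#' @export
budbreak_time <- function(w, season_year, start, traits, station_id = NULL) {
  g <- accumulate_gdh(w, season_year, start, traits$tb_c, station_id)
  i <- which(g$gdh >= traits$theta_ch)
  if (length(i) == 0L) return(as.POSIXct(NA, tz = "UTC"))
  g$time_end[i[1L]]
}

# Resolve the GDH start instant from the chilling crossing under a dialect:
# "hour" starts at the exact crossing instant, "midnight" at 00:00 of the
# calendar day containing it.
gdh_start_instant <- function(chill_time, gdh_start) {
  if (gdh_start == "hour") return(chill_time)
  trunc.POSIXt(chill_time, units = "days")
}

#' Compare bud-break timing of trait combinations against a reference
#'
#' For every valid season, chilling threshold and trait scenario, simulates
#' the chilling-satisfaction instant and bud-break instant and reports the
#' delay in days relative to the reference combination (positive = later bud
#' break). Seasons in which the chilling threshold is never reached, or in
#' which the reference does not complete before 30 June, are omitted.
#'
#' @param w Regularized weather series (may hold several stations).
#' @param thresholds Chilling thresholds in hours (default `c(500, 750, 1000)`).
#' @param scenarios Data frame with columns `tb_c`, `theta_ch`, one row per
#'   trait combination.
#' @param reference An [hr_traits()] combination (default 2.2 C, 7000 C h,
#'   the cross-accession average).
#' @param gdh_start `"hour"` (GDH starts at the exact crossing instant,
#'   default) or `"midnight"` (start of the crossing day).
#' @return Tibble with one row per station x season x threshold x scenario:
#'   `station_id`, `season_year`, `chill_threshold_h`, `tb_c`, `theta_ch`,
#'   `chill_reached_at`, `budbreak_at`, `reference_budbreak_at`,
#'   `delay_days` (signed, fractional).
#' @export
compare_traits <- function(w, thresholds = c(500, 750, 1000), scenarios,
                           reference = hr_traits(2.2, 7000),
                           gdh_start = c("hour", "midnight")) {
  gdh_start <- match.arg(gdh_start)
  stopifnot(all(c("tb_c", "theta_ch") %in% names(scenarios)))
  st <- season_status(w)
  st <- st[st$valid, , drop = FALSE]
  if (nrow(st) == 0L) stop("no valid seasons in weather series")

  rows <- list()
  for (k in seq_len(nrow(st))) {
    sid <- st$station_id[k]; sy <- st$season_year[k]
    for (thr in thresholds) {
      ct <- chill_threshold_time(w, sy, thr, station_id = sid)
      if (is.na(ct)) next
      start <- gdh_start_instant(ct, gdh_start)
      ref_bb <- budbreak_time(w, sy, start, reference, station_id = sid)
      if (is.na(ref_bb)) {
        message("season ", sy, " at ", sid, ", threshold ", thr,
                " h: reference did not complete by 30 Jun; season omitted")
        next
      }
      for (j in seq_len(nrow(scenarios))) {
        tr <- hr_traits(scenarios$tb_c[j], scenarios$theta_ch[j])
        bb <- budbreak_time(w, sy, start, tr, station_id = sid)
        delay <- if (is.na(bb)) NA_real_ else
          as.numeric(difftime(bb, ref_bb, units = "hours")) / 24
        rows[[length(rows) + 1L]] <- tibble::tibble(
          station_id = sid, season_year = sy, chill_threshold_h = thr,
          tb_c = tr$tb_c, theta_ch = tr$theta_ch,
          chill_reached_at = ct, budbreak_at = bb,
          reference_budbreak_at = ref_bb, delay_days = delay)
      }
    }
  }
  if (length(rows) == 0L) stop("no season reached any chilling threshold")
  dplyr::bind_rows(rows)
}

#' Summarise trait-scenario delays
#'
#' Median, minimum and maximum bud-break delay per station x chilling
#' threshold x scenario, over seasons in which the scenario completed.
#'
#' @param results Output of [compare_traits()].
#' @return Tibble with `n_seasons`, `median_delay_days`, `min_delay_days`,
#'   `max_delay_days` per cell.
#' @export
summarise_trait_delays <- function(results) {
  results |>
    dplyr::filter(!is.na(.data$delay_days)) |>
    dplyr::group_by(.data$station_id, .data$chill_threshold_h,
                    .data$tb_c, .data$theta_ch) |>
    dplyr::summarise(
      n_seasons = dplyr::n(),
      median_delay_days = stats::median(.data$delay_days),
      min_delay_days = min(.data$delay_days),
      max_delay_days = max(.data$delay_days),
      .groups = "drop")
}

#' Test scenario delays against the reference
#'
#' Two-sided Wilcoxon signed-rank test of the paired per-season delays of
#' each scenario against zero (no shift relative to the reference), per
#' station x threshold x scenario. The choice of a signed-rank test is a
#' package assumption: delays are paired by season and need not be Gaussian.
#'
#' @param results Output of [compare_traits()].
#' @return Tibble with `n_seasons`, `median_delay_days`, `p_value` per cell.
#' @export
test_trait_delays <- function(results) {
  results |>
    dplyr::filter(!is.na(.data$delay_days)) |>
    dplyr::group_by(.data$station_id, .data$chill_threshold_h,
                    .data$tb_c, .data$theta_ch) |>
    dplyr::summarise(
      n_seasons = dplyr::n(),
      median_delay_days = stats::median(.data$delay_days),
      p_value = if (all(.data$delay_days == 0)) 1 else
        suppressWarnings(stats::wilcox.test(.data$delay_days)$p.value),
      .groups = "drop")
}
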
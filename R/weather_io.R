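# Hourly weather input and regularization.
#
# The simulator consumes one value per clock hour, in local standard time,
# organised into dormant seasons running 01 October -- 30 June. All timestamps
# are stored as POSIXct in the "UTC" zone, which here simply encodes local
# standard time without daylight-saving shifts.

#' Start and end of a dormant season
#'
#' A season is the interval from 01 October of `season_year` through the last
#' hour of 30 June of the following calendar year. Chill accumulation is
#' anchored at the season start.
#'
#' @param season_year Calendar year in which the season begins (integer).
#' @return A list with POSIXct elements `start` (01 Oct 00:00) and
#'   `end` (30 Jun 23:00 of the next year).
#' @export
#' @examples
#' season_bounds(1999)
season_bounds <- function(season_year) {
  list(
    start = as.POSIXct(sprintf("%d-10-01 00:00:00", season_year), tz = "UTC"),
    end   = as.POSIXct(sprintf("%d-06-30 23:00:00", season_year + 1), tz = "UTC")
  )
}

#' Season membership of a timestamp
#'
#' Maps each instant to the dormant season (01 Oct--30 Jun) containing it.
#' Hours in July--September belong to no season and map to `NA`.
#'
#' @param time POSIXct vector.
#' @return Integer vector of season start years, `NA` outside any season.
#' @export
season_year_of <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  out <- ifelse(mon >= 10L, yr, ifelse(mon <= 6L, yr - 1L, NA_integer_))
  as.integer(out)
}

#' Read an hourly temperature table
#'
#' Reads a raw (possibly irregular) hourly air-temperature record. Two dialects
#' are supported:
#' \describe{
#'   \item{`simple_csv`}{header `timestamp,temp_c`; ISO-8601 timestamps;
#'     temperatures in degrees C.}
#'   \item{`isd_lite`}{NOAA ISD-Lite fixed-width rows
#'     (`year month day hour temp ...`), temperature in tenths of a degree C
#'     with `-9999` marking a missing hour.}
#' }
#' No regularization is applied: readings may be irregular, duplicated within
#' an hour, or missing. Missing sentinels become `NA` temperatures. Rows are
#' returned sorted by time.
#'
#' @param path Path to the file.
#' @param dialect `"simple_csv"` or `"isd_lite"`.
#' @param station_id Station label attached to every row (defaults to the
#'   file name without extension).
#' @return A tibble with columns `station_id`, `time` (POSIXct), `temp_c`.
#' @export
read_hourly_table <- function(path, dialect = c("simple_csv", "isd_lite"),
                              station_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("weather file not found: ", path)
  if (is.null(station_id)) {
    station_id <- sub("\\.[^.]*$", "", basename(path))
  }

  if (dialect == "simple_csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      timestamp = readr::col_character(),
      temp_c = readr::col_double()
    ), progress = FALSE)
    if (nrow(raw) == 0L) stop("empty weather file: ", path)
    time <- suppressWarnings(readr::parse_datetime(raw$timestamp))
    attr(time, "tzone") <- "UTC"
    bad <- which(is.na(time))
    if (length(bad) > 0L) {
      stop("unparseable timestamp at data line ", bad[1L], " of ", path)
    }
    out <- tibble::tibble(station_id = station_id, time = time,
                          temp_c = raw$temp_c)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty weather file: ", path)
    fields <- strsplit(trimws(lines), "\\s+")
    nf <- vapply(fields, length, integer(1))
    bad <- which(nf < 5L)
    if (length(bad) > 0L) {
      stop("unparseable ISD-Lite row at line ", bad[1L], " of ", path)
    }
    num <- function(k) suppressWarnings(
      vapply(fields, function(f) as.numeric(f[[k]]), numeric(1)))
    yr <- num(1); mo <- num(2); dy <- num(3); hr <- num(4); tmp <- num(5)
    bad <- which(is.na(yr) | is.na(mo) | is.na(dy) | is.na(hr))
    if (length(bad) > 0L) {
      stop("unparseable ISD-Lite row at line ", bad[1L], " of ", path)
    }
    time <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:00:00", yr, mo, dy, hr),
                       tz = "UTC")
    temp_c <- ifelse(is.na(tmp) | tmp == -9999, NA_real_, tmp / 10)
    out <- tibble::tibble(station_id = station_id, time = time, temp_c = temp_c)
  }
  dplyr::arrange(out, .data$time)
}

# Lengths of runs of NA in x, returned as (start index, length) pairs.
na_runs <- function(x) {
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Regularize an hourly weather series
#'
#' Collapses the raw record to exactly one value per clock hour and season.
#' A reading at clock time `[h:00, h+1:00)` belongs to hour `h`; multiple
#' readings within an hour are averaged. Hours outside the 01 Oct--30 Jun
#' season window are dropped. Within each season, gaps of at most `max_gap_h`
#' consecutive missing hours are filled by linear interpolation (constant
#' extension at season edges) and flagged `imputed`; a season with any longer
#' gap, or with more than `max_imputed_frac` of its hours imputed, is flagged
#' invalid and is skipped by the simulator.
#'
#' The operation is idempotent: regularizing an already-regular series changes
#' nothing, and previously assigned `imputed` flags are preserved.
#'
#' @param w Tibble from [read_hourly_table()] or [gen_weather()] with columns
#'   `station_id`, `time`, `temp_c` (and optionally `imputed`).
#' @param max_gap_h Longest gap (consecutive missing hours) that may be
#'   interpolated; default 6.
#' @param max_imputed_frac Largest tolerated fraction of imputed hours per
#'   season; default 0.05.
#' @return A tibble with columns `station_id`, `season_year`, `time`,
#'   `temp_c`, `imputed`, carrying a `seasons` attribute (see
#'   [season_status()]) with per-season validity.
#' @export
regularize_hourly <- function(w, max_gap_h = 6L, max_imputed_frac = 0.05) {
  stopifnot(all(c("station_id", "time", "temp_c") %in% names(w)))
  if (nrow(w) == 0L) stop("empty weather series")
  if (!"imputed" %in% names(w)) w$imputed <- FALSE

  hour <- as.POSIXct(floor(as.numeric(w$time) / 3600) * 3600,
                     origin = "1970-01-01", tz = "UTC")
  hourly <- tibble::tibble(station_id = w$station_id, time = hour,
                           temp_c = w$temp_c, imputed = w$imputed) |>
    dplyr::group_by(.data$station_id, .data$time) |>
    dplyr::summarise(
      temp_c = if (all(is.na(.data$temp_c))) NA_real_ else
        mean(.data$temp_c, na.rm = TRUE),
      imputed = any(.data$imputed),
      .groups = "drop"
    )
  hourly$season_year <- season_year_of(hourly$time)
  hourly <- hourly[!is.na(hourly$season_year), , drop = FALSE]
  if (nrow(hourly) == 0L) stop("no observations fall inside a 01 Oct-30 Jun season")

  pieces <- split(hourly,
                  interaction(hourly$station_id, hourly$season_year, drop = TRUE))
  out <- vector("list", length(pieces))
  status <- vector("list", length(pieces))

  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    sy <- p$season_year[1L]
    sb <- season_bounds(sy)
    grid <- seq(sb$start, sb$end, by = 3600)
    full <- tibble::tibble(
      station_id = p$station_id[1L], season_year = sy, time = grid)
    full <- dplyr::left_join(full, p[, c("time", "temp_c", "imputed")],
                             by = "time")
    full$imputed[is.na(full$imputed)] <- TRUE

    runs <- na_runs(full$temp_c)
    max_gap <- if (nrow(runs) == 0L) 0L else max(runs$length)
    obs <- which(!is.na(full$temp_c))
    if (length(obs) >= 2L && max_gap <= max_gap_h) {
      filled <- stats::approx(x = as.numeric(full$time[obs]),
                              y = full$temp_c[obs],
                              xout = as.numeric(full$time),
                              rule = 2)$y
      full$temp_c <- filled
    }
    n_imp <- sum(full$imputed)
    frac_imp <- n_imp / nrow(full)
    valid <- length(obs) >= 2L && max_gap <= max_gap_h &&
      frac_imp <= max_imputed_frac && all(is.finite(full$temp_c))
    out[[i]] <- full
    status[[i]] <- tibble::tibble(
      station_id = full$station_id[1L], season_year = sy,
      n_hours = nrow(full), n_imputed = n_imp,
      frac_imputed = frac_imp, max_gap_h = max_gap, valid = valid)
  }

  res <- dplyr::bind_rows(out)
  res <- dplyr::arrange(res, .data$station_id, .data$time)
  attr(res, "seasons") <- dplyr::bind_rows(status) |>
    dplyr::arrange(.data$station_id, .data$season_year)
  res
}

#' Per-season validity of a regularized weather series
#'
#' @param w A series returned by [regularize_hourly()].
#' @return Tibble with one row per station x season: `n_hours`, `n_imputed`,
#'   `frac_imputed`, `max_gap_h`, `valid`.
#' @export
season_status <- function(w) {
  st <- attr(w, "seasons")
  if (is.null(st)) stop("weather series has no season status; run regularize_hourly() first")
  st
}

# Extract one valid season for a station; errors if absent or invalid.
season_slice <- function(w, season_year, station_id = NULL) {
  st <- season_status(w)
  if (is.null(station_id)) {
    ids <- unique(w$station_id)
    if (length(ids) != 1L) stop("multiple stations present; supply station_id")
    station_id <- ids
  }
  row <- st[st$station_id == station_id & st$season_year == season_year, ]
  if (nrow(row) == 0L) stop("no season ", season_year, " for station ", station_id)
  if (!row$valid) stop("season ", season_year, " at ", station_id,
                       " is flagged invalid (gaps or excessive imputation)")
  w[w$station_id == station_id & w$season_year == season_year, , drop = FALSE]
}
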
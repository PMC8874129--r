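# Independent oracles and fixture builders used across the suite.

# Normal-equations least squares, independent of lm(): solves X'X beta = X'y.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(b = beta[1L], m = beta[2L])
}

# Naive per-hour loop for chill hours (< 7.2 C, strict).
chill_loop_oracle <- function(temp_c) {
  total <- integer(length(temp_c))
  acc <- 0L
  for (i in seq_along(temp_c)) {
    if (temp_c[i] < 7.2) acc <- acc + 1L
    total[i] <- acc
  }
  total
}

# Naive per-hour loop for GDH above a base temperature.
gdh_loop_oracle <- function(temp_c, tb_c) {
  total <- numeric(length(temp_c))
  acc <- 0
  for (i in seq_along(temp_c)) {
    acc <- acc + max(temp_c[i] - tb_c, 0)
    total[i] <- acc
  }
  total
}

# Regularized single-season weather series with temperatures supplied either
# as a constant or as a function of the hour index (1-based).
make_season_weather <- function(temp, season_year = 2000,
                                station_id = "TEST") {
  sb <- season_bounds(season_year)
  grid <- seq(sb$start, sb$end, by = 3600)
  temps <- if (is.function(temp)) temp(seq_along(grid)) else
    rep_len(temp, length(grid))
  raw <- tibble::tibble(station_id = station_id, time = grid, temp_c = temps)
  regularize_hourly(raw)
}

# Write a small simple_csv weather file and return its path.
write_simple_csv <- function(times, temps, path = tempfile(fileext = ".csv")) {
  writeLines(c("timestamp,temp_c",
               paste0(format(times, "%Y-%m-%dT%H:%M:%S"), ",", temps)), path)
  path
}
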
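test_that("chill hours count strictly sub-7.2 C hours from the season anchor", {
  w <- make_season_weather(5.0)
  ch <- chill_hours(w, 2000)
  expect_equal(ch$chill_h[100], 100L)
  expect_equal(diff(ch$chill_h), rep(1L, nrow(ch) - 1L))

  # the boundary temperature contributes nothing (strict inequality)
  w72 <- make_season_weather(7.2)
  expect_equal(max(chill_hours(w72, 2000)$chill_h), 0L)
})

test_that("chill accumulation and threshold crossing match the loop oracle", {
  temps <- withr::with_seed(7, {
    base <- 8 - 6 * cos(2 * pi * (seq_len(6552) / 6552))
    e <- stats::filter(rnorm(6552, 0, 1.5), 0.8, method = "recursive")
    base + as.numeric(e)
  })
  w <- make_season_weather(function(i) temps[i])
  ch <- chill_hours(w, 2000)
  expect_equal(ch$chill_h, chill_loop_oracle(w$temp_c))

  for (thr in c(500, 750, 1000)) {
    got <- chill_threshold_time(w, 2000, thr)
    oracle_idx <- which(chill_loop_oracle(w$temp_c) >= thr)[1]
    if (is.na(oracle_idx)) expect_true(is.na(got)) else
      expect_equal(got, w$time[oracle_idx] + 3600)
  }
})

test_that("a season that never cools below 7.2 C reaches no threshold", {
  w <- make_season_weather(15)
  expect_true(is.na(chill_threshold_time(w, 2000, 500)))
})

test_that("GDH accumulates max(T - Tb, 0) per hour with a zero floor", {
  w <- make_season_weather(12)
  start <- season_bounds(2000)$start
  g <- accumulate_gdh(w, 2000, start, tb_c = 2.0)
  expect_equal(g$gdh[700], 7000)
  expect_equal(diff(g$gdh), rep(10, nrow(g) - 1L))

  cold <- make_season_weather(1.5)
  expect_equal(max(accumulate_gdh(cold, 2000, start, 2.0)$gdh), 0)

  # alternating 12-h blocks of 0 and 10 C with tb 2 -> 96 degree-hours per day
  alt <- make_season_weather(function(i) ifelse(((i - 1) %/% 12) %% 2 == 0, 0, 10))
  g3 <- accumulate_gdh(alt, 2000, start, 2.0)
  expect_equal(g3$gdh[240], 96 * 10)
})

test_that("bud break under constant temperature matches the closed form", {
  w <- make_season_weather(12)
  start <- season_bounds(2000)$start
  bb <- budbreak_time(w, 2000, start, hr_traits(2.0, 7000))
  expect_equal(as.numeric(difftime(bb, start, units = "hours")), 700)

  # unreachable requirement before 30 June -> absent
  expect_true(is.na(budbreak_time(w, 2000, start, hr_traits(11.5, 7000))))
})

test_that("bud break is monotone in theta and in Tb", {
  w <- regularize_hourly(gen_weather(n_seasons = 2, seed = 21))
  start <- chill_threshold_time(w, 1990, 500)
  for (tb in c(0, 2.2, 5)) {
    bbs <- vapply(c(3000, 5000, 7000, 9000), function(th)
      as.numeric(budbreak_time(w, 1990, start, hr_traits(tb, th))),
      numeric(1))
    expect_true(all(diff(bbs) >= 0))
  }
  for (th in c(5000, 9000)) {
    bbs <- vapply(c(-1, 1, 3, 5), function(tb)
      as.numeric(budbreak_time(w, 1990, start, hr_traits(tb, th))),
      numeric(1))
    expect_true(all(diff(bbs) >= 0))
  }
})

test_that("GDH is additive over disjoint hour ranges", {
  w <- regularize_hourly(gen_weather(n_seasons = 1, seed = 5))
  start <- season_bounds(1990)$start
  mid <- start + 2000 * 3600
  g_all <- accumulate_gdh(w, 1990, start, 3.0)
  g_head <- g_all$gdh[g_all$time_end == mid]
  g_tail <- accumulate_gdh(w, 1990, mid, 3.0)
  expect_equal(g_head + max(g_tail$gdh), max(g_all$gdh), tolerance = 1e-9)
})

test_that("compare_traits reproduces per-season loop simulation", {
  w <- regularize_hourly(gen_weather(n_seasons = 10, seed = 13))
  scen <- peach_hr_scenarios()
  res <- compare_traits(w, scenarios = scen)

  # identity: the reference scenario has exactly zero delay everywhere
  self <- res[res$tb_c == 2.2 & res$theta_ch == 7000, ]
  expect_true(all(self$delay_days == 0))

  # every cell equals an independent per-season loop re-simulation
  for (k in sample(seq_len(nrow(res)), 20)) {
    row <- res[k, ]
    s <- w[w$season_year == row$season_year, ]
    chl <- chill_loop_oracle(s$temp_c)
    ci <- which(chl >= row$chill_threshold_h)[1]
    start_t <- s$time[ci] + 3600
    idx <- which(s$time >= start_t)
    gd <- gdh_loop_oracle(s$temp_c[idx], row$tb_c)
    bi <- which(gd >= row$theta_ch)[1]
    expect_equal(row$budbreak_at, s$time[idx[bi]] + 3600)
  }
})

test_that("delay summaries and signed-rank tests cover completing seasons", {
  w <- regularize_hourly(gen_weather(n_seasons = 8, seed = 2))
  res <- compare_traits(w, thresholds = c(500, 750),
                        scenarios = peach_hr_scenarios())
  smry <- summarise_trait_delays(res)
  expect_true(all(smry$min_delay_days <= smry$median_delay_days &
                    smry$median_delay_days <= smry$max_delay_days))
  tst <- test_trait_delays(res)
  self <- tst[tst$tb_c == 2.2 & tst$theta_ch == 7000, ]
  expect_true(all(self$p_value == 1))
  expect_true(all(tst$p_value >= 0 & tst$p_value <= 1))
})

test_that("the midnight GDH-start dialect starts at the crossing day's 00:00", {
  w <- make_season_weather(function(i) ifelse(i <= 600, 5, 15))
  resH <- compare_traits(w, thresholds = 500,
                         scenarios = data.frame(tb_c = 2.2, theta_ch = 7000),
                         gdh_start = "hour")
  resM <- compare_traits(w, thresholds = 500,
                         scenarios = data.frame(tb_c = 2.2, theta_ch = 7000),
                         gdh_start = "midnight")
  # the crossing falls mid-day; the midnight dialect accumulates from 00:00
  # of that day, so bud break can only be earlier, by less than a day
  expect_lte(as.numeric(resM$budbreak_at), as.numeric(resH$budbreak_at))
  expect_lt(as.numeric(difftime(resH$budbreak_at, resM$budbreak_at,
                                units = "hours")), 24)
})
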
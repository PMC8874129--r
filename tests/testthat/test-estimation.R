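test_that("bud-break fractions are the direct ratio and validate their input", {
  expect_equal(bud_break_fraction(c(10, 60, 100), 100), c(0.1, 0.6, 1.0))
  expect_equal(bud_break_fraction(c(0, 0, 0), 120), c(0, 0, 0))
  expect_equal(bud_break_fraction(50, 100), 0.5)
  expect_error(bud_break_fraction(c(10, 5), 100), "non-decreasing")
  expect_error(bud_break_fraction(10, 0), "n_initial")
  expect_error(bud_break_fraction(101, 100), "exceeds")
})

test_that("hours_to_half interpolates the first bracketing pair", {
  expect_equal(hours_to_half(c(96, 120), c(0.4, 0.6)), 108)
  expect_equal(hours_to_half(c(48, 72, 96), c(0.1, 0.5, 0.9)), 72)  # exact hit
  expect_true(is.na(hours_to_half(c(100, 200, 300), c(0.2, 0.4, 0.45))))
  # crossing before the first observation interpolates from the origin
  expect_equal(hours_to_half(c(100), c(1.0)), 50)
})

test_that("uniformly faster bud break never increases hours_to_half", {
  hours <- seq(24, 480, by = 48)
  for (seed in 1:20) {
    f <- withr::with_seed(seed, sort(runif(length(hours))))
    shift <- c(f[-1], 1)  # every fraction reached one observation earlier
    t1 <- hours_to_half(hours, f)
    t2 <- hours_to_half(hours, shift)
    if (!is.na(t1) && !is.na(t2)) expect_lte(t2, t1)
  }
})

test_that("noise-free rates invert exactly to the generating traits", {
  temps <- c(11.8, 13.6, 15.9, 17.8, 20.1)
  fit <- fit_rate_response(temps, (temps - 4.0) / 5000, n_boot = 0)
  expect_equal(fit$tb_c, 4.0, tolerance = 1e-12)
  expect_equal(fit$theta_ch, 5000, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_identical(fit$status, "ok")
})

test_that("fit_rate_response matches the normal-equations oracle with noise", {
  temps <- c(11.8, 13.6, 15.9, 17.8, 20.1)
  rates <- (temps - 4.0) / 5000 +
    withr::with_seed(42, rnorm(5, 0, 5e-5))
  fit <- fit_rate_response(temps, rates, n_boot = 0)
  or <- ols_oracle(temps, rates)
  expect_equal(fit$m, or[["m"]], tolerance = 1e-10)
  expect_equal(fit$b, or[["b"]], tolerance = 1e-10)
  expect_equal(fit$tb_c, -or[["b"]] / or[["m"]], tolerance = 1e-10)
  expect_error(fit_rate_response(temps[1:2], rates[1:2]), "insufficient")
})

test_that("bootstrap and delta intervals bracket the point estimates coherently", {
  temps <- c(11.8, 13.6, 15.9, 17.8, 20.1)
  rates <- (temps - 3.0) / 6000 + withr::with_seed(9, rnorm(5, 0, 4e-5))
  bs <- fit_rate_response(temps, rates, n_boot = 500, boot_seed = 7)
  dl <- fit_rate_response(temps, rates, n_boot = 1, ci_method = "delta")
  for (f in list(bs, dl)) {
    expect_lt(f$tb_lo, f$tb_c); expect_gt(f$tb_hi, f$tb_c)
    expect_lt(f$theta_lo, f$theta_ch); expect_gt(f$theta_hi, f$theta_ch)
  }
  # seeded bootstrap is reproducible
  bs2 <- fit_rate_response(temps, rates, n_boot = 500, boot_seed = 7)
  expect_identical(bs, bs2)
})

test_that("a negative rate-temperature slope is flagged invalid", {
  temps <- c(12, 14, 16, 18, 20)
  fit <- fit_rate_response(temps, rev(temps) / 1e4, n_boot = 0)
  expect_identical(fit$status, "invalid_slope")
})

test_that("estimate_accession composes interpolation, exclusion and the fit", {
  full <- gen_forcing_experiment(4, 5000, theta_cv = 0.1, seed = 3,
                                 accession = "OK1")
  est <- estimate_accession(full, n_boot = 0)
  expect_identical(est$status, "ok")
  expect_equal(est$n_points, 5L)
  expect_gt(est$r_squared, 0.95)

  # base temperature above every chamber: never reaches half anywhere
  cold <- gen_forcing_experiment(25, 5000, seed = 4, accession = "NV1")
  expect_identical(estimate_accession(cold)$status, "excluded_below_half")

  # only two temperatures reach half -> insufficient
  two <- full[full$temp_c %in% c(11.8, 13.6), ]
  expect_identical(estimate_accession(two)$status, "insufficient_temperatures")
})

test_that("the Tb-theta relationship is recovered and predicts on the line", {
  theta <- c(2500, 4000, 6000, 9000, 12000)
  curve <- fit_tb_theta_curve(10 - 1 * log(theta), theta)
  expect_equal(curve$a, 10, tolerance = 1e-10)
  expect_equal(curve$c, -1, tolerance = 1e-10)
  expect_equal(predict(curve, exp(10)), 0, tolerance = 1e-9)
  expect_error(fit_tb_theta_curve(c(1, 2), c(3000, 5000)), ">= 3")
  expect_error(fit_tb_theta_curve(c(1, 2, 3), c(3000, -1, 5000)), "positive")
})

test_that("correlate matches the closed-form Pearson formula", {
  expect_equal(correlate(1:10, 2 * (1:10))$r, 1.0)
  x <- c(-1, 1, -1, 1); y <- c(-1, -1, 1, 1)
  expect_equal(correlate(x, y)$r, 0.0)
  xy <- withr::with_seed(5, list(x = rnorm(50), y = rnorm(50)))
  r_direct <- sum((xy$x - mean(xy$x)) * (xy$y - mean(xy$y))) /
    sqrt(sum((xy$x - mean(xy$x))^2) * sum((xy$y - mean(xy$y))^2))
  expect_equal(correlate(xy$x, xy$y)$r, r_direct, tolerance = 1e-12)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
})
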
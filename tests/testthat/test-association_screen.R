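test_that("OLS agrees with the normal-equations oracle on random instances", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:40, 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    y <- runif(1, -5, 5) * x + rnorm(n, sd = runif(1, 0.1, 5))
    f <- fit_linear(as_paired_series(x, y))
    o <- ols_oracle(x, y)
    expect_equal(unname(f$coefficients["slope"]), unname(o["slope"]),
                 tolerance = 1e-10)
    expect_equal(unname(f$coefficients["intercept"]), unname(o["intercept"]),
                 tolerance = 1e-10)
    expect_equal(f$r, cor(x, y), tolerance = 1e-12)
    expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("hand-derived small fits come out exactly", {
  # normal equations by hand: Sxy = 5, Sxx = 2 -> slope 2.5, intercept -2/3
  f <- fit_linear(as_paired_series(c(1, 2, 3), c(2, 4, 7)))
  expect_equal(unname(f$coefficients["slope"]), 2.5, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["intercept"]), -2 / 3, tolerance = 1e-12)

  f2 <- fit_linear(as_paired_series(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(unname(f2$coefficients), c(1, 0), tolerance = 1e-12)
  expect_equal(f2$r, 1)
  expect_equal(f2$r_squared, 1)
  expect_equal(f2$p_value, 0)

  expect_error(fit_linear(as_paired_series(c(2, 2, 2), c(1, 2, 3))),
               "degenerate predictor")
})

test_that("sign of r follows the slope and slope/intercept transform correctly", {
  set.seed(7)
  x <- runif(20, 1, 5)
  y <- -2 * x + rnorm(20, sd = 0.5)
  f <- fit_linear(as_paired_series(x, y))
  expect_true(f$r < 0 && f$coefficients["slope"] < 0)
  # shifting y moves only the intercept
  f_shift <- fit_linear(as_paired_series(x, y + 10))
  expect_equal(unname(f_shift$coefficients["slope"]),
               unname(f$coefficients["slope"]), tolerance = 1e-12)
  expect_equal(unname(f_shift$coefficients["intercept"]),
               unname(f$coefficients["intercept"]) + 10, tolerance = 1e-10)
  # scaling x by c > 0 divides the slope by c, leaves r and p unchanged
  f_scale <- fit_linear(as_paired_series(3 * x, y))
  expect_equal(unname(f_scale$coefficients["slope"]),
               unname(f$coefficients["slope"]) / 3, tolerance = 1e-12)
  expect_equal(f_scale$r, f$r, tolerance = 1e-12)
  expect_equal(f_scale$p_value, f$p_value, tolerance = 1e-12)
})

test_that("non-linear trendline families recover their own exact signals", {
  x <- 1:5
  f_exp <- fit_trend(as_paired_series(x, exp(x)), "exponential")
  expect_equal(f_exp$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(f_exp$coefficients["rate"]), 1, tolerance = 1e-10)

  f_log <- fit_trend(as_paired_series(x, 3 * log(x) + 1), "logarithmic")
  expect_equal(f_log$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(f_log$coefficients["slope"]), 3, tolerance = 1e-10)

  f_poly <- fit_trend(as_paired_series(1:4, (1:4)^2), "polynomial2")
  expect_equal(unname(f_poly$coefficients["quadratic"]), 1, tolerance = 1e-8)
  expect_equal(f_poly$r_squared, 1, tolerance = 1e-12)
})

test_that("inapplicable families are skipped with a recorded reason", {
  s <- as_paired_series(c(1, 2, 3), c(0, 1, 2))   # y contains 0
  out <- fit_trend(s, "exponential")
  expect_s3_class(out, "family_inapplicable")
  expect_match(out$reason, "y > 0")

  s2 <- as_paired_series(c(0, 1, 2), c(1, 2, 3))  # x contains 0
  expect_s3_class(fit_trend(s2, "logarithmic"), "family_inapplicable")

  s3 <- as_paired_series(c(1, 2, 3), c(1, 2, 3))  # n = 3 < 4
  expect_s3_class(fit_trend(s3, "polynomial2"), "family_inapplicable")
})

test_that("correlation p value matches the t transform and its limits", {
  # t = 0.5 * sqrt(8) / sqrt(0.75) = 1.6330, 8 df (tabulated oracle)
  expect_equal(correlation_p_value(0.5, 10), 0.1411133, tolerance = 1e-6)
  expect_equal(correlation_p_value(0, 10), 1)
  expect_equal(correlation_p_value(1, 10), 0)
  expect_equal(correlation_p_value(-1, 10), 0)
  # the study's kidney-mass correlation: r = 0.73 at n = 27 gives p < 0.01
  expect_lt(correlation_p_value(0.73, 27), 0.01)
  expect_error(correlation_p_value(0.5, 2), "insufficient")
})

test_that("correlation p value is monotone in |r| and in n", {
  rs <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(rs, correlation_p_value, numeric(1), n = 15)
  expect_true(all(diff(ps) < 0))
  ns <- c(5, 10, 20, 50, 100, 500)
  pn <- vapply(ns, function(n) correlation_p_value(0.4, n), numeric(1))
  expect_true(all(diff(pn) < 0))
  # symmetric in the sign of r
  expect_equal(correlation_p_value(-0.6, 20), correlation_p_value(0.6, 20))
})

test_that("screening gate admits strong linear signal and rejects noise", {
  tab <- toy_table(n = 27, seed = 3, noise_sd = 1.2)
  dec_sig <- screen_variable(tab, "marker_signal")
  expect_true(dec_sig$passed)
  expect_equal(dec_sig$chosen$family, "linear")
  dec_null <- screen_variable(tab, "marker_noise")
  expect_false(dec_null$passed)
  expect_null(dec_null$chosen)
})

test_that("fixture screening matches the study's reported correlations", {
  tab <- load_fixture()
  dec_cc <- screen_variable(tab, "cystatin_c_serum")
  expect_false(dec_cc$passed)
  dec_bun <- screen_variable(tab, "bun")
  expect_true(dec_bun$passed)
  expect_equal(dec_bun$chosen$family, "linear")
  dec_km <- screen_variable(tab, "kidney_mass")
  expect_true(dec_km$passed)
  expect_equal(round(dec_km$linear$r, 2), 0.73)
})

test_that("screen_all passes exactly the five reported variables", {
  tab <- load_fixture()
  screen <- screen_all(tab)
  expect_setequal(passing_variables(screen),
                  c("kidney_mass", "kidney_body_ratio", "bun", "scr",
                    "il18_urine"))
  expect_setequal(passing_variables(screen, c("serum", "urine")),
                  c("bun", "scr", "il18_urine"))
})

test_that("gate configuration is honoured", {
  tab <- load_fixture()
  # on the printed data the linear r for SCr (0.662) is below 0.7, so a
  # strictly linear gate rejects it while the best-family gate keeps it
  strict <- screen_variable(tab, "scr", gate_on = "linear")
  expect_false(strict$passed)
  # an over-strict threshold empties the gate
  screen <- screen_all(tab, r_min = 0.99)
  expect_length(passing_variables(screen), 0)
})
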
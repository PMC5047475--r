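test_that("fixture screen yields the three-biomarker equation family", {
  screen <- screen_all(load_fixture())
  eqs <- equations_from_screen(screen)
  expect_setequal(vapply(eqs, `[[`, character(1), "variable"),
                  c("bun", "scr", "il18_urine"))
  slopes <- vapply(eqs, `[[`, numeric(1), "slope")
  # published rows: 0.95 BUN, 53.63 SCr, 1368 IL-18 (printed rounding; the
  # SCr row lands one unit of the last digit away on the printed data)
  expect_equal(unname(slopes["bun"]), 0.95, tolerance = 0.005)
  expect_equal(unname(slopes["scr"]), 53.63, tolerance = 4e-4)
  expect_equal(unname(slopes["il18_urine"]), 1368, tolerance = 5e-4)
  expect_error(equations_from_screen(screen, eligible_fluids = "unknown"),
               "empty calculator")
  # kidney mass also clears the gate but is excluded by fluid eligibility
  mass_eqs <- equations_from_screen(screen, eligible_fluids = "tissue")
  expect_equal(vapply(mass_eqs, `[[`, character(1), "variable"),
               c(kidney_mass = "kidney_mass"))
})

test_that("signal averaging reproduces the published composite exactly", {
  calc <- signal_average(published_equations())
  expect_equal(unname(calc$coefficients["il18_urine"]), 1368 / 3)
  expect_identical(1368 / 3, 456)
  expect_equal(round(unname(calc$coefficients["bun"]), 2), 0.32)
  expect_equal(round(unname(calc$coefficients["scr"]), 1), 17.9)
  expect_equal(calc$intercept, (-8.15 - 9.66 + 11.27) / 3)
  expect_equal(round(calc$intercept, 2), -2.18)
})

test_that("signal averaging is plain equal-weight arithmetic", {
  eqs <- list(linear_equation("a", 3, 1), linear_equation("b", 6, 5))
  calc <- signal_average(eqs)
  expect_equal(unname(calc$coefficients), c(1.5, 3))
  expect_equal(calc$intercept, 3)
  # averaging k copies of one equation reproduces that equation
  same <- signal_average(list(linear_equation("a", 2.5, -1)))
  expect_equal(unname(same$coefficients), 2.5)
  expect_equal(same$intercept, -1)
  expect_error(signal_average(list(linear_equation("a", 1, 0),
                                   linear_equation("a", 2, 0))),
               "duplicate")
})

test_that("composite prediction equals the mean of component predictions", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    eqs <- lapply(seq_len(k), function(j)
      linear_equation(paste0("v", j), runif(1, -10, 10), runif(1, -20, 20)))
    calc <- signal_average(eqs)
    panel <- stats::setNames(runif(k, 0, 50), paste0("v", seq_len(k)))
    p <- predict_ci(calc, panel)
    expect_equal(as.numeric(p), mean(attr(p, "components")),
                 tolerance = 1e-12)
    by_hand <- mean(vapply(eqs, function(eq)
      evaluate_equation(eq, panel[[eq$variable]]), numeric(1)))
    expect_equal(as.numeric(p), by_hand, tolerance = 1e-12)
  }
})

test_that("component order never changes the composite", {
  eqs <- list(linear_equation("a", 1, 0), linear_equation("b", 2, 3),
              linear_equation("c", -4, 7))
  calc1 <- signal_average(eqs)
  calc2 <- signal_average(rev(eqs))
  panel <- c(a = 1.5, b = 2.5, c = 0.5)
  expect_equal(as.numeric(predict_ci(calc1, panel)),
               as.numeric(predict_ci(calc2, panel)), tolerance = 1e-14)
  expect_equal(calc1$intercept, calc2$intercept)
})

test_that("predictions are affine in each input", {
  calc <- signal_average(published_equations())
  base <- c(bun = 30, scr = 0.5, il18_urine = 0.005)
  p0 <- as.numeric(predict_ci(calc, base))
  bumped <- base; bumped["bun"] <- 2 * base["bun"]
  p1 <- as.numeric(predict_ci(calc, bumped))
  expect_equal(p1 - p0, unname(calc$coefficients["bun"] * base["bun"]),
               tolerance = 1e-12)
})

test_that("published calculator applied to the first study animal", {
  calc <- signal_average(published_equations())
  panel <- c(bun = 36, scr = 0.61, il18_urine = 0.005328081)
  p <- predict_ci(calc, panel)
  # arithmetic oracle on the full-precision average of the three equations:
  # ((0.95*36 - 8.15) + (53.63*0.61 - 9.66) + (1368*0.005328081 + 11.27))/3
  expect_equal(as.numeric(p), 22.55437, tolerance = 1e-5)
  # display-rounded composite gives the familiar 0.32/17.9/456/-2.18 value
  expect_equal(0.32 * 36 + 17.9 * 0.61 + 456 * 0.005328081 - 2.18,
               22.6886, tolerance = 1e-6)
  comps <- attr(p, "components")
  expect_equal(unname(comps["bun"]), 0.95 * 36 - 8.15, tolerance = 1e-12)
  expect_false(attr(p, "out_of_range"))
})

test_that("panel validation and range flagging behave", {
  calc <- signal_average(published_equations())
  expect_error(predict_ci(calc, c(bun = 30)), "scr")
  expect_error(predict_ci(calc, c(bun = 30)), "il18_urine")
  expect_error(predict_ci(calc, c(bun = -1, scr = 0.5, il18_urine = 0.01)),
               "negative")
  zero <- predict_ci(calc, c(bun = 0, scr = 0, il18_urine = 0))
  expect_equal(as.numeric(zero), calc$intercept)
  expect_true(attr(zero, "out_of_range"))  # intercept is negative CI
  big <- predict_ci(calc, c(bun = 500, scr = 10, il18_urine = 1))
  expect_true(attr(big, "out_of_range"))
})

test_that("formula rendering reproduces the published display rounding", {
  calc <- signal_average(published_equations())
  txt <- render_formula(calc)
  expect_match(txt, "0.32", fixed = TRUE)
  expect_match(txt, "17.9", fixed = TRUE)
  expect_match(txt, "456", fixed = TRUE)
  expect_match(txt, "- 2.18", fixed = TRUE)
  # a fixture-derived calculator renders to the same published formula
  derived <- signal_average(equations_from_screen(screen_all(load_fixture())))
  for (tok in c("0.32", "17.9", "456", "2.18"))
    expect_match(render_formula(derived), tok, fixed = TRUE)
  # hand case and singleton identity
  two <- signal_average(list(linear_equation("a", 3, 1, units = "u"),
                             linear_equation("b", 6, 5, units = "u")))
  expect_match(render_formula(two), "1.50", fixed = TRUE)
  expect_match(render_formula(two), "3.00", fixed = TRUE)
  one <- signal_average(list(linear_equation("X", 1, 0, units = "u")))
  expect_match(render_formula(one), "(1.00*X (u))", fixed = TRUE)
  expect_match(render_formula(one), "+ 0.00", fixed = TRUE)
})

test_that("calculator JSON serialization round-trips at full precision", {
  derived <- signal_average(equations_from_screen(screen_all(load_fixture())))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  calculator_to_json(derived, f)
  back <- calculator_from_json(f)
  expect_equal(back$coefficients, derived$coefficients, tolerance = 1e-14)
  expect_equal(back$intercept, derived$intercept, tolerance = 1e-14)
  panel <- c(bun = 25, scr = 0.5, il18_urine = 0.004)
  expect_equal(as.numeric(predict_ci(back, panel)),
               as.numeric(predict_ci(derived, panel)), tolerance = 1e-12)
})
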
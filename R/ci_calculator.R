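#' A univariate linear equation for cystic index
#'
#' Represents CI = slope * x + intercept for one biomarker, with optional
#' provenance (fit n, r, p) carried along from the screening step.
#'
#' @param variable biomarker name
#' @param slope CI percent per unit of the variable
#' @param intercept CI percent
#' @param units units of the variable
#' @param n,r,p optional fit provenance
#' @return An object of class `linear_equation`.
#' @export
linear_equation <- function(variable, slope, intercept, units = "unspecified",
                            n = NA_integer_, r = NA_real_, p = NA_real_) {
  stopifnot(is.character(variable), length(variable) == 1,
            is.finite(slope), is.finite(intercept))
  structure(list(variable = variable, slope = slope, intercept = intercept,
                 units = units, n = n, r = r, p = p),
            class = "linear_equation")
}

#' Evaluate a univariate CI equation
#' @param equation a `linear_equation`
#' @param x biomarker value(s)
#' @return predicted CI percent(s)
#' @export
evaluate_equation <- function(equation, x) {
  stopifnot(inherits(equation, "linear_equation"))
  equation$slope * x + equation$intercept
}

#' @export
print.linear_equation <- function(x, ...) {
  cat(sprintf("CI = %.6g * %s (%s) %+.6g\n", x$slope, x$variable, x$units,
              x$intercept))
  invisible(x)
}

#' Extract the calculator's component equations from a screen
#'
#' One linear equation (full-precision OLS slope and intercept) per passing
#' variable whose fluid is eligible. By default only serum and urine
#' biomarkers feed the calculator: kidney mass and kidney/body-mass ratio
#' also pass the gate on the study data, but an index that requires the
#' excised kidney defeats the purpose of a non-invasive calculator.
#'
#' @param screen a `ci_screen` from [screen_all()]
#' @param eligible_fluids fluids admitted to the calculator
#' @return list of `linear_equation`
#' @export
equations_from_screen <- function(screen, eligible_fluids = c("serum", "urine")) {
  stopifnot(inherits(screen, "ci_screen"))
  vars <- passing_variables(screen, eligible_fluids)
  if (!length(vars))
    stop("empty calculator: no biomarker passed the screening gate",
         call. = FALSE)
  lapply(unclass(screen)[vars], function(d) {
    cf <- d$chosen$coefficients
    linear_equation(d$variable, unname(cf["slope"]), unname(cf["intercept"]),
                    units = if (is.null(d$units)) "unspecified" else d$units,
                    n = d$chosen$n, r = d$chosen$r, p = d$chosen$p_value)
  })
}

#' The published equation family for the PCK rat study
#'
#' The three univariate CI equations as printed in the source study's
#' equation table (coefficients at printed rounding): CI from BUN, from
#' serum creatinine, and from 24-h urine IL-18. Useful as a reference input
#' for the signal-averaging step and as a cross-check against the
#' fixture-derived fits.
#'
#' @return list of three `linear_equation`
#' @export
published_equations <- function() {
  list(
    bun = linear_equation("bun", 0.95, -8.15, units = "mg/dL", n = 27L),
    scr = linear_equation("scr", 53.63, -9.66, units = "mg/dL", n = 27L),
    il18_urine = linear_equation("il18_urine", 1368, 11.27,
                                 units = "ug per 24 h", n = 22L)
  )
}

#' Combine univariate CI equations by signal averaging
#'
#' The composite prediction is the equal-weight arithmetic mean of the k
#' component predictions. Expanded, that is a single linear formula whose
#' coefficient for each biomarker is the component slope divided by k and
#' whose intercept is the mean of the component intercepts; the identity
#' composite(panel) == mean(component predictions) holds exactly.
#'
#' @param equations list of `linear_equation` with distinct variable names
#' @return An object of class `ci_calculator` with fields `components`,
#'   `coefficients` (named vector, slope/k per variable) and `intercept`.
#' @export
signal_average <- function(equations) {
  stopifnot(is.list(equations), length(equations) >= 1,
            all(vapply(equations, inherits, logical(1), "linear_equation")))
  vars <- vapply(equations, `[[`, character(1), "variable")
  if (anyDuplicated(vars))
    stop("duplicate variable names among component equations: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "), call. = FALSE)
  k <- length(equations)
  coefs <- vapply(equations, `[[`, numeric(1), "slope") / k
  names(coefs) <- vars
  intercept <- mean(vapply(equations, `[[`, numeric(1), "intercept"))
  units <- vapply(equations, `[[`, character(1), "units")
  names(units) <- vars
  structure(list(components = equations, coefficients = coefs,
                 intercept = intercept, units = units, k = k),
            class = "ci_calculator")
}

#' Predict cystic index from a biomarker panel
#'
#' Evaluates the composite formula sum(coefficient * value) + intercept.
#' The panel must supply every component variable; values must be
#' non-negative. Predictions outside [0, 100] percent are returned as
#' computed, flagged via the `out_of_range` attribute (no clamping).
#'
#' @param calculator a `ci_calculator`
#' @param panel named numeric vector (or list) of biomarker values
#' @return predicted CI percent, with attributes `components` (the
#'   per-equation univariate predictions) and `out_of_range`.
#' @export
predict_ci <- function(calculator, panel) {
  stopifnot(inherits(calculator, "ci_calculator"))
  panel <- unlist(panel)
  need <- names(calculator$coefficients)
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stop("incomplete panel: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  vals <- panel[need]
  if (anyNA(vals))
    stop("incomplete panel: missing ",
         paste(need[is.na(vals)], collapse = ", "), call. = FALSE)
  if (any(vals < 0))
    stop("negative biomarker value: ",
         paste(need[vals < 0], collapse = ", "), call. = FALSE)
  ci <- sum(calculator$coefficients * vals) + calculator$intercept
  comps <- vapply(calculator$components, function(eq)
    evaluate_equation(eq, panel[[eq$variable]]), numeric(1))
  names(comps) <- need
  structure(ci, components = comps, out_of_range = ci < 0 || ci > 100)
}

# Display rounding matched to the published composite formula: coefficients
# are shown with 2 decimals below 10, 1 decimal in [10, 100), none at or
# above 100 (0.31666... -> 0.32, 17.8766... -> 17.9, 456.0 -> 456).
round_display <- function(x) {
  d <- ifelse(abs(x) >= 100, 0L, ifelse(abs(x) >= 10, 1L, 2L))
  mapply(function(v, dd) formatC(round(v, dd), format = "f", digits = dd),
         x, d)
}

#' Render the composite formula as text
#'
#' @param calculator a `ci_calculator`
#' @param digits "paper" for magnitude-dependent display rounding matching
#'   the published formula, "full" for full precision, or an integer number
#'   of decimals.
#' @return a single formula string, deterministic in component order
#' @export
render_formula <- function(calculator, digits = "paper") {
  stopifnot(inherits(calculator, "ci_calculator"))
  fmt <- function(x) {
    if (identical(digits, "paper")) round_display(x)
    else if (identical(digits, "full")) format(x, digits = 15)
    else formatC(round(x, digits), format = "f", digits = digits)
  }
  terms <- sprintf("(%s*%s (%s))", fmt(calculator$coefficients),
                   names(calculator$coefficients),
                   calculator$units[names(calculator$coefficients)])
  ic <- calculator$intercept
  sprintf("%%CI = %s %s %s", paste(terms, collapse = " + "),
          if (ic < 0) "-" else "+", fmt(abs(ic)))
}

#' @export
print.ci_calculator <- function(x, ...) {
  cat("Composite CI calculator (", x$k, " signal-averaged equations)\n",
      sep = "")
  cat(render_formula(x), "\n")
  invisible(x)
}

#' Serialize a calculator to JSON
#'
#' Full-precision coefficients plus per-component provenance; round-trips
#' with [calculator_from_json()].
#'
#' @param calculator a `ci_calculator`
#' @param path output file
#' @export
calculator_to_json <- function(calculator, path) {
  stopifnot(inherits(calculator, "ci_calculator"))
  doc <- list(
    intercept = calculator$intercept,
    coefficients = as.list(calculator$coefficients),
    components = lapply(calculator$components, function(eq)
      list(variable = eq$variable, slope = eq$slope,
           intercept = eq$intercept, units = eq$units,
           n = eq$n, r = eq$r, p = eq$p))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a calculator back from JSON
#' @param path file written by [calculator_to_json()]
#' @return a `ci_calculator`
#' @export
calculator_from_json <- function(path) {
  doc <- jsonlite::read_json(path)
  eqs <- lapply(doc$components, function(c)
    linear_equation(c$variable, c$slope, c$intercept, units = c$units,
                    n = if (is.null(c$n)) NA_integer_ else as.integer(c$n),
                    r = if (is.null(c$r)) NA_real_ else c$r,
                    p = if (is.null(c$p)) NA_real_ else c$p))
  signal_average(eqs)
}
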
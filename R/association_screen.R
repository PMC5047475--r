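#' Two-tailed p value for a Pearson correlation
#'
#' Uses the exact t transform for a product-moment correlation under the
#' null of no association: t = r * sqrt(n - 2) / sqrt(1 - r^2), referred to
#' a t distribution with n - 2 degrees of freedom. |r| = 1 gives p = 0.
#'
#' @param r correlation in [-1, 1]
#' @param n number of pairs (>= 3)
#' @return two-tailed p value
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(is.numeric(r), is.numeric(n))
  if (n < 3) stop("insufficient data: need n >= 3", call. = FALSE)
  if (abs(r) > 1 + 1e-12) stop("r must lie in [-1, 1]", call. = FALSE)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

new_fit_result <- function(variable, family, coefficients, r_squared, r, n,
                           p_value = correlation_p_value(r, n)) {
  structure(list(variable = variable, family = family,
                 coefficients = coefficients, r_squared = r_squared,
                 r = r, p_value = p_value, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit of CI on %s (n = %d): r = %.3f, r2 = %.3f, p = %.2g\n",
              x$family, x$variable, x$n, x$r, x$r_squared, x$p_value))
  cat("coefficients:", paste(sprintf("%s = %.6g", names(x$coefficients),
                                     x$coefficients), collapse = ", "), "\n")
  invisible(x)
}

#' Ordinary least-squares linear fit of CI on a biomarker
#'
#' Fits y = slope * x + intercept by OLS. `r` is the signed Pearson
#' correlation of x and y (its sign equals the slope's sign), `r_squared`
#' the coefficient of determination, and `p_value` the two-tailed
#' correlation test at n - 2 degrees of freedom.
#'
#' @param series a `paired_series`
#' @return A `fit_result` with `coefficients = c(slope, intercept)`.
#' @export
fit_linear <- function(series) {
  stopifnot(inherits(series, "paired_series"))
  x <- series$x; y <- series$y
  if (stats::sd(x) == 0)
    stop("degenerate predictor: '", series$variable, "' is constant",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  new_fit_result(series$variable, "linear",
                 c(slope = slope, intercept = intercept),
                 r_squared = r^2, r = r, n = series$n)
}

#' Fit one trendline family of CI on a biomarker
#'
#' The four spreadsheet-style trendline families: linear (y on x),
#' exponential (ln y on x, i.e. y = a * exp(b x)), logarithmic (y on ln x),
#' and quadratic polynomial (y on x and x^2). The exponential family is
#' fitted by least squares in log space, matching the trendline convention;
#' its `r_squared` is the coefficient of determination in that fitting
#' space. For the non-linear families `r` is the Pearson correlation
#' between fitted and observed y (non-negative in practice); for the linear
#' family it is the signed correlation of x and y.
#'
#' A family whose domain requirement fails (exponential needs all y > 0,
#' logarithmic all x > 0, polynomial2 needs n >= 4) is reported as
#' inapplicable rather than an error: the returned object has class
#' `family_inapplicable` and carries the reason.
#'
#' @param series a `paired_series`
#' @param family one of "linear", "exponential", "logarithmic", "polynomial2"
#' @return A `fit_result`, or a `family_inapplicable` marker.
#' @export
fit_trend <- function(series,
                      family = c("linear", "exponential", "logarithmic",
                                 "polynomial2")) {
  stopifnot(inherits(series, "paired_series"))
  family <- match.arg(family)
  x <- series$x; y <- series$y
  inapplicable <- function(reason)
    structure(list(variable = series$variable, family = family,
                   reason = reason), class = "family_inapplicable")
  if (family == "linear") return(fit_linear(series))
  if (stats::sd(x) == 0) return(inapplicable("constant predictor"))
  if (family == "exponential") {
    if (any(y <= 0)) return(inapplicable("requires all y > 0"))
    fit <- stats::lm(log(y) ~ x)
    cf <- stats::coef(fit)
    fitted_y <- exp(stats::fitted(fit))
    r <- stats::cor(fitted_y, y)
    return(new_fit_result(series$variable, family,
                          c(scale = unname(exp(cf[1])), rate = unname(cf[2])),
                          r_squared = r_squared_of(fit), r = r,
                          n = series$n))
  }
  if (family == "logarithmic") {
    if (any(x <= 0)) return(inapplicable("requires all x > 0"))
    fit <- stats::lm(y ~ log(x))
    cf <- stats::coef(fit)
    r <- stats::cor(stats::fitted(fit), y)
    return(new_fit_result(series$variable, family,
                          c(slope = unname(cf[2]), intercept = unname(cf[1])),
                          r_squared = r_squared_of(fit), r = r,
                          n = series$n))
  }
  # polynomial2
  if (series$n < 4L) return(inapplicable("needs n >= 4"))
  if (length(unique(x)) < 3L) return(inapplicable("needs >= 3 distinct x"))
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  r <- stats::cor(stats::fitted(fit), y)
  new_fit_result(series$variable, family,
                 c(quadratic = unname(cf[3]), linear = unname(cf[2]),
                   intercept = unname(cf[1])),
                 r_squared = r_squared_of(fit), r = r, n = series$n)
}


# R^2 in the model's fitting space, without summary.lm's perfect-fit warning
r_squared_of <- function(fit) {
  resp <- stats::model.response(stats::model.frame(fit))
  sst <- sum((resp - mean(resp))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}

.family_order <- c("linear", "logarithmic", "exponential", "polynomial2")

#' Screen one variable against cystic index
#'
#' Fits all applicable trendline families, identifies the best-correlating
#' family, and applies the screening gate: the best family's r must reach
#' `r_min` with p below `p_max`, and the linear fit must come within
#' `linear_pref` of the best fit's r (the linear-preference rule — a
#' slightly better curved fit is sacrificed in favor of the linear
#' equation). When the gate passes, the chosen equation is always the
#' linear fit.
#'
#' `gate_on` selects whether the r/p gate is evaluated on the best family's
#' correlation (default, the trendline reading) or strictly on the linear
#' fit's. `pref_mode` selects whether the preference margin is the absolute
#' difference r_best - |r_linear| (default) or that difference relative to
#' r_best.
#'
#' @param table a `study_table`
#' @param variable_name a panel variable
#' @param r_min correlation gate threshold (default 0.7)
#' @param p_max significance gate threshold (default 0.05)
#' @param linear_pref maximum tolerated shortfall of the linear fit's r
#'   behind the best fit's r (default 0.10)
#' @param gate_on "best" or "linear"
#' @param pref_mode "absolute" or "relative"
#' @return An object of class `screen_decision`.
#' @export
screen_variable <- function(table, variable_name, r_min = 0.7, p_max = 0.05,
                            linear_pref = 0.10,
                            gate_on = c("best", "linear"),
                            pref_mode = c("absolute", "relative")) {
  gate_on <- match.arg(gate_on)
  pref_mode <- match.arg(pref_mode)
  series <- paired_series(table, variable_name)
  fits <- lapply(.family_order, function(f) fit_trend(series, f))
  names(fits) <- .family_order
  ok <- !vapply(fits, inherits, logical(1), "family_inapplicable")
  applicable <- fits[ok]
  linear_fit <- fits$linear
  if (inherits(linear_fit, "family_inapplicable"))
    stop("linear fit inapplicable for '", variable_name, "': ",
         linear_fit$reason, call. = FALSE)
  rs <- vapply(applicable, function(f) f$r, numeric(1))
  # ties broken by fixed family order (linear first)
  best <- applicable[[which.max(rs)]]
  r_lin <- abs(linear_fit$r)
  shortfall <- best$r - r_lin
  pref_margin <- if (pref_mode == "absolute") shortfall
                 else if (best$r > 0) shortfall / best$r else 0
  pref_ok <- best$family == "linear" || pref_margin <= linear_pref
  gate_fit <- if (gate_on == "best") best else linear_fit
  passed <- abs(gate_fit$r) >= r_min && gate_fit$p_value < p_max && pref_ok
  idx <- match(variable_name, table$panel$name)
  structure(list(variable = variable_name,
                 fluid = table$panel$fluid[idx],
                 units = table$panel$units[idx],
                 fits = fits,
                 linear = linear_fit,
                 best = best,
                 chosen = if (passed) linear_fit else NULL,
                 passed = passed,
                 linear_preference_applied = passed && best$family != "linear",
                 pref_margin = pref_margin,
                 thresholds = list(r_min = r_min, p_max = p_max,
                                   linear_pref = linear_pref,
                                   gate_on = gate_on, pref_mode = pref_mode)),
            class = "screen_decision")
}

#' @export
print.screen_decision <- function(x, ...) {
  cat(sprintf("%s [%s]: %s (linear r = %.3f, best %s r = %.3f, n = %d)\n",
              x$variable, x$fluid, if (x$passed) "PASS" else "fail",
              x$linear$r, x$best$family, x$best$r, x$linear$n))
  invisible(x)
}

#' Screen every panel variable against cystic index
#'
#' @inheritParams screen_variable
#' @return A list of `screen_decision` (class `ci_screen`), one per panel
#'   variable, in panel order. Use [as.data.frame()] for a summary table.
#' @export
screen_all <- function(table, r_min = 0.7, p_max = 0.05, linear_pref = 0.10,
                       gate_on = c("best", "linear"),
                       pref_mode = c("absolute", "relative")) {
  stopifnot(inherits(table, "study_table"))
  gate_on <- match.arg(gate_on)
  pref_mode <- match.arg(pref_mode)
  decisions <- lapply(table$panel$name, function(v)
    screen_variable(table, v, r_min = r_min, p_max = p_max,
                    linear_pref = linear_pref, gate_on = gate_on,
                    pref_mode = pref_mode))
  names(decisions) <- table$panel$name
  structure(decisions, class = "ci_screen")
}

#' @export
as.data.frame.ci_screen <- function(x, ...) {
  rows <- lapply(unclass(x), function(d) {
    data.frame(variable = d$variable,
               fluid = d$fluid,
               n = d$linear$n,
               slope = unname(d$linear$coefficients["slope"]),
               intercept = unname(d$linear$coefficients["intercept"]),
               r_linear = d$linear$r,
               p_linear = d$linear$p_value,
               best_family = d$best$family,
               r_best = d$best$r,
               p_best = d$best$p_value,
               passed = d$passed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.ci_screen <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Variables passing the screening gate
#'
#' @param screen a `ci_screen` from [screen_all()]
#' @param eligible_fluids restrict to these fluids (default all)
#' @return character vector of passing variable names
#' @export
passing_variables <- function(screen, eligible_fluids = NULL) {
  stopifnot(inherits(screen, "ci_screen"))
  keep <- vapply(unclass(screen), function(d) {
    d$passed && (is.null(eligible_fluids) || d$fluid %in% eligible_fluids)
  }, logical(1))
  names(screen)[keep]
}
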
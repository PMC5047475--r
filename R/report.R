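#' End-to-end derivation report for the study table
#'
#' Runs the whole derivation on one study table: screens every panel
#' variable against CI, extracts the passing biomarkers' linear equations,
#' signal-averages them into the composite calculator, and evaluates
#' predicted vs observed CI for every record with a complete component
#' panel. Also carries the complete-pair count report with its published
#' discrepancies.
#'
#' @param table a `study_table` (default the packaged fixture)
#' @param r_min,p_max,linear_pref,gate_on,pref_mode screening thresholds,
#'   as in [screen_all()]
#' @param eligible_fluids fluids admitted to the calculator
#' @return An object of class `ci_report`: list with `screen` (summary data
#'   frame), `decisions`, `pair_counts`, `equations` (data frame),
#'   `calculator`, `formula`, `predictions` (per-animal predicted vs
#'   observed CI) and `passing_biomarkers`.
#' @export
reproduce_report <- function(table = load_fixture(), r_min = 0.7,
                             p_max = 0.05, linear_pref = 0.10,
                             gate_on = "best", pref_mode = "absolute",
                             eligible_fluids = c("serum", "urine")) {
  decisions <- screen_all(table, r_min = r_min, p_max = p_max,
                          linear_pref = linear_pref, gate_on = gate_on,
                          pref_mode = pref_mode)
  eqs <- equations_from_screen(decisions, eligible_fluids = eligible_fluids)
  calc <- signal_average(eqs)
  eq_tab <- data.frame(
    variable = vapply(eqs, `[[`, character(1), "variable"),
    slope = vapply(eqs, `[[`, numeric(1), "slope"),
    intercept = vapply(eqs, `[[`, numeric(1), "intercept"),
    units = vapply(eqs, `[[`, character(1), "units"),
    n = vapply(eqs, `[[`, numeric(1), "n"),
    r = vapply(eqs, `[[`, numeric(1), "r"),
    p = vapply(eqs, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(screen = as.data.frame(decisions),
                 decisions = decisions,
                 pair_counts = pair_count_report(table),
                 equations = eq_tab,
                 calculator = calc,
                 formula = render_formula(calc),
                 predictions = predict_panels(calc, table$data),
                 passing_biomarkers = passing_variables(decisions,
                                                        eligible_fluids)),
            class = "ci_report")
}

#' @export
print.ci_report <- function(x, ...) {
  cat("Screening summary:\n")
  print(x$screen, digits = 3)
  cat("\nEquation family (full precision):\n")
  print(x$equations, digits = 6)
  cat("\nComposite formula:\n  ", x$formula, "\n", sep = "")
  n_ok <- sum(!is.na(x$predictions$ci_predicted))
  cat(sprintf("\nPredicted vs observed CI available for %d/%d animals\n",
              n_ok, nrow(x$predictions)))
  invisible(x)
}

#' Predict CI for a table of biomarker panels
#'
#' Applies a composite calculator row-wise to a data frame. Every component
#' variable must be present as a column (a missing column is an error
#' naming it); rows with a missing value in any component get an NA
#' prediction and a note listing the missing variables. Predictions outside
#' [0, 100] are flagged in `out_of_range`, not clamped.
#'
#' @param calculator a `ci_calculator`
#' @param panels data frame with one row per panel
#' @return data frame with one row per input row: component predictions,
#'   `ci_predicted`, `out_of_range`, `note`, plus `animal_id` and
#'   `ci_observed` when present in the input.
#' @export
predict_panels <- function(calculator, panels) {
  stopifnot(inherits(calculator, "ci_calculator"), is.data.frame(panels))
  need <- names(calculator$coefficients)
  absent <- setdiff(need, names(panels))
  if (length(absent))
    stop("missing panel columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- data.frame(row = seq_len(nrow(panels)))
  if ("animal_id" %in% names(panels)) out$animal_id <- panels$animal_id
  if ("ci_percent" %in% names(panels)) out$ci_observed <- panels$ci_percent
  nr <- nrow(panels)
  for (v in need) out[[paste0("ci_from_", v)]] <- rep(NA_real_, nr)
  out$ci_predicted <- rep(NA_real_, nr)
  out$out_of_range <- rep(NA, nr)
  out$note <- rep("", nr)
  for (i in seq_len(nrow(panels))) {
    vals <- as.numeric(panels[i, need])
    names(vals) <- need
    if (anyNA(vals)) {
      out$note[i] <- paste("missing:", paste(need[is.na(vals)], collapse = ", "))
      next
    }
    p <- predict_ci(calculator, vals)
    out$ci_predicted[i] <- as.numeric(p)
    out$out_of_range[i] <- attr(p, "out_of_range")
    comps <- attr(p, "components")
    for (v in need) out[[paste0("ci_from_", v)]][i] <- comps[[v]]
  }
  out
}
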
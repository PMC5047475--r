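#' Construct a study table
#'
#' A study table couples a per-animal data frame (histological cystic index
#' plus a biomarker panel, missing cells allowed) with a panel schema
#' describing each variable's fluid of origin and units. The cystic index
#' column must be complete; all present values must be non-negative.
#'
#' @param data data frame with columns `animal_id`, `ci_percent`, and one
#'   column per panel variable. Missing biomarker cells are `NA`.
#' @param panel data frame with columns `name`, `fluid`
#'   (serum/urine/tissue/derived), `units`, and optionally `column_label` and
#'   `published_n` (the complete-pair count reported in the source study).
#' @return An object of class `study_table`.
#' @export
study_table <- function(data, panel) {
  stopifnot(is.data.frame(data), is.data.frame(panel))
  if (!all(c("animal_id", "ci_percent") %in% names(data)))
    stop("data must have 'animal_id' and 'ci_percent' columns", call. = FALSE)
  if (!all(c("name", "fluid", "units") %in% names(panel)))
    stop("panel must have 'name', 'fluid' and 'units' columns", call. = FALSE)
  if (anyDuplicated(panel$name))
    stop("duplicate variable names in panel", call. = FALSE)
  if (any(!nzchar(panel$units)))
    stop("panel units must be non-empty", call. = FALSE)
  vars <- setdiff(names(data), c("animal_id", "ci_percent"))
  unknown <- setdiff(vars, panel$name)
  if (length(unknown))
    stop("data columns missing from panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (anyNA(data$ci_percent))
    stop("ci_percent must be present for every record", call. = FALSE)
  if (any(data$ci_percent < 0 | data$ci_percent > 100))
    stop("ci_percent must lie in [0, 100]", call. = FALSE)
  for (v in vars) {
    bad <- which(!is.na(data[[v]]) & data[[v]] < 0)
    if (length(bad))
      stop(sprintf("negative value in row %d, column '%s'", bad[1], v),
           call. = FALSE)
  }
  structure(list(data = data, panel = panel[panel$name %in% vars, , drop = FALSE]),
            class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("Study table: %d animals, %d panel variables\n",
              nrow(x$data), nrow(x$panel)))
  cat(sprintf("CI range: %.2f-%.2f%%; %d missing biomarker cells\n",
              min(x$data$ci_percent), max(x$data$ci_percent),
              sum(is.na(x$data[, x$panel$name]))))
  invisible(x)
}

#' Variable names of a study table's panel
#' @param table a `study_table`
#' @return character vector of panel variable names
#' @export
panel_variables <- function(table) {
  stopifnot(inherits(table, "study_table"))
  table$panel$name
}

# Anchor cells checked at fixture load; value NA means the cell must be NA.
.fixture_anchors <- data.frame(
  row = c(1L, 1L, 1L, 4L, 18L, 27L),
  column = c("ci_percent", "bun", "ngal_serum", "il18_urine", "ci_percent",
             "microalbuminuria"),
  value = c(27.58, 36, NA, 0.020001416, 0.45, NA),
  stringsAsFactors = FALSE
)

#' Load the packaged PCK rat study table
#'
#' Returns the 27-animal table of histological cystic index, kidney mass,
#' kidney/body mass ratio, and serum/urine biomarker levels from the
#' uninephrectomized PCK rat study, exactly as printed (missing cells
#' preserved). An integrity check verifies row count and a set of anchor
#' cells and fails naming the first mismatching cell.
#'
#' @return A `study_table` with 27 records and 13 panel variables.
#' @export
load_fixture <- function() {
  csv <- system.file("extdata", "pck_study.csv", package = "cystindex")
  schema <- system.file("extdata", "pck_study_schema.csv", package = "cystindex")
  if (!nzchar(csv) || !nzchar(schema))
    stop("packaged fixture not found", call. = FALSE)
  tab <- read_study_table(csv, schema = schema)
  if (nrow(tab$data) != 27L)
    stop(sprintf("fixture integrity failure: expected 27 records, found %d",
                 nrow(tab$data)), call. = FALSE)
  a <- .fixture_anchors
  for (i in seq_len(nrow(a))) {
    got <- tab$data[[a$column[i]]][a$row[i]]
    exp <- a$value[i]
    ok <- if (is.na(exp)) is.na(got) else isTRUE(got == exp)
    if (!ok)
      stop(sprintf("fixture integrity failure at row %d, column '%s'",
                   a$row[i], a$column[i]), call. = FALSE)
  }
  tab
}

#' Read a study table from delimited text
#'
#' @param file path to a delimited text file with a header row naming
#'   `ci_percent` and the biomarker columns.
#' @param missing_token string standing for a missing value (default "NA").
#' @param sep field separator.
#' @param schema optional path to (or data frame of) a panel schema with
#'   columns `name`, `fluid`, `units`; variables absent from the schema get
#'   fluid "unknown" and units "unspecified".
#' @return A `study_table`.
#' @export
read_study_table <- function(file, missing_token = "NA", sep = ",",
                             schema = NULL) {
  raw <- utils::read.table(file, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  if (!"ci_percent" %in% names(raw))
    stop("schema error: no 'ci_percent' column in ", file, call. = FALSE)
  if (!"animal_id" %in% names(raw))
    raw <- cbind(animal_id = as.character(seq_len(nrow(raw))), raw)
  num_cols <- setdiff(names(raw), "animal_id")
  out <- raw
  for (v in num_cols) {
    cell <- raw[[v]]
    miss <- cell == missing_token | is.na(cell)
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(parsed))
    if (length(bad))
      stop(sprintf("unparseable numeric cell in row %d, column '%s': '%s'",
                   bad[1], v, cell[bad[1]]), call. = FALSE)
    parsed[miss] <- NA_real_
    out[[v]] <- parsed
  }
  panel <- resolve_schema(schema, setdiff(num_cols, "ci_percent"))
  study_table(out, panel)
}

resolve_schema <- function(schema, vars) {
  if (is.null(schema)) {
    return(data.frame(name = vars, fluid = "unknown", units = "unspecified",
                      stringsAsFactors = FALSE))
  }
  if (is.character(schema))
    schema <- utils::read.csv(schema, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(schema))
  missing <- setdiff(vars, schema$name)
  if (length(missing)) {
    schema <- rbind(schema[, c("name", "fluid", "units")],
                    data.frame(name = missing, fluid = "unknown",
                               units = "unspecified"))
  }
  schema
}

#' Write a study table to delimited text
#'
#' Round-trips with [read_study_table()] under the same dialect: numeric
#' values are written at full precision (up to 15 significant digits) and
#' missing cells as `missing_token`.
#'
#' @param table a `study_table`
#' @param file output path
#' @param missing_token string to write for missing values
#' @param sep field separator
#' @export
write_study_table <- function(table, file, missing_token = "NA", sep = ",") {
  stopifnot(inherits(table, "study_table"))
  d <- table$data
  fmt <- d
  for (v in setdiff(names(d), "animal_id")) {
    s <- vapply(d[[v]], function(x)
      if (is.na(x)) missing_token else format(x, digits = 15, scientific = FALSE),
      character(1))
    fmt[[v]] <- s
  }
  utils::write.table(fmt, file, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Pairwise-complete series of one variable against cystic index
#'
#' Implements pairwise deletion: for the requested variable, every record
#' whose biomarker value is present contributes an (x, y) pair in record
#' order; records with a missing value for that variable are dropped from
#' this analysis only.
#'
#' @param table a `study_table`
#' @param variable_name a panel variable name
#' @return An object of class `paired_series` with fields `variable`, `x`,
#'   `y` (CI percents), `n`, and `units`.
#' @export
paired_series <- function(table, variable_name) {
  stopifnot(inherits(table, "study_table"))
  if (identical(variable_name, "ci_percent"))
    stop("cystic index cannot be paired with itself", call. = FALSE)
  if (!variable_name %in% table$panel$name)
    stop("unknown variable: ", variable_name, call. = FALSE)
  keep <- !is.na(table$data[[variable_name]])
  n <- sum(keep)
  if (n < 3L)
    stop(sprintf("insufficient data for '%s': %d complete pairs (need >= 3)",
                 variable_name, n), call. = FALSE)
  structure(list(variable = variable_name,
                 x = table$data[[variable_name]][keep],
                 y = table$data$ci_percent[keep],
                 n = n,
                 units = table$panel$units[match(variable_name, table$panel$name)]),
            class = "paired_series")
}

#' Build a paired series directly from vectors
#'
#' Convenience constructor used when no study table is involved (tests,
#' simulations, ad hoc fits).
#'
#' @param x,y numeric vectors of equal length with no missing values
#' @param variable name for the x variable
#' @param units units label
#' @return A `paired_series`.
#' @export
as_paired_series <- function(x, y, variable = "x", units = "unspecified") {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  if (length(x) < 3L)
    stop("insufficient data: need >= 3 pairs", call. = FALSE)
  structure(list(variable = variable, x = as.numeric(x), y = as.numeric(y),
                 n = length(x), units = units),
            class = "paired_series")
}

#' Complete-pair counts per variable, against the published counts
#'
#' For every panel variable, reports the number of complete (biomarker, CI)
#' pairs in the table, the number of missing cells, and — when the panel
#' schema carries a `published_n` column — the complete-pair count reported
#' by the source study, flagging any discrepancy. For the packaged fixture,
#' urine NGAL (24 vs 25) and urine IL-18 (22 vs 23) disagree with the
#' published per-variable counts; the table as printed is taken as ground
#' truth and the disagreement is surfaced here rather than reconciled.
#'
#' @param table a `study_table`
#' @return data frame with columns `variable`, `n_pairs`, `n_missing`,
#'   `published_n`, `discrepancy`.
#' @export
pair_count_report <- function(table) {
  stopifnot(inherits(table, "study_table"))
  vars <- table$panel$name
  n_pairs <- vapply(vars, function(v) sum(!is.na(table$data[[v]])), integer(1))
  pub <- if ("published_n" %in% names(table$panel))
    table$panel$published_n else rep(NA_integer_, length(vars))
  data.frame(variable = vars,
             n_pairs = n_pairs,
             n_missing = nrow(table$data) - n_pairs,
             published_n = pub,
             discrepancy = !is.na(pub) & pub != n_pairs,
             row.names = NULL, stringsAsFactors = FALSE)
}
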
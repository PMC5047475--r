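# Closed-form normal-equations oracle for simple OLS, independent of lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - n * mean(x)^2
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Minimal in-memory study table: one signal biomarker (CI/2 + noise) and
# one pure-noise biomarker, optional NA cells.
toy_table <- function(n = 27, seed = 42, noise_sd = 1.5, na_cells = NULL) {
  set.seed(seed)
  ci <- runif(n, 0.4, 35)
  d <- data.frame(
    animal_id = as.character(seq_len(n)),
    ci_percent = ci,
    marker_signal = ci / 2 + rnorm(n, 0, noise_sd),
    marker_noise = rlnorm(n, 0, 0.5)
  )
  d$marker_signal <- pmax(d$marker_signal, 0)
  if (!is.null(na_cells))
    for (cell in na_cells) d[cell[[1]], cell[[2]]] <- NA_real_
  panel <- data.frame(
    name = c("marker_signal", "marker_noise"),
    fluid = c("serum", "serum"),
    units = c("mg/dL", "mg/dL")
  )
  study_table(d, panel)
}
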
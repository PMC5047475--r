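#!/usr/bin/env Rscript
# Step 2 — derive the composite cystic-index calculator.
#
# Takes the serum/urine biomarkers that cleared the screening gate (BUN,
# SCr, 24-h urine IL-18), extracts their full-precision univariate linear
# equations, and signal-averages them into the composite formula. Exits
# non-zero if the gate-passing biomarker set differs from the expected
# three. Writes the equation family (CSV), the calculator (JSON, full
# precision) and the display-rounded formula (text) under results/.

suppressPackageStartupMessages(library(cystindex))
dir.create("results", showWarnings = FALSE)

report <- reproduce_report()

expected <- c("bun", "scr", "il18_urine")
if (!setequal(report$passing_biomarkers, expected)) {
  cat("ERROR: gate-passing biomarkers are {",
      paste(report$passing_biomarkers, collapse = ", "),
      "}, expected {", paste(expected, collapse = ", "), "}\n")
  quit(status = 2)
}

write.csv(report$equations, "results/equation_family.csv", row.names = FALSE)
calculator_to_json(report$calculator, "results/calculator.json")
writeLines(report$formula, "results/composite_formula.txt")

cat("Univariate equation family (full precision):\n")
print(report$equations, digits = 6)
cat("\nSignal-averaged composite (display rounding):\n  ",
    report$formula, "\n", sep = "")
cat("\nFull-precision coefficients:\n")
print(c(report$calculator$coefficients,
        intercept = report$calculator$intercept), digits = 8)
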
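#!/usr/bin/env Rscript
# Step 3 — predicted vs observed cystic index on the study animals.
#
# Applies the fixture-derived composite calculator back to the study
# table: every animal with a complete BUN + SCr + urine IL-18 panel (22 of
# 27) gets a composite prediction plus the three univariate component
# predictions. Writes results/predictions.csv and prints summary accuracy.

suppressPackageStartupMessages(library(cystindex))
dir.create("results", showWarnings = FALSE)

report <- reproduce_report()
pred <- report$predictions
write.csv(pred, "results/predictions.csv", row.names = FALSE)

ok <- !is.na(pred$ci_predicted)
cat(sprintf("Predictions for %d/%d animals (complete biomarker panels)\n",
            sum(ok), nrow(pred)))
resid <- pred$ci_predicted[ok] - pred$ci_observed[ok]
cat(sprintf("Predicted vs observed CI: r = %.3f, RMSE = %.2f%%\n",
            cor(pred$ci_predicted[ok], pred$ci_observed[ok]),
            sqrt(mean(resid^2))))
cat(sprintf("mean absolute error = %.2f%% over observed CI range %.2f-%.2f%%\n",
            mean(abs(resid)), min(pred$ci_observed[ok]),
            max(pred$ci_observed[ok])))
print(pred[ok, c("animal_id", "ci_observed", "ci_predicted")],
      digits = 4, row.names = FALSE)
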
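#!/usr/bin/env Rscript
# Kidney absorbed doses across the injected-activity range.
#
# Calibrates the saturable uptake model to the low/mid activity anchors
# (30 -> 16, 60 -> 29, 90 -> 40 Gy), then runs the full time-activity-curve
# -> MIRD pipeline at all five activities. The declining Gy/MBq with
# increasing injected activity reflects receptor saturation.

suppressPackageStartupMessages(library(renaltox))
dir.create("results", showWarnings = FALSE)

model <- calibrate_uptake_model()
cat(sprintf("Calibrated uptake model: u0 = %.4f, k_sat = %.1f MBq\n",
            model$u0, model$k_sat_MBq))

dt <- dose_table(c(30, 60, 90, 120, 150), model)
print(dt, digits = 4)
cat(sprintf("Dose per MBq falls from %.3f to %.3f Gy/MBq across the range\n",
            dt$gy_per_MBq[1], dt$gy_per_MBq[nrow(dt)]))

utils::write.table(dt, "results/dose_table.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("wrote results/dose_table.tsv\n")
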
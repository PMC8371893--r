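#!/usr/bin/env Rscript

# Train the wavelet network and the three baselines (random forest, RBF,
# back-propagation) on the blue-edge and derivative-VI feature sets, score
# both splits, and write the metrics grid plus the percent-change
# comparisons.

suppressPackageStartupMessages(library(nitraspec))

modeling <- read.csv("results/modeling_features.csv",
                     stringsAsFactors = FALSE)
validation <- read.csv("results/validation_features.csv",
                       stringsAsFactors = FALSE)

rep_out <- comparison_report(modeling, validation,
                             cfg = train_config(seed = 1))
write_report(rep_out, "results/model_metrics.csv",
             "results/model_report.json")

val <- rep_out$metrics[rep_out$metrics$split == "validation" &
                         rep_out$metrics$feature_set == "blue_edge", ]
cat("validation (blue edge):\n")
print(val[c("model", "r_squared", "rmse", "mae")], row.names = FALSE)
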
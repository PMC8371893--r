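#!/usr/bin/env Rscript

# Correlation and single-feature regression screening on the modeling
# feature table: Pearson correlations with significance at p < 0.01, and
# linear / quadratic / exponential fits per feature.

suppressPackageStartupMessages(library(nitraspec))

ft <- read.csv("results/modeling_features.csv", stringsAsFactors = FALSE)
tabs <- screening_tables(ft)
write_table(tabs$trilateral_cor, "results/screening_trilateral_cor.csv")
write_table(tabs$vi_cor, "results/screening_vi_cor.csv")
write_table(tabs$trilateral_fits, "results/screening_trilateral_fits.csv")
write_table(tabs$vi_fits, "results/screening_vi_fits.csv")

best <- tabs$trilateral_fits[which.max(tabs$trilateral_fits$r_squared), ]
cat("best trilateral fit:", best$feature, best$family,
    "R2 =", round(best$r_squared, 3), "\n")
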
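#!/usr/bin/env Rscript

# Derive the trilateral edge parameters and the red-edge vegetation indices
# (original and first-derivative bases) from the averaged spectra written by
# 01_simulate.R, join the nitrate targets, and write one feature table per
# split.

suppressPackageStartupMessages(library(nitraspec))

for (split in c("modeling", "validation")) {
  s <- read_spectra(file.path("results", paste0(split, "_spectra.csv")))
  targets <- read_targets(file.path("results", paste0(split,
                                                      "_targets.csv")))
  ft <- feature_table(s, targets)
  write_table(ft, file.path("results", paste0(split, "_features.csv")))
  cat(split, ": ", nrow(ft), " samples x ", ncol(ft) - 2,
      " features\n", sep = "")
}
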
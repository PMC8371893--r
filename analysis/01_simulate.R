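#!/usr/bin/env Rscript

# Generate the synthetic field campaign: 60 modeling samples (5 N rates x
# 3 replicates x 4 growth stages) and 60 validation samples (15 plots x 4
# stages), three reflectance scans per sample. Writes the averaged spectra
# and the nitrate targets to results/.

suppressPackageStartupMessages(library(nitraspec))

cfg <- sim_config(seed = 1)
ds <- generate_dataset(cfg)

dir.create("results", showWarnings = FALSE)
for (split in c("modeling", "validation")) {
  avg <- average_scans(ds[[split]]$spectra)
  write_spectra(avg, file.path("results", paste0(split, "_spectra.csv")))
  write_table(ds[[split]]$targets,
              file.path("results", paste0(split, "_targets.csv")))
}
cat("simulated", n_samples(ds$modeling$spectra), "modeling scans and",
    n_samples(ds$validation$spectra), "validation scans\n")
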
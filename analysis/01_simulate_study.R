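#!/usr/bin/env Rscript
# Step 1: generate the synthetic root-spectra study used by all later
# steps. 120 samples on the 662-band FT-NIR grid (800-2782 nm), lignin
# drawn from the truncated normal N(20.52, 7.7^2) on [7.7, 42.8] %,
# Beer-Lambert mixing of the 9-band component library, then scatter,
# polynomial baseline and edge-weighted noise. Writes the spectra and
# reference CSVs that steps 3-4 read back.

suppressPackageStartupMessages(library(rootlignin))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- synth_config(n_samples = 120L, seed = 2026L)
sim <- simulate_spectra(cfg)

write_spectra(sim$spectra, "results/data/spectra.csv")
write_reference(sim$reference, "results/data/reference.csv")
write.csv(sim$compositions, "results/data/compositions_synthetic.csv",
          row.names = FALSE)

y <- sim$reference$lignin_pct
cat(sprintf("simulated %d samples x %d bands\n",
            nrow(sim$spectra), ncol(sim$spectra)))
cat(sprintf("lignin content: %.2f +/- %.2f %% (range %.1f-%.1f %%)\n",
            mean(y), sd(y), min(y), max(y)))
cat("wrote results/data/{spectra,reference,compositions_synthetic}.csv\n")
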
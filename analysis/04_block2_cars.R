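#!/usr/bin/env Rscript
# Step 4 (Block II): CARS wavelength selection wrapped around PLSR, on
# the same saved splits as Block I, against the full-spectrum reference
# model. Pre-processing is SNV: it acts on each spectrum alone (the
# operational requirement when predicting single unknown samples) and it
# is the treatment the root-spectroscopy field study carried into its
# selection stage; on this simulator the baseline correctors edge it out
# in Block I, see results/block1_aggregate.csv. Reports the
# comparison table, per-band selection frequency over the repeats, and
# the adjacent-run clustering of the most frequently selected bands.

suppressPackageStartupMessages(library(rootlignin))
dir.create("results", showWarnings = FALSE)

X <- read_spectra("results/data/spectra.csv")
ref <- read_reference("results/data/reference.csv")
y <- ref$lignin_pct
wl <- wavelengths(X)

splits <- make_splits(nrow(X), 71, 49, repeats = 25, master_seed = 4001L)

full <- run_validation(X, y, splits, preprocess = "snv", model = "full")
cars <- suppressWarnings(
  run_validation(X, y, splits, preprocess = "snv", model = "cars"))

cmp <- rbind(cbind(model = "full", full$metrics),
             cbind(model = "cars", cars$metrics))
write.csv(cmp, "results/block2_metrics.csv", row.names = FALSE)

tab <- rbind(aggregate_reports(full$metrics, "Full spectrum PLSR")$formatted,
             aggregate_reports(cars$metrics, "CARS-PLSR")$formatted)
cat("validation accuracies (mean +/- SD over 25 repeats):\n")
print(tab, row.names = FALSE)
cat(sprintf("mean selected wavelengths in CARS: %.1f of %d\n",
            mean(cars$metrics$n_bands), length(wl)))

freq <- selection_frequency(cars$subsets, length(wl))
write.csv(data.frame(wavelength_nm = wl, selection_pct = freq),
          "results/selection_frequency.csv", row.names = FALSE)

# bands selected in at least half of the repeats, as adjacent clusters
hot <- which(freq >= 50)
if (length(hot)) {
  cl <- cluster_adjacent(hot, gap = 2)
  clusters <- vapply(split(hot, cl), function(ix) {
    sprintf("%.0f-%.0f nm (max %.0f %%)", min(wl[ix]), max(wl[ix]),
            max(freq[ix]))
  }, "")
  cat("wavelength clusters selected in >= 50 % of repeats:\n")
  cat(paste(" ", clusters, collapse = "\n"), "\n")
}
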
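#!/usr/bin/env Rscript
# Step 4 — simulate the qPCR runs.
# One standard dilution series (2.34e2..2.34e8 copies/uL, triplicate) per
# assay plus triplicate reactions of every gBTM design under every assay,
# with per-template efficiencies from the mismatch model and the packaged
# override scenario. Curves go out in the long instrument-export format.
# Writes: results/curves_standards.csv, results/curves_samples.csv

suppressPackageStartupMessages(library(ampliq))
dir.create("results", showWarnings = FALSE)
seed <- 20260926

ref <- dsrb_reference()
model <- efficiency_model(overrides = ref$overrides)
designs <- gbtm_grid(ref$templates, priority = ref$priority)
sets <- names(ref$primer_sets)

standards <- list()
for (ai in seq_along(sets)) {
  curves <- simulate_dilution_series(replicates = 3, seed = seed + 13 * ai)
  long <- curves_to_long(curves)
  long$primer_set <- sets[ai]
  standards[[ai]] <- long
}
write.csv(do.call(rbind, standards), "results/curves_standards.csv",
          row.names = FALSE)

samples <- list()
for (di in seq_along(designs)) {
  for (ai in seq_along(sets)) {
    eff <- efficiency_from_matrix(ref$amplifiability, sets[ai], model)
    curves <- simulate_mixture(designs[[di]], eff, replicates = 3,
                               seed = seed + 101 * di + 9901 * ai)
    long <- curves_to_long(curves)
    long$primer_set <- sets[ai]
    long$input_total <- designs[[di]]$total_concentration
    samples[[length(samples) + 1L]] <- long
  }
}
write.csv(do.call(rbind, samples), "results/curves_samples.csv",
          row.names = FALSE)

cat("Simulated", length(standards) * 21, "standard wells and",
    length(samples) * 3, "sample wells (35 cycles each).\n")
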
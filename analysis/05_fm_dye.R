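#!/usr/bin/env Rscript
# FM1-43 quantification on the simulated load/unload pair: per-bouton
# background-corrected load and unload means and the unload (discharge)
# fraction 1 - unload/load, against the planted destaining fraction.
#
# Input:  results/scenes/ (from 01_simulate_scenes.R)
# Output: results/fm_metrics.csv

suppressPackageStartupMessages(library(nmjquant))
dir.create("results", showWarnings = FALSE)

load_scene <- read_scene("results/scenes/fm_load.yaml")
unload_scene <- read_scene("results/scenes/fm_unload.yaml")
truth <- read_truth("results/scenes/fm_truth.yaml")

masks <- filter_by_area(segment_boutons(load_scene))$kept
res <- fm_metrics(load_scene, unload_scene, masks)
print(res$per_bouton[, c("bouton_label", "load_mean", "unload_mean",
                         "unload_fraction")])
message(sprintf("per-preparation mean unload fraction %.3f (planted %.2f)",
                res$summary$mean_unload_fraction, truth$unload_fraction))
write.csv(res$per_bouton, "results/fm_metrics.csv", row.names = FALSE)
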
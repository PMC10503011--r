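#!/usr/bin/env Rscript
# Segment boutons from the membrane (HRP) channel of the simulated STED
# scene, compare them against the generator's ground-truth footprints, apply
# the type-Ib size filter, and fit the bouton-size distribution with BIC
# model selection on a larger simulated size sample.
#
# Input:  results/scenes/ (from 01_simulate_scenes.R)
# Output: results/segmentation.csv, results/size_model.csv

suppressPackageStartupMessages(library(nmjquant))
dir.create("results", showWarnings = FALSE)

scene <- read_scene("results/scenes/sted_puncta.yaml")
truth <- read_truth("results/scenes/sted_puncta_truth.yaml")

masks <- segment_boutons(scene)
m <- match_boutons(masks, truth$boutons)
message(sprintf("segmented %d boutons; Jaccard vs truth: %s",
                length(masks), paste(round(m$jaccard, 3), collapse = ", ")))

flt <- filter_by_area(masks)
message(sprintf("%d of %d boutons inside the type-Ib range [2.5, 12] um^2",
                length(flt$kept), length(masks)))

rows <- measurement_rows(
  "sted_puncta",
  rep(vapply(masks, `[[`, 0L, "label"), each = 2),
  rep(c("area", "jaccard_vs_truth"), length(masks)),
  as.vector(rbind(vapply(masks, `[[`, 0, "area_um2"),
                  m$jaccard[order(m$mask_label)])),
  rep(c("um2", ""), length(masks)))
write_measurements(rows, "results/segmentation.csv")

# bouton-size distribution: a single-population type-Ib size sample
set.seed(20260926)
areas <- rnorm(400, 6.5, 2.0)
areas <- areas[areas > 0.5]
fit <- fit_size_model(areas, max_components = 3)
print(fit)
df <- data.frame(k = seq_along(fit$bic_values), bic = fit$bic_values)
write.csv(df, "results/size_model.csv", row.names = FALSE)
message(sprintf("BIC selects k = %d; derived type-Ib range %.2f-%.2f um^2",
                fit$selected_k, fit$type_ib_range[1], fit$type_ib_range[2]))
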
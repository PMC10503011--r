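#!/usr/bin/env Rscript
# Program A on the simulated STED scene: detect CSP-like particles as local
# maxima inside each segmented bouton, partition each bouton into the 200 nm
# peripheral band and the central remainder, and compare the measured zone
# densities against the planted truth.
#
# Input:  results/scenes/ (from 01_simulate_scenes.R)
# Output: results/zone_densities.csv

suppressPackageStartupMessages(library(nmjquant))
dir.create("results", showWarnings = FALSE)

scene <- read_scene("results/scenes/sted_puncta.yaml")
truth <- read_truth("results/scenes/sted_puncta_truth.yaml")

masks <- filter_by_area(segment_boutons(scene))$kept
rows <- NULL
for (m in masks) {
  ps <- detect_local_maxima(scene, m, background_exclude = masks)
  zones <- partition_zones(m)
  zd <- zone_density(ps, zones)
  message(sprintf(
    "bouton %d: %d particles; peripheral %.2f /um^2, central %.2f /um^2",
    m$label, ps$n_total, zd$peripheral_density, zd$central_density))
  rows <- rbind(rows, measurement_rows(
    "sted_puncta", m$label,
    c("n_particles", "peripheral_density", "central_density",
      "peripheral_area", "central_area"),
    c(ps$n_total, zd$peripheral_density, zd$central_density,
      zd$peripheral_area_um2, zd$central_area_um2),
    c("count", "per_um2", "per_um2", "um2", "um2")))
}
tr <- truth$zone_density_truth
message(sprintf("planted densities: peripheral %.2f, central %.2f per um^2",
                tr[[1]]$planted_peripheral, tr[[1]]$planted_central))
write_measurements(rows, "results/zone_densities.csv")
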
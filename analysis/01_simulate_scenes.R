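#!/usr/bin/env Rscript
# Simulate the synthetic study scenes used by the downstream analyses and
# write them to disk (TIFF channels + YAML manifests + truth files), so every
# later step runs from files exactly as it would on real acquisitions.
#
# Scenes:
#   * a STED-mode puncta scene (membrane + vesicle channels, 3 boutons)
#     for segmentation and Program A/B measurements;
#   * a paired unstimulated/stimulated scene set on shared geometry;
#   * an FM1-43 load/unload pair (confocal mode).
#
# Output: results/scenes/

suppressPackageStartupMessages(library(nmjquant))
seed <- 20260926L
out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating STED puncta scene (3 boutons, densities 2.0 / 0.5) ...")
main <- make_puncta_scene(n_boutons = 3, peripheral_density = 2,
                          central_density = 0.5, seed = seed)
write_scene(main$scene, out, "sted_puncta")
write_truth(main$truth, file.path(out, "sted_puncta_truth.yaml"))

message("simulating paired US/S scenes (peripheral ratio 1.8) ...")
cal <- calibration_preset("confocal")
geom <- make_bouton_geometry(4, c(5, 10), calibration = cal, seed = seed + 1L)
pair <- make_paired_scenes(geom, c(1, 1), c(1.8, 1.2), calibration = cal,
                           seed = seed + 1L)
write_scene(pair$us$scene, out, "paired_us")
write_scene(pair$s$scene, out, "paired_s")
write_truth(pair$us$truth, file.path(out, "paired_us_truth.yaml"))
write_truth(pair$s$truth, file.path(out, "paired_s_truth.yaml"))

message("simulating FM1-43 load/unload pair (planted unload 0.6) ...")
fm <- make_fm_pair(0.6, seed = seed + 2L)
write_scene(fm$load, out, "fm_load")
write_scene(fm$unload, out, "fm_unload")
write_truth(fm$truth, file.path(out, "fm_truth.yaml"))

message("scenes written under ", out)
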
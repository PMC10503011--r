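# Shared fixture builders. All fixtures are generated in code at test time.

# Wrap a generator bouton truth as a mask usable by the measurement stages
# (the "hand-drawn ROI" path).
truth_mask <- function(bouton, label = 1L) {
  structure(list(footprint = bouton$footprint, label = label,
                 area_um2 = bouton$area_um2,
                 bbox = NULL, center_slice = NA_integer_),
            class = "bouton_mask")
}

truth_masks <- function(geometry) {
  lapply(seq_along(geometry), function(i) truth_mask(geometry[[i]], i))
}

# Minimal particle_set built directly from planted puncta (bypasses
# detection; used for tests of zone/band bookkeeping, not of detection).
particles_from_truth <- function(puncta, label = 1L) {
  df <- data.frame(y = puncta$y, x = puncta$x,
                   intensity = puncta$amplitude %||% 1)
  structure(list(bouton_label = label, particles = df, n_total = nrow(df),
                 detection_params = list(min_intensity = 0,
                                         neighborhood = "8-connected",
                                         mode = "truth")),
            class = "particle_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small calibrated stack holding one frame.
frame_stack <- function(frame, pixel_size_xy = 27.5, z_step = 0.1145,
                        role = "vesicle") {
  calibrated_stack(array(frame, c(dim(frame), 1L)), pixel_size_xy, z_step,
                   role)
}

# Random connected bouton-like mask (single component, border-clear).
random_mask <- function(seed, area_range = c(2.5, 12), irregularity = 0.4,
                        calibration = calibration_preset("sted")) {
  geom <- make_bouton_geometry(1, area_range, irregularity, calibration,
                               seed = seed)
  geom[[1]]
}
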
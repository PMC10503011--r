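# Program A: CSP particle detection by local maxima, peripheral/central zone
# partition at a fixed physical band depth, and zone particle densities.

#' Detect vesicle-marker particles as local intensity maxima
#'
#' A pixel is a particle candidate iff its intensity is >= all 8 neighbours,
#' >= the detection threshold, and inside the bouton footprint. Plateaus
#' (8-connected runs of equal-valued candidates) yield exactly one particle at
#' the plateau centroid, rounded to the nearest pixel with ties toward the
#' top-left; a plateau only counts when some neighbour outside it is strictly
#' smaller, so a constant image yields no particles.
#'
#' @param vesicle `calibrated_stack` (vesicle channel) or `nmj_scene`.
#' @param mask a `bouton_mask` (or any list with a `footprint`).
#' @param min_intensity detection threshold, or `"auto"`: background mean +
#'   `auto_k` background s.d., estimated outside `background_exclude` (all
#'   masks) on the analysis frame.
#' @param auto_k multiplier for the automatic threshold. With quantized
#'   Gaussian read noise essentially every above-threshold background pixel
#'   is a local maximum (ties make its neighbourhood condition vacuous), so
#'   the expected count of pure-noise particles is about
#'   n_mask_pixels x P(Z > auto_k); the default 5 keeps that expectation
#'   below ~0.01 for boutons of 10^4-10^5 pixels.
#' @param mode `"projection"` (maximum-intensity projection, default) or
#'   `"slices"` (per-slice detection, unique maxima aggregated across Z).
#' @param min_separation_px non-maximum suppression radius: among maxima
#'   closer than this (Euclidean), only the strongest is kept (ties resolved
#'   toward the top-left). The default 3 px sits at the optical resolution
#'   scale of the STED calibration (~80 nm) and removes secondary shoulder
#'   maxima that noise raises on the flank of a bright spot; set to 1 to
#'   disable suppression.
#' @param background_exclude optional list of masks excluded from the
#'   automatic background estimate; defaults to `mask` alone.
#' @return object of class `particle_set`: `bouton_label`, `particles`
#'   (data.frame y, x, intensity, and z in slice mode), `n_total`,
#'   `detection_params`.
#' @export
detect_local_maxima <- function(vesicle, mask, min_intensity = "auto",
                                auto_k = 5, mode = c("projection", "slices"),
                                min_separation_px = 3,
                                background_exclude = NULL) {
  if (inherits(vesicle, "nmj_scene"))
    vesicle <- scene_channel(vesicle, "vesicle")
  mode <- match.arg(mode)
  fp <- mask$footprint
  if (!any(fp)) {
    return(structure(list(bouton_label = mask$label %||% NA_integer_,
                          particles = data.frame(y = integer(), x = integer(),
                                                 intensity = numeric()),
                          n_total = 0L,
                          detection_params = list(min_intensity = NA_real_,
                                                  neighborhood = "8-connected",
                                                  mode = mode)),
                     class = "particle_set"))
  }
  frames <- if (mode == "projection") list(max_projection(vesicle))
            else lapply(seq_len(n_slices(vesicle)),
                        function(z) vesicle$voxels[, , z])
  if (identical(min_intensity, "auto")) {
    excl <- background_exclude %||% list(mask)
    bg_mask <- !Reduce(`|`, lapply(excl, `[[`, "footprint"))
    bg_vals <- frames[[1]][bg_mask]
    if (length(bg_vals) < 16)
      .stop_validation("no background pixels available for the auto threshold")
    min_intensity <- mean(bg_vals) + auto_k * stats::sd(bg_vals)
  }
  all_p <- list()
  for (zi in seq_along(frames)) {
    frame <- frames[[zi]]
    nmax <- .neighbor_max(frame)
    nmin <- .neighbor_min(frame)
    cand <- frame >= nmax & frame >= min_intensity & fp
    if (!any(cand)) next
    lab <- .as_num(EBImage::bwlabel(cand * 1))
    for (l in seq_len(max(lab))) {
      comp <- which(lab == l, arr.ind = TRUE)
      # plateau validity: some 8-neighbour of the plateau is strictly smaller
      vals <- frame[comp]
      if (!any(nmin[comp] < vals[1] & is.finite(nmin[comp]))) next
      cy <- as.integer(.round_half_down(mean(comp[, 1])))
      cx <- as.integer(.round_half_down(mean(comp[, 2])))
      if (!fp[cy, cx]) { # centroid of a bent plateau can fall outside
        d2 <- (comp[, 1] - mean(comp[, 1]))^2 + (comp[, 2] - mean(comp[, 2]))^2
        j <- which.min(d2)
        cy <- as.integer(comp[j, 1]); cx <- as.integer(comp[j, 2])
      }
      all_p[[length(all_p) + 1L]] <-
        data.frame(y = cy, x = cx, intensity = vals[1],
                   z = if (mode == "slices") zi else NA_integer_)
    }
  }
  particles <- if (length(all_p)) do.call(rbind, all_p)
               else data.frame(y = integer(), x = integer(),
                               intensity = numeric(), z = integer())
  if (mode == "slices" && nrow(particles)) {
    particles <- particles[!duplicated(particles[, c("y", "x")]), ,
                           drop = FALSE]
  } else if (nrow(particles)) {
    particles$z <- NULL
  }
  if (nrow(particles) > 1 && min_separation_px > 1) {
    o <- order(-particles$intensity, particles$y, particles$x)
    particles <- particles[o, , drop = FALSE]
    keep <- logical(nrow(particles))
    ky <- numeric(0); kx <- numeric(0)
    for (i in seq_len(nrow(particles))) {
      if (length(ky) == 0 ||
          min((ky - particles$y[i])^2 + (kx - particles$x[i])^2) >=
            min_separation_px^2) {
        keep[i] <- TRUE
        ky <- c(ky, particles$y[i]); kx <- c(kx, particles$x[i])
      }
    }
    particles <- particles[keep, , drop = FALSE]
    particles <- particles[order(particles$y, particles$x), , drop = FALSE]
  }
  rownames(particles) <- NULL
  structure(list(bouton_label = mask$label %||% NA_integer_,
                 particles = particles, n_total = nrow(particles),
                 detection_params = list(min_intensity = min_intensity,
                                         neighborhood = "8-connected",
                                         min_separation_px = min_separation_px,
                                         mode = mode)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> bouton %s: %d particles (threshold %.4g, %s)\n",
              x$bouton_label, x$n_total,
              x$detection_params$min_intensity, x$detection_params$mode))
  invisible(x)
}

#' Partition a bouton into peripheral band and central remainder
#'
#' Peripheral zone: pixels whose Euclidean distance (pixel center to nearest
#' exterior pixel center, scaled by the XY pixel size) to the footprint
#' exterior is <= `band_nm`; central zone: the rest. At the STED calibration
#' the default 200 nm band is about 7.27 px deep. The two zones partition the
#' footprint exactly.
#'
#' @param mask a `bouton_mask` (or list with `footprint`).
#' @param band_nm physical band depth in nm (> 0).
#' @param calibration list with `pixel_size_xy` in nm.
#' @return object of class `zone_partition`: logical `peripheral` and
#'   `central` masks, `band_nm`, and both areas in um^2.
#' @export
partition_zones <- function(mask, band_nm = 200,
                            calibration = calibration_preset("sted")) {
  stopifnot(band_nm > 0)
  fp <- mask$footprint
  px <- calibration$pixel_size_xy
  dm <- .as_num(EBImage::distmap(fp * 1))
  peripheral <- fp & (dm * px <= band_nm)
  central <- fp & !peripheral
  structure(list(peripheral = peripheral, central = central,
                 band_nm = band_nm,
                 peripheral_area_um2 = .mask_area_um2(peripheral, px),
                 central_area_um2 = .mask_area_um2(central, px)),
            class = "zone_partition")
}

#' Peripheral and central particle densities
#'
#' Counts particles by zone membership of their coordinates and divides by
#' the zone areas. A zero-area central zone (bouton thinner than the band)
#' reports `central_density = NA` with `central_defined = FALSE` rather
#' than 0.
#'
#' @param particles a `particle_set`.
#' @param zones a `zone_partition` from the same bouton.
#' @return list: `peripheral_density`, `central_density` (particles/um^2),
#'   counts, areas, `central_defined`.
#' @export
zone_density <- function(particles, zones) {
  p <- particles$particles
  in_peri <- if (nrow(p))
    zones$peripheral[cbind(p$y, p$x)] else logical(0)
  n_peri <- sum(in_peri)
  n_cent <- nrow(p) - n_peri
  central_defined <- zones$central_area_um2 > 0
  list(peripheral_density = n_peri / zones$peripheral_area_um2,
       central_density = if (central_defined)
         n_cent / zones$central_area_um2 else NA_real_,
       n_peripheral = n_peri, n_central = n_cent,
       peripheral_area_um2 = zones$peripheral_area_um2,
       central_area_um2 = zones$central_area_um2,
       central_defined = central_defined)
}

#' Match detected particles to planted ground truth
#'
#' Greedy nearest matching under a Chebyshev distance cap: each truth punctum
#' is matched to at most one detection.
#'
#' @param particles a `particle_set`.
#' @param truth_puncta data.frame with `y`, `x` of planted puncta.
#' @param max_dist_px match radius (Chebyshev), default 1 pixel.
#' @return list: `n_matched`, `n_truth`, `n_false_positive`, `matches`
#'   (data.frame truth row, detection row, distance).
#' @export
match_particles <- function(particles, truth_puncta, max_dist_px = 1) {
  det <- particles$particles
  nT <- nrow(truth_puncta); nD <- nrow(det)
  if (nT == 0 || nD == 0)
    return(list(n_matched = 0L, n_truth = nT, n_false_positive = nD,
                matches = data.frame()))
  used <- logical(nD)
  rows <- list()
  for (i in seq_len(nT)) {
    d <- pmax(abs(det$y - truth_puncta$y[i]), abs(det$x - truth_puncta$x[i]))
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= max_dist_px) {
      used[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(truth = i, detection = j,
                                              dist = d[j])
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(n_matched = nrow(matches), n_truth = nT,
       n_false_positive = nD - sum(used), matches = matches)
}
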
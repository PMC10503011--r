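# Synthetic NMJ scene generator with exhaustive ground truth.
#
# Scenes emulate the statistical structure of stained larval NMJ images:
# bouton-shaped footprints in the type-Ib size range, a membrane (HRP) rim
# channel, vesicle-marker (CSP) puncta planted with controlled peripheral vs
# central densities, FM1-43 load/unload pairs with a planted destaining
# fraction, and endosome-marker channels with a controlled overlap fraction.
# Every generator is a pure function of (parameters, seed).

#' Calibration presets
#'
#' `"sted"`: 27.5 nm XY pixels, 0.1145 um Z step (super-resolution mode).
#' `"confocal"`: 60 nm XY pixels, 0.5 um Z step.
#'
#' @param mode `"sted"` or `"confocal"`.
#' @return list with `pixel_size_xy` (nm) and `z_step` (um).
#' @export
calibration_preset <- function(mode = c("sted", "confocal")) {
  mode <- match.arg(mode)
  switch(mode,
         sted = list(pixel_size_xy = 27.5, z_step = 0.1145),
         confocal = list(pixel_size_xy = 60, z_step = 0.5))
}

#' Ground truth of a synthetic scene
#'
#' @param boutons list of per-bouton truths: `footprint` (logical matrix on
#'   the scene canvas), `area_um2`, `center` (y, x).
#' @param puncta per-bouton list of data.frames (z, y, x, amplitude).
#' @param zone_density_truth per-bouton list with planted and realized
#'   (post-thinning) peripheral/central densities, puncta per um^2.
#' @param overlap_fraction planted fraction of endosome spot intensity placed
#'   on vesicle puncta positions, in [0, 1] (NA when not a coloc scene).
#' @param unload_fraction planted destaining fraction in [0, 1] (NA when not
#'   an FM scene).
#' @param seed integer seed the scene was generated with.
#' @param calibration calibration list (see [calibration_preset()]).
#' @param extra free-form list of generator-specific truth values.
#' @return an object of class `scene_truth`.
#' @export
scene_truth <- function(boutons, puncta = NULL, zone_density_truth = NULL,
                        overlap_fraction = NA_real_,
                        unload_fraction = NA_real_, seed = NA_integer_,
                        calibration = calibration_preset("sted"),
                        extra = list()) {
  if (!is.na(overlap_fraction))
    stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  if (!is.na(unload_fraction))
    stopifnot(unload_fraction >= 0, unload_fraction <= 1)
  structure(list(boutons = boutons, puncta = puncta,
                 zone_density_truth = zone_density_truth,
                 overlap_fraction = overlap_fraction,
                 unload_fraction = unload_fraction, seed = seed,
                 calibration = calibration, extra = extra),
            class = "scene_truth")
}

# ---- bouton geometry --------------------------------------------------------

# Rasterize one star-shaped bouton outline: boundary radius R * (1 + dev(theta))
# with a low-order random Fourier deviation, rescaled until the realized pixel
# area is within `area_tol` of the target.
.raster_bouton <- function(target_px, irregularity) {
  a <- stats::runif(3, -1, 1) / (2:4)
  phi <- stats::runif(3, 0, 2 * pi)
  dev_fun <- function(theta) {
    d <- a[1] * cos(2 * theta + phi[1]) + a[2] * cos(3 * theta + phi[2]) +
      a[3] * cos(4 * theta + phi[3])
    irregularity * d / max(1e-9, max(abs(a)) * 2)
  }
  r0 <- sqrt(target_px / pi)
  scale <- 1
  for (iter in 1:12) {
    rmax <- r0 * scale * 1.8 + 2
    side <- 2L * ceiling(rmax) + 3L
    c0 <- (side + 1) / 2
    yy <- matrix(seq_len(side), side, side)
    xx <- matrix(seq_len(side), side, side, byrow = TRUE)
    dy <- yy - c0; dx <- xx - c0
    rho <- sqrt(dy^2 + dx^2)
    theta <- atan2(dy, dx)
    m <- rho <= r0 * scale * (1 + dev_fun(theta))
    realized <- sum(m)
    if (realized > 0 && abs(realized - target_px) / target_px <= 0.02) break
    scale <- scale * sqrt(target_px / max(realized, 1))
  }
  # keep the largest connected component (tiny satellites can rasterize off the
  # main body at high irregularity)
  lab <- .as_num(EBImage::bwlabel(m * 1))
  if (max(lab) > 1) {
    keep <- which.max(tabulate(lab[lab > 0]))
    m <- lab == keep
  }
  bb <- .mask_bbox(m)
  m[bb[1]:bb[2], bb[3]:bb[4], drop = FALSE]
}

#' Generate ground-truth bouton footprints
#'
#' Places `n_boutons` non-overlapping, border-clear, single-component masks on
#' a shared canvas. Target areas are drawn uniformly from `area_range_um2`;
#' realized pixel areas are within 5% of their targets.
#'
#' @param n_boutons number of boutons (0 returns an empty list).
#' @param area_range_um2 `(min, max)` bouton area in um^2; default is the
#'   type-Ib range 2.5-12 um^2.
#' @param shape_irregularity 0 (quasi-circular) to 1 (strongly lobed).
#' @param calibration calibration list.
#' @param canvas `c(ny, nx)` canvas in pixels; auto-sized when NULL.
#' @param gap_px minimum pairwise gap between boutons (pixels). The default 8
#'   keeps neighbouring boutons separable by the segmentation's morphological
#'   closing; the generator guarantees at least a 2-pixel gap in any case.
#' @param seed integer seed.
#' @param max_retries placement retries per bouton before a placement error.
#' @return list of bouton truths (`footprint`, `area_um2`, `center`), with the
#'   canvas dimensions as attribute `canvas`.
#' @export
make_bouton_geometry <- function(n_boutons, area_range_um2 = c(2.5, 12),
                                 shape_irregularity = 0.25,
                                 calibration = calibration_preset("sted"),
                                 canvas = NULL, gap_px = 8L, seed = 1L,
                                 max_retries = 200L) {
  stopifnot(n_boutons >= 0, area_range_um2[1] > 0,
            area_range_um2[2] >= area_range_um2[1],
            shape_irregularity >= 0, shape_irregularity <= 1)
  px_um2 <- (calibration$pixel_size_xy / 1000)^2
  if (n_boutons == 0) {
    out <- list()
    attr(out, "canvas") <- canvas %||% c(64L, 64L)
    attr(out, "calibration") <- calibration
    return(out)
  }
  rmax_px <- sqrt(area_range_um2[2] / px_um2 / pi) * 1.6
  if (is.null(canvas)) {
    ncell <- ceiling(sqrt(n_boutons))
    cell <- ceiling(2 * rmax_px + 2 * gap_px + 6)
    canvas <- c(ncell * cell + 8L, ceiling(n_boutons / ncell) * cell + 8L)
  }
  withr::with_seed(seed, {
    boutons <- vector("list", n_boutons)
    occupied <- matrix(FALSE, canvas[1], canvas[2])
    for (i in seq_len(n_boutons)) {
      target_um2 <- stats::runif(1, area_range_um2[1], area_range_um2[2])
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        m <- .raster_bouton(target_um2 / px_um2, shape_irregularity)
        hs <- dim(m)
        if (any(hs + 2 * gap_px + 2 >= canvas)) break
        oy <- sample.int(canvas[1] - hs[1] - 2 * gap_px - 2, 1) + gap_px + 1L
        ox <- sample.int(canvas[2] - hs[2] - 2 * gap_px - 2, 1) + gap_px + 1L
        full <- matrix(FALSE, canvas[1], canvas[2])
        full[oy:(oy + hs[1] - 1L), ox:(ox + hs[2] - 1L)] <- m
        # enforce the pairwise gap by dilating the candidate before the
        # occupancy test
        grown <- .as_logical_mask(
          EBImage::dilate(full * 1, EBImage::makeBrush(2L * gap_px + 1L, "disc")))
        if (!any(grown & occupied)) {
          occupied <- occupied | full
          idx <- which(full, arr.ind = TRUE)
          boutons[[i]] <- list(
            footprint = full,
            area_um2 = sum(full) * px_um2,
            target_area_um2 = target_um2,
            center = c(mean(idx[, 1]), mean(idx[, 2])))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement error: canvas too small for requested boutons",
             call. = FALSE)
    }
  })
  attr(boutons, "canvas") <- canvas
  attr(boutons, "calibration") <- calibration
  boutons
}

# ---- puncta planting --------------------------------------------------------

# Greedy spacing thinning: keep draws in order, drop any within min_spacing_px
# (Euclidean) of an already-kept punctum.
.thin_spacing <- function(pos, kept, min_spacing_px) {
  keep <- logical(nrow(pos))
  ky <- kept[, 1]; kx <- kept[, 2]
  for (i in seq_len(nrow(pos))) {
    if (length(ky) == 0 ||
        min((ky - pos[i, 1])^2 + (kx - pos[i, 2])^2) >= min_spacing_px^2) {
      keep[i] <- TRUE
      ky <- c(ky, pos[i, 1]); kx <- c(kx, pos[i, 2])
    }
  }
  keep
}

.sample_zone_positions <- function(zone_mask, count, kept, min_spacing_px) {
  pix <- which(zone_mask, arr.ind = TRUE)
  if (count == 0 || nrow(pix) == 0)
    return(matrix(numeric(0), 0, 2))
  if (count > 0.25 * nrow(pix))
    stop("saturation error: requested puncta density too high for the 2-px spacing",
         call. = FALSE)
  draw <- pix[sample.int(nrow(pix), count), , drop = FALSE]
  draw[.thin_spacing(draw, kept, min_spacing_px), , drop = FALSE]
}

#' Plant vesicle-marker puncta in a bouton with zone-controlled densities
#'
#' Zone counts are Poisson with mean density x zone area; positions are
#' uniform over the zone's pixels; a minimum pairwise spacing is enforced by
#' thinning and the realized (post-thinning) counts are recorded as truth.
#'
#' @param bouton one bouton truth from [make_bouton_geometry()] (or any list
#'   with a `footprint` logical matrix).
#' @param peripheral_density,central_density puncta per um^2 (>= 0).
#' @param band_nm peripheral band depth from the outer edge, default 200 nm.
#' @param calibration calibration list.
#' @param amplitude integrated spot intensity given to every punctum.
#' @param min_spacing_px minimum pairwise spacing (pixels).
#' @param z slice index the puncta live on.
#' @param seed integer seed.
#' @return list with `puncta` (data.frame z, y, x, amplitude, zone),
#'   `planted` densities, `realized` densities and counts, and the
#'   [partition_zones()] used.
#' @export
plant_puncta <- function(bouton, peripheral_density, central_density,
                         band_nm = 200, calibration = calibration_preset("sted"),
                         amplitude = 1000, min_spacing_px = 2, z = 1L,
                         seed = 1L) {
  stopifnot(peripheral_density >= 0, central_density >= 0, band_nm > 0)
  mask <- bouton$footprint
  zones <- partition_zones(list(footprint = mask), band_nm = band_nm,
                           calibration = calibration)
  withr::with_seed(seed, {
    n_p <- stats::rpois(1, peripheral_density * zones$peripheral_area_um2)
    n_c <- stats::rpois(1, central_density * zones$central_area_um2)
    kept <- matrix(numeric(0), 0, 2)
    pp <- .sample_zone_positions(zones$peripheral, n_p, kept, min_spacing_px)
    cp <- .sample_zone_positions(zones$central, n_c, rbind(kept, pp),
                                 min_spacing_px)
  })
  n_all <- nrow(pp) + nrow(cp)
  puncta <- data.frame(
    z = rep(as.integer(z), n_all),
    y = as.integer(c(pp[, 1], cp[, 1])),
    x = as.integer(c(pp[, 2], cp[, 2])),
    amplitude = rep_len(amplitude, n_all),
    zone = rep(c("peripheral", "central"), c(nrow(pp), nrow(cp))))
  realized <- list(
    n_peripheral = nrow(pp), n_central = nrow(cp),
    peripheral_density = nrow(pp) / zones$peripheral_area_um2,
    central_density = if (zones$central_area_um2 > 0)
      nrow(cp) / zones$central_area_um2 else NA_real_)
  list(puncta = puncta,
       planted = list(peripheral_density = peripheral_density,
                      central_density = central_density),
       realized = realized, zones = zones)
}

#' Plant an exact number of well-separated puncta uniformly over a bouton
#'
#' Used for detection-recovery studies where the planted count must be exact.
#' Rejection-samples positions until `n` puncta at the requested spacing are
#' placed, or fails with a saturation error.
#'
#' @inheritParams plant_puncta
#' @param n exact number of puncta.
#' @export
plant_puncta_n <- function(bouton, n, min_spacing_px = 8, amplitude = 1000,
                           z = 1L, seed = 1L, max_rounds = 200L) {
  mask <- bouton$footprint
  pix <- which(mask, arr.ind = TRUE)
  withr::with_seed(seed, {
    kept <- matrix(numeric(0), 0, 2)
    for (round in seq_len(max_rounds)) {
      need <- n - nrow(kept)
      if (need <= 0) break
      draw <- pix[sample.int(nrow(pix), min(nrow(pix), 4L * need)), ,
                  drop = FALSE]
      add <- draw[.thin_spacing(draw, kept, min_spacing_px), , drop = FALSE]
      if (nrow(add) > need) add <- add[seq_len(need), , drop = FALSE]
      kept <- rbind(kept, add)
    }
  })
  if (nrow(kept) < n)
    stop("saturation error: cannot place ", n, " puncta at spacing ",
         min_spacing_px, " px", call. = FALSE)
  data.frame(z = z, y = kept[, 1], x = kept[, 2], amplitude = amplitude,
             zone = NA_character_)
}

# ---- rendering --------------------------------------------------------------

# Add one normalized-Gaussian spot of integrated intensity `amp` at (y, x).
.add_spot <- function(frame, y, x, amp, kernel) {
  r <- (nrow(kernel) - 1L) / 2L
  y0 <- y - r; y1 <- y + r; x0 <- x - r; x1 <- x + r
  ky0 <- 1L + max(0L, 1L - y0); kx0 <- 1L + max(0L, 1L - x0)
  ky1 <- nrow(kernel) - max(0L, y1 - nrow(frame))
  kx1 <- ncol(kernel) - max(0L, x1 - ncol(frame))
  fy0 <- max(1L, y0); fx0 <- max(1L, x0)
  fy1 <- min(nrow(frame), y1); fx1 <- min(ncol(frame), x1)
  frame[fy0:fy1, fx0:fx1] <- frame[fy0:fy1, fx0:fx1] +
    amp * kernel[ky0:ky1, kx0:kx1]
  frame
}

# Rim of a footprint: footprint minus `width` successive 8-connected erosions.
.rim <- function(footprint, width = 2L) {
  core <- footprint * 1
  for (i in seq_len(width)) core <- .as_num(EBImage::erode(core, .brush3()))
  footprint & !(core > 0.5)
}

.apply_noise_quantize <- function(v, noise, quantize_bits) {
  if (!is.null(noise$gaussian_sd) && noise$gaussian_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$gaussian_sd)
  if (isTRUE(noise$poisson))
    v <- array(stats::rpois(length(v), pmax(v, 0)), dim = dim(v))
  v <- pmax(v, 0)
  if (!is.null(quantize_bits))
    v <- pmin(round(v), 2^quantize_bits - 1)
  array(v, dim = dim(v))
}

#' Render a synthetic scene from ground truth
#'
#' The membrane channel is a 2-pixel-wide rim of each bouton footprint (an
#' HRP-like membrane outline), blurred and noised; the vesicle channel is the
#' sum of normalized Gaussian spots at the planted puncta plus background and
#' noise. Blur kernels sum to 1, so without noise, background, or
#' quantization the vesicle channel integrates exactly to the summed planted
#' amplitudes.
#'
#' @param truth a [scene_truth()] whose `puncta` entries came from
#'   [plant_puncta()] / [plant_puncta_n()].
#' @param psf_sigma_nm Gaussian blur s.d. in nm (>= 0).
#' @param background_level constant background added to every voxel.
#' @param noise list with `gaussian_sd` (additive read noise s.d.) and
#'   `poisson` (logical shot noise); `list(gaussian_sd = 0)` disables noise.
#' @param nz number of Z slices; `center_z` is the slice the puncta and the
#'   widest membrane extent are rendered on; away from it the bouton outline
#'   shrinks by `z_shrink_px` erosions per slice.
#' @param membrane_amp rim intensity before blurring.
#' @param quantize_bits integer bit depth voxels are rounded/clipped to;
#'   `NULL` keeps float voxels (used when exact conservation matters).
#' @param channels which channels to render.
#' @param condition,experiment_id scene metadata.
#' @param seed integer seed (noise only; geometry lives in `truth`).
#' @return an [nmj_scene()].
#' @export
render_scene <- function(truth, psf_sigma_nm = 40, background_level = 10,
                         noise = list(gaussian_sd = 5, poisson = FALSE),
                         nz = 1L, center_z = ceiling(nz / 2),
                         z_shrink_px = 2L, membrane_amp = 8000,
                         quantize_bits = 16L,
                         channels = c("membrane", "vesicle"),
                         condition = "n/a", experiment_id = "synthetic",
                         seed = 1L) {
  stopifnot(psf_sigma_nm >= 0, background_level >= 0)
  calib <- truth$calibration
  canvas <- dim(truth$boutons[[1]]$footprint)
  sigma_px <- psf_sigma_nm / calib$pixel_size_xy
  kernel <- gaussian_spot_kernel(sigma_px)
  out <- list()
  withr::with_seed(seed, {
    if ("membrane" %in% channels) {
      vol <- array(0, dim = c(canvas, nz))
      for (z in seq_len(nz)) {
        d <- z_shrink_px * abs(z - center_z)
        frame <- matrix(0, canvas[1], canvas[2])
        for (b in truth$boutons) {
          fp <- b$footprint * 1
          if (d > 0) for (i in seq_len(d))
            fp <- .as_num(EBImage::erode(fp, .brush3()))
          fp <- fp > 0.5
          if (!any(fp)) next
          frame[.rim(fp)] <- membrane_amp
        }
        if (sigma_px > 0)
          frame <- .as_num(EBImage::filter2(frame, kernel, boundary = 0))
        vol[, , z] <- frame
      }
      vol <- .apply_noise_quantize(vol + background_level, noise, quantize_bits)
      out$membrane <- calibrated_stack(vol, calib$pixel_size_xy, calib$z_step,
                                       "membrane",
                                       if (is.null(quantize_bits)) 32L else quantize_bits)
    }
    if ("vesicle" %in% channels) {
      vol <- array(0, dim = c(canvas, nz))
      for (bi in seq_along(truth$puncta)) {
        pts <- truth$puncta[[bi]]
        if (is.null(pts) || nrow(pts) == 0) next
        for (i in seq_len(nrow(pts))) {
          z <- min(max(1L, pts$z[i] + center_z - 1L), nz)
          vol[, , z] <- .add_spot(vol[, , z], pts$y[i], pts$x[i],
                                  pts$amplitude[i], kernel)
        }
      }
      vol <- .apply_noise_quantize(vol + background_level, noise, quantize_bits)
      out$vesicle <- calibrated_stack(vol, calib$pixel_size_xy, calib$z_step,
                                      "vesicle",
                                      if (is.null(quantize_bits)) 32L else quantize_bits)
    }
  })
  nmj_scene(out, experiment_id = experiment_id, condition = condition)
}

# ---- composite generators ---------------------------------------------------

#' Generate a fully-specified single study scene (geometry + puncta + render)
#'
#' Convenience wrapper: draws geometry, plants puncta at the requested zone
#' densities in every bouton, and renders. Returns the scene and its truth.
#'
#' @inheritParams make_bouton_geometry
#' @inheritParams plant_puncta
#' @param render_args list of extra arguments for [render_scene()].
#' @export
make_puncta_scene <- function(n_boutons = 1, peripheral_density = 2,
                              central_density = 0.5,
                              area_range_um2 = c(2.5, 12), band_nm = 200,
                              calibration = calibration_preset("sted"),
                              shape_irregularity = 0.25, amplitude = 1000,
                              seed = 1L, render_args = list(),
                              condition = "n/a") {
  geom <- make_bouton_geometry(n_boutons, area_range_um2, shape_irregularity,
                               calibration, seed = seed)
  puncta <- vector("list", length(geom))
  zdt <- vector("list", length(geom))
  for (i in seq_along(geom)) {
    pl <- plant_puncta(geom[[i]], peripheral_density, central_density,
                       band_nm = band_nm, calibration = calibration,
                       amplitude = amplitude, seed = seed + 1000L * i)
    puncta[[i]] <- pl$puncta
    zdt[[i]] <- c(list(planted_peripheral = pl$planted$peripheral_density,
                        planted_central = pl$planted$central_density),
                   pl$realized)
  }
  truth <- scene_truth(geom, puncta, zdt, seed = seed,
                       calibration = calibration)
  scene <- do.call(render_scene,
                   c(list(truth = truth, seed = seed + 777L,
                          condition = condition), render_args))
  list(scene = scene, truth = truth)
}

#' Generate a paired unstimulated/stimulated scene set on shared geometry
#'
#' Both scenes share identical bouton footprints; the only ground-truth
#' difference is the planted zone densities, emulating a KCl-stimulation
#' paired design.
#'
#' @param geometry bouton list from [make_bouton_geometry()].
#' @param densities_us,densities_s `c(peripheral, central)` planted densities
#'   (puncta/um^2) for the unstimulated and stimulated member.
#' @inheritParams make_puncta_scene
#' @export
make_paired_scenes <- function(geometry, densities_us = c(1, 1),
                               densities_s = c(1.8, 1.2), band_nm = 200,
                               calibration = calibration_preset("sted"),
                               amplitude = 1000, seed = 1L,
                               render_args = list()) {
  build <- function(dens, cond, sub) {
    puncta <- vector("list", length(geometry))
    zdt <- vector("list", length(geometry))
    for (i in seq_along(geometry)) {
      pl <- plant_puncta(geometry[[i]], dens[1], dens[2], band_nm = band_nm,
                         calibration = calibration, amplitude = amplitude,
                         seed = seed + sub + 1000L * i)
      puncta[[i]] <- pl$puncta
      zdt[[i]] <- c(list(planted_peripheral = pl$planted$peripheral_density,
                        planted_central = pl$planted$central_density),
                   pl$realized)
    }
    truth <- scene_truth(geometry, puncta, zdt, seed = seed,
                         calibration = calibration)
    scene <- do.call(render_scene,
                     c(list(truth = truth, seed = seed + sub + 777L,
                            condition = cond), render_args))
    list(scene = scene, truth = truth)
  }
  list(us = build(densities_us, "unstimulated", 0L),
       s = build(densities_s, "stimulated", 500000L))
}

#' Generate an FM1-43 load/unload scene pair
#'
#' Boutons are filled with a uniform dye intensity in the load member; the
#' unload member carries `load_mean * (1 - unload_fraction)` before noise.
#' Background is a `remote_bk` plane, replaced by `local_bk` on a halo
#' around (and under) the boutons, emulating muscle background next to the
#' terminal.
#'
#' @param unload_fraction planted destaining fraction in [0, 1].
#' @param load_mean mean dye intensity added inside boutons after loading.
#' @param n_boutons,area_range_um2,calibration,seed geometry controls.
#' @param local_bk,remote_bk background levels (local defaults to remote:
#'   spatially uniform background).
#' @param noise noise model as in [render_scene()].
#' @param halo_px halo width around boutons carrying the local background.
#' @return list with `load` and `unload` scenes (each also carrying the
#'   membrane channel) and the shared `truth`.
#' @export
make_fm_pair <- function(unload_fraction, load_mean = 1000, n_boutons = 4,
                         area_range_um2 = c(2.5, 12),
                         calibration = calibration_preset("confocal"),
                         local_bk = 50, remote_bk = 50,
                         noise = list(gaussian_sd = 5), halo_px = 12L,
                         membrane_amp = 8000, quantize_bits = 16L,
                         seed = 1L) {
  stopifnot(unload_fraction >= 0, unload_fraction <= 1,
            load_mean >= 0, local_bk >= 0, remote_bk >= 0)
  geom <- make_bouton_geometry(n_boutons, area_range_um2, 0.25, calibration,
                               seed = seed)
  canvas <- attr(geom, "canvas")
  all_fp <- Reduce(`|`, lapply(geom, `[[`, "footprint"))
  halo <- .as_logical_mask(EBImage::dilate(
    all_fp * 1, EBImage::makeBrush(2L * halo_px + 1L, "disc")))
  bk_plane <- matrix(remote_bk, canvas[1], canvas[2])
  bk_plane[halo] <- local_bk
  rim_frame <- matrix(0, canvas[1], canvas[2])
  for (b in geom) rim_frame[.rim(b$footprint)] <- membrane_amp
  build <- function(level, role, cond, sub) {
    dye <- bk_plane + level * all_fp
    mem <- rim_frame + remote_bk
    withr::with_seed(seed + sub, {
      dye <- .apply_noise_quantize(array(dye, c(canvas, 1L)), noise,
                                   quantize_bits)
      mem <- .apply_noise_quantize(array(mem, c(canvas, 1L)), noise,
                                   quantize_bits)
    })
    chans <- list(
      calibrated_stack(mem, calibration$pixel_size_xy,
                       calibration$z_step, "membrane",
                       quantize_bits %||% 32L),
      calibrated_stack(dye, calibration$pixel_size_xy,
                       calibration$z_step, role,
                       quantize_bits %||% 32L))
    names(chans) <- c("membrane", role)
    nmj_scene(chans, experiment_id = "fm_synthetic", condition = cond)
  }
  truth <- scene_truth(geom, unload_fraction = unload_fraction, seed = seed,
                       calibration = calibration,
                       extra = list(load_mean = load_mean, local_bk = local_bk,
                                    remote_bk = remote_bk))
  list(load = build(load_mean, "dye_load", "load", 11L),
       unload = build(load_mean * (1 - unload_fraction), "dye_unload",
                      "unload", 22L),
       truth = truth)
}

#' Generate a colocalization scene with a controlled overlap fraction
#'
#' Vesicle-marker (CSP) spots are planted uniformly; a fraction
#' `overlap_fraction` of the endosome-marker (Rab) spots is placed exactly on
#' vesicle spot positions, the rest at positions kept `min_sep_px` away from
#' every vesicle spot. With equal spot amplitudes the planted fraction of
#' endosome intensity on vesicle positions equals the realized count fraction,
#' recorded in the truth.
#'
#' @param overlap_fraction in [0, 1].
#' @param csp_density,rab_density spots per um^2.
#' @param area_um2 bouton area.
#' @param amplitude integrated spot intensity (both channels).
#' @param psf_sigma_nm,background_level,noise render controls (defaults give
#'   a high-SNR, deconvolved-like scene).
#' @param min_sep_px separation enforced between non-overlapping Rab spots and
#'   all CSP spots.
#' @inheritParams make_puncta_scene
#' @return list with `scene` (membrane + vesicle + endosome channels) and
#'   `truth` (realized overlap fraction in `truth$overlap_fraction`).
#' @export
make_coloc_scene <- function(overlap_fraction, csp_density = 2,
                             rab_density = 1.5, area_um2 = 8,
                             amplitude = 1000, psf_sigma_nm = 40,
                             background_level = 0,
                             noise = list(gaussian_sd = 0.2),
                             calibration = calibration_preset("sted"),
                             min_sep_px = 6L, quantize_bits = NULL,
                             seed = 1L) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  geom <- make_bouton_geometry(1, c(area_um2, area_um2), 0.2, calibration,
                               seed = seed)
  b <- geom[[1]]
  pix <- which(b$footprint, arr.ind = TRUE)
  withr::with_seed(seed + 31L, {
    n_csp <- max(1L, stats::rpois(1, csp_density * b$area_um2))
    csp <- pix[sample.int(nrow(pix), n_csp), , drop = FALSE]
    csp <- csp[.thin_spacing(csp, matrix(numeric(0), 0, 2), min_sep_px), ,
               drop = FALSE]
    n_csp <- nrow(csp)
    n_rab <- max(1L, stats::rpois(1, rab_density * b$area_um2))
    k <- min(round(overlap_fraction * n_rab), n_csp)
    on_idx <- if (k > 0) sample.int(n_csp, k) else integer(0)
    rab_on <- csp[on_idx, , drop = FALSE]
    rab_off <- matrix(numeric(0), 0, 2)
    guard <- rbind(csp, rab_on)
    attempts <- 0L
    while (nrow(rab_off) < n_rab - k && attempts < 400L) {
      cand <- pix[sample.int(nrow(pix), 4L * (n_rab - k)), , drop = FALSE]
      ok <- .thin_spacing(cand, guard, min_sep_px)
      add <- cand[ok, , drop = FALSE]
      if (nrow(add) > 0) {
        need <- n_rab - k - nrow(rab_off)
        add <- add[seq_len(min(nrow(add), need)), , drop = FALSE]
        rab_off <- rbind(rab_off, add)
        guard <- rbind(guard, add)
      }
      attempts <- attempts + 1L
    }
  })
  rab <- rbind(rab_on, rab_off)
  n_rab_real <- nrow(rab)
  realized_overlap <- if (n_rab_real > 0) nrow(rab_on) / n_rab_real else NA_real_
  canvas <- dim(b$footprint)
  sigma_px <- psf_sigma_nm / calibration$pixel_size_xy
  kernel <- gaussian_spot_kernel(sigma_px)
  render_ch <- function(pts, role, sub) {
    frame <- matrix(0, canvas[1], canvas[2])
    if (nrow(pts)) for (i in seq_len(nrow(pts)))
      frame <- .add_spot(frame, pts[i, 1], pts[i, 2], amplitude, kernel)
    withr::with_seed(seed + sub, {
      v <- .apply_noise_quantize(array(frame + background_level,
                                       c(canvas, 1L)),
                                 noise, quantize_bits)
    })
    calibrated_stack(v, calibration$pixel_size_xy, calibration$z_step, role,
                     quantize_bits %||% 32L)
  }
  mem_frame <- matrix(0, canvas[1], canvas[2])
  mem_frame[.rim(b$footprint)] <- 8000
  mem <- calibrated_stack(array(mem_frame, c(canvas, 1L)),
                          calibration$pixel_size_xy, calibration$z_step,
                          "membrane", quantize_bits %||% 32L)
  scene <- nmj_scene(list(membrane = mem,
                          vesicle = render_ch(csp, "vesicle", 51L),
                          endosome = render_ch(rab, "endosome", 52L)),
                     experiment_id = "coloc_synthetic")
  truth <- scene_truth(
    geom,
    puncta = list(data.frame(z = 1L, y = csp[, 1], x = csp[, 2],
                             amplitude = amplitude, zone = NA)),
    overlap_fraction = realized_overlap, seed = seed,
    calibration = calibration,
    extra = list(planted_overlap = overlap_fraction,
                 rab = data.frame(y = rab[, 1], x = rab[, 2]),
                 n_rab_on = nrow(rab_on), n_rab = n_rab_real))
  list(scene = scene, truth = truth)
}

#' Generate a scene of boutons filled with given mean intensities
#'
#' Emulates diffuse-marker staining (pMAD/CSP/VGLUT-style mean-intensity
#' studies): each bouton is filled with its own uniform level on every slice,
#' over a constant background.
#'
#' @param bouton_levels numeric vector, one fill level per bouton.
#' @param background constant background level.
#' @param nz number of Z slices.
#' @inheritParams make_fm_pair
#' @export
make_intensity_scene <- function(bouton_levels, background = 50, nz = 1L,
                                 area_range_um2 = c(2.5, 12),
                                 calibration = calibration_preset("confocal"),
                                 noise = list(gaussian_sd = 5),
                                 membrane_amp = 8000, quantize_bits = 16L,
                                 seed = 1L) {
  n <- length(bouton_levels)
  geom <- make_bouton_geometry(n, area_range_um2, 0.25, calibration,
                               seed = seed)
  canvas <- attr(geom, "canvas")
  frame <- matrix(background, canvas[1], canvas[2])
  rim_frame <- matrix(background, canvas[1], canvas[2])
  for (i in seq_len(n)) {
    frame[geom[[i]]$footprint] <- background + bouton_levels[i]
    rim_frame[.rim(geom[[i]]$footprint)] <- membrane_amp
  }
  withr::with_seed(seed + 5L, {
    vol <- .apply_noise_quantize(
      array(rep(frame, nz), c(canvas, nz)), noise, quantize_bits)
    mem <- .apply_noise_quantize(
      array(rep(rim_frame, nz), c(canvas, nz)), noise, quantize_bits)
  })
  truth <- scene_truth(geom, seed = seed, calibration = calibration,
                       extra = list(bouton_levels = bouton_levels,
                                    background = background))
  list(scene = nmj_scene(list(
         membrane = calibrated_stack(mem, calibration$pixel_size_xy,
                                     calibration$z_step, "membrane",
                                     quantize_bits %||% 32L),
         vesicle = calibrated_stack(vol, calibration$pixel_size_xy,
                                    calibration$z_step, "vesicle",
                                    quantize_bits %||% 32L)),
         experiment_id = "intensity_synthetic"),
       truth = truth)
}

# ---- truth serialization ----------------------------------------------------

.rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = as.integer(r$values))
}

.rle_decode <- function(enc) {
  v <- inverse.rle(list(lengths = enc$lengths,
                        values = as.logical(enc$values)))
  matrix(v, enc$dim[1], enc$dim[2])
}

#' Serialize a scene truth to YAML (lossless)
#'
#' Footprints are stored run-length encoded; puncta tables as column lists.
#'
#' @param truth a [scene_truth()].
#' @param path output YAML path.
#' @export
write_truth <- function(truth, path) {
  ser <- list(
    boutons = lapply(truth$boutons, function(b)
      list(footprint = .rle_encode(b$footprint), area_um2 = b$area_um2,
           center = b$center)),
    puncta = lapply(truth$puncta, function(p)
      if (is.null(p)) NULL else as.list(p)),
    zone_density_truth = truth$zone_density_truth,
    overlap_fraction = truth$overlap_fraction,
    unload_fraction = truth$unload_fraction,
    seed = truth$seed,
    calibration = truth$calibration,
    extra = lapply(truth$extra, function(e)
      if (is.data.frame(e)) as.list(e) else e))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read back a scene truth written by [write_truth()]
#' @param path YAML path.
#' @export
read_truth <- function(path) {
  ser <- yaml::read_yaml(path)
  boutons <- lapply(ser$boutons, function(b)
    list(footprint = .rle_decode(b$footprint), area_um2 = b$area_um2,
         center = unlist(b$center)))
  puncta <- lapply(ser$puncta, function(p)
    if (is.null(p)) NULL else as.data.frame(p))
  scene_truth(boutons, puncta, ser$zone_density_truth,
              ser$overlap_fraction %||% NA_real_,
              ser$unload_fraction %||% NA_real_,
              ser$seed %||% NA_integer_, ser$calibration,
              extra = ser$extra %||% list())
}
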
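# Background-corrected mean-intensity quantification per bouton and FM1-43
# load/unload metrics with normalization to a control group.

#' Estimate image background
#'
#' Three strategies, following the convention of averaging a remote image
#' background with the non-synaptic region immediately lateral to each
#' bouton:
#' * `"remote"` — mean of the 5% dimmest tiles of the frame outside all
#'   masks (deterministic automatic stand-in for a hand-chosen region), or of
#'   an explicit `remote_roi` mask;
#' * `"local"` — per-bouton mean of a ring 3-10 px outside the footprint,
#'   excluding all other masks;
#' * `"combined"` — mean of the remote value and the (per-bouton) local
#'   value.
#'
#' @param frame numeric matrix, `calibrated_stack` (projection used) or
#'   `nmj_scene` (the dye/vesicle channel if present, else the first channel).
#' @param masks list of `bouton_mask`s to exclude (and to ring around).
#' @param strategy `"remote"`, `"local"` or `"combined"`.
#' @param remote_roi optional logical matrix naming the remote region.
#' @param tile_px tile size for the automatic remote estimate.
#' @return `"remote"`: a scalar. `"local"`/`"combined"`: numeric vector, one
#'   value per mask.
#' @export
estimate_background <- function(frame, masks,
                                strategy = c("combined", "remote", "local"),
                                remote_roi = NULL, tile_px = 16L) {
  strategy <- match.arg(strategy)
  if (inherits(frame, "nmj_scene")) {
    role <- intersect(c("dye_load", "dye_unload", "vesicle"),
                      names(frame$channels))
    frame <- frame$channels[[if (length(role)) role[1] else 1L]]
  }
  if (inherits(frame, "calibrated_stack")) frame <- max_projection(frame)
  all_masks <- Reduce(`|`, lapply(masks, `[[`, "footprint"),
                      accumulate = FALSE) %||%
    matrix(FALSE, nrow(frame), ncol(frame))
  outside <- !all_masks
  if (!any(outside)) .stop_validation("no background pixels outside the masks")
  remote <- if (!is.null(remote_roi)) mean(frame[remote_roi & outside])
            else .remote_tile_mean(frame, outside, tile_px)
  if (strategy == "remote") return(remote)
  local <- vapply(masks, function(m) {
    ring <- .as_logical_mask(EBImage::dilate(m$footprint * 1,
                                             EBImage::makeBrush(21L, "disc"))) &
      !.as_logical_mask(EBImage::dilate(m$footprint * 1,
                                        EBImage::makeBrush(7L, "disc")))
    ring <- ring & outside
    if (!any(ring)) return(NA_real_)
    mean(frame[ring])
  }, 0)
  local[is.na(local)] <- remote
  if (strategy == "local") return(local)
  (remote + local) / 2
}

# Mean of the 5% dimmest whole tiles lying fully outside the masks.
.remote_tile_mean <- function(frame, outside, tile_px) {
  ny <- nrow(frame); nx <- ncol(frame)
  ty <- seq(1L, ny - tile_px + 1L, by = tile_px)
  tx <- seq(1L, nx - tile_px + 1L, by = tile_px)
  means <- c()
  for (y0 in ty) for (x0 in tx) {
    ys <- y0:(y0 + tile_px - 1L); xs <- x0:(x0 + tile_px - 1L)
    if (all(outside[ys, xs])) means <- c(means, mean(frame[ys, xs]))
  }
  if (length(means) == 0) return(mean(frame[outside]))
  k <- max(1L, ceiling(0.05 * length(means)))
  mean(sort(means)[seq_len(k)])
}

#' Background-corrected mean bouton intensity over the center slice +/- flanks
#'
#' The ROI mean is taken on the bouton's center (maximum-area) slice and the
#' `n_flank` slices above and below, with equal slice weights (the 5-slice
#' representative sample at the default `n_flank = 2`); slices outside the
#' stack are clipped and recorded. The background `bk` is subtracted and the
#' result floored at 0 (raw value retained).
#'
#' @param channel `calibrated_stack` or `nmj_scene` (vesicle channel used).
#' @param mask a `bouton_mask` (non-empty).
#' @param center_slice 1-based Z index of the bouton's maximum-area slice.
#' @param n_flank slices included on each side, default 2.
#' @param bk background level to subtract.
#' @param slice_agg `"mean"` (default) or `"sum"` over the slice means.
#' @return list (class `intensity_measurement`): `bouton_label`, `raw_mean`,
#'   `bk`, `corrected_mean`, `slices_used`, `clipped`.
#' @export
bouton_mean_intensity <- function(channel, mask, center_slice = 1L,
                                  n_flank = 2L, bk = 0,
                                  slice_agg = c("mean", "sum")) {
  if (inherits(channel, "nmj_scene")) {
    role <- intersect(c("vesicle", "dye_load", "dye_unload"),
                      names(channel$channels))
    channel <- channel$channels[[if (length(role)) role[1] else 1L]]
  }
  slice_agg <- match.arg(slice_agg)
  if (!any(mask$footprint)) .stop_validation("empty ROI")
  nz <- n_slices(channel)
  want <- (center_slice - n_flank):(center_slice + n_flank)
  use <- want[want >= 1L & want <= nz]
  slice_means <- vapply(use, function(z)
    mean(channel$voxels[, , z][mask$footprint]), 0)
  raw <- if (slice_agg == "mean") mean(slice_means) else sum(slice_means)
  structure(list(bouton_label = mask$label %||% NA_integer_,
                 raw_mean = raw, bk = bk,
                 corrected_mean = max(raw - bk, 0),
                 slices_used = use, clipped = length(use) < length(want)),
            class = "intensity_measurement")
}

#' Normalize corrected intensities to a control group
#'
#' Divides every corrected mean by the control group's mean corrected value,
#' independently within each experiment, so the control group's own mean
#' normalized value is exactly 1 per experiment.
#'
#' @param measurements data.frame with columns `corrected_mean`, `group`,
#'   and optionally `experiment` (single experiment assumed when absent).
#' @param control_group label of the control group.
#' @return the data.frame with a `normalized` column added.
#' @export
normalize_to_control <- function(measurements, control_group = "control") {
  stopifnot(is.data.frame(measurements),
            "corrected_mean" %in% names(measurements),
            "group" %in% names(measurements))
  if (!"experiment" %in% names(measurements)) measurements$experiment <- "e1"
  measurements$normalized <- NA_real_
  for (ex in unique(measurements$experiment)) {
    sel <- measurements$experiment == ex
    ctrl <- sel & measurements$group == control_group
    if (!any(ctrl))
      .stop_validation("control group empty in experiment ", ex)
    m <- mean(measurements$corrected_mean[ctrl])
    if (!(m > 0))
      .stop_validation("control mean not positive in experiment ", ex)
    measurements$normalized[sel] <- measurements$corrected_mean[sel] / m
  }
  measurements
}

#' FM1-43 load/unload metrics per bouton
#'
#' For each bouton the background-corrected mean dye intensity is measured on
#' its maximum-area slice in the load and in the unload image (assumed
#' aligned and sharing the bouton masks), with combined (remote + local)
#' background subtraction by default. The unload fraction is
#' 1 - unload_mean / load_mean, clipped to [0, 1] with the raw value
#' retained; boutons with non-positive corrected load are flagged undefined.
#' A preparation-level summary averages the defined bouton fractions (the
#' per-larva value).
#'
#' @param load_scene,unload_scene `nmj_scene`s with a `dye_load` /
#'   `dye_unload` channel.
#' @param masks shared list of `bouton_mask`s.
#' @param strategy background strategy, see [estimate_background()].
#' @return list: `per_bouton` data.frame (`bouton_label`, `load_mean`,
#'   `unload_mean`, `unload_fraction`, `unload_fraction_raw`, `defined`,
#'   backgrounds) and `summary` (mean unload fraction over defined boutons,
#'   n).
#' @export
fm_metrics <- function(load_scene, unload_scene, masks,
                       strategy = "combined") {
  load_ch <- scene_channel(load_scene, "dye_load")
  unload_ch <- scene_channel(unload_scene, "dye_unload")
  bk_l <- estimate_background(load_ch, masks, strategy)
  bk_u <- estimate_background(unload_ch, masks, strategy)
  bk_l <- rep_len(bk_l, length(masks))
  bk_u <- rep_len(bk_u, length(masks))
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    cz <- m$center_slice
    if (is.na(cz %||% NA)) cz <- 1L
    lm <- bouton_mean_intensity(load_ch, m, cz, n_flank = 0L, bk = bk_l[i])
    um <- bouton_mean_intensity(unload_ch, m, cz, n_flank = 0L, bk = bk_u[i])
    defined <- lm$corrected_mean > 0
    raw_frac <- if (defined) 1 - um$corrected_mean / lm$corrected_mean
                else NA_real_
    data.frame(bouton_label = m$label %||% i,
               load_mean = lm$corrected_mean,
               unload_mean = um$corrected_mean,
               load_bk = bk_l[i], unload_bk = bk_u[i],
               unload_fraction_raw = raw_frac,
               unload_fraction = if (defined) min(max(raw_frac, 0), 1)
                                 else NA_real_,
               defined = defined)
  })
  per_bouton <- do.call(rbind, rows)
  ok <- per_bouton$defined
  list(per_bouton = per_bouton,
       summary = list(
         mean_unload_fraction = if (any(ok))
           mean(per_bouton$unload_fraction[ok]) else NA_real_,
         mean_load = mean(per_bouton$load_mean[ok]),
         n_boutons = sum(ok)))
}
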
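# Bouton segmentation from the membrane (HRP) channel, size filtering in the
# type-Ib range, and BIC model selection on the bouton-size distribution.

#' Segment boutons from the membrane channel
#'
#' The HRP-like rim signal on the maximum-intensity projection is thresholded
#' (Otsu by default), closed morphologically so small rim gaps seal, and the
#' enclosed regions are filled and labelled. Components below `min_area_um2`
#' are discarded. Labels are assigned in raster order of the component
#' centroids (top-left first).
#'
#' @param membrane a `calibrated_stack` with role `"membrane"` (or any stack
#'   to segment), or an `nmj_scene` whose membrane channel is used.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold when `threshold_method = "fixed"`.
#' @param min_area_um2 discard components smaller than this (um^2).
#' @param projection `"max"` (default analysis frame) or `"none"` (first
#'   slice).
#' @param closing_radius radius (pixels) of the disc used to close rim gaps.
#' @return list of `bouton_mask` objects: `label`, `footprint` (logical
#'   matrix), `area_um2`, `bbox`, `center_slice` (NA until [center_slice()]).
#'   An empty or constant membrane image yields an empty list with a warning.
#' @export
segment_boutons <- function(membrane, threshold_method = c("otsu", "fixed"),
                            fixed_value = NULL, min_area_um2 = 1,
                            projection = c("max", "none"),
                            closing_radius = 3L) {
  if (inherits(membrane, "nmj_scene"))
    membrane <- scene_channel(membrane, "membrane")
  threshold_method <- match.arg(threshold_method)
  projection <- match.arg(projection)
  stopifnot(min_area_um2 >= 0)
  frame <- if (projection == "max") max_projection(membrane)
           else membrane$voxels[, , 1]
  if (max(frame) == min(frame)) {
    warning("constant membrane image: no boutons segmented")
    return(list())
  }
  thr <- if (threshold_method == "otsu") otsu_threshold(as.vector(frame))
         else fixed_value
  bin <- (frame > thr) * 1
  if (!any(bin > 0)) {
    warning("threshold above all intensities: no boutons segmented")
    return(list())
  }
  closed <- EBImage::closing(bin, EBImage::makeBrush(2L * closing_radius + 1L,
                                                     "disc"))
  filled <- .as_num(EBImage::fillHull(closed))
  lab <- .as_num(EBImage::bwlabel(filled))
  nlab <- max(lab)
  if (nlab == 0) return(list())
  px_um2 <- (membrane$pixel_size_xy / 1000)^2
  masks <- list()
  for (l in seq_len(nlab)) {
    fp <- lab == l
    area <- sum(fp) * px_um2
    if (area < min_area_um2) next
    idx <- which(fp, arr.ind = TRUE)
    masks[[length(masks) + 1L]] <- list(
      footprint = fp, area_um2 = area, bbox = .mask_bbox(fp),
      centroid = c(mean(idx[, 1]), mean(idx[, 2])),
      center_slice = NA_integer_, threshold = thr)
  }
  if (length(masks) == 0) return(list())
  # raster order of (rounded) centroids: top row first, then left to right
  cy <- vapply(masks, function(m) .round_half_down(m$centroid[1]), 0)
  cx <- vapply(masks, function(m) .round_half_down(m$centroid[2]), 0)
  o <- order(cy, cx)
  masks <- masks[o]
  for (i in seq_along(masks)) {
    masks[[i]]$label <- i
    class(masks[[i]]) <- "bouton_mask"
  }
  masks
}

#' Center slice of a bouton
#'
#' Returns the Z index of the slice on which the bouton's membrane-enclosed
#' area is maximal (the "maximum area" optical section convention). Ties are
#' broken toward the middle of the stack (and toward the lower index at equal
#' distance from the middle).
#'
#' @param membrane `calibrated_stack` (membrane channel) or `nmj_scene`.
#' @param mask a `bouton_mask` from [segment_boutons()] on this scene.
#' @param threshold threshold for the per-slice rim signal; defaults to the
#'   one stored in the mask.
#' @return integer slice index (1-based).
#' @export
center_slice <- function(membrane, mask, threshold = NULL) {
  if (inherits(membrane, "nmj_scene"))
    membrane <- scene_channel(membrane, "membrane")
  nz <- n_slices(membrane)
  if (nz == 1L) return(1L)
  thr <- threshold %||% mask$threshold %||%
    otsu_threshold(as.vector(membrane$voxels))
  areas <- numeric(nz)
  for (z in seq_len(nz)) {
    bin <- (membrane$voxels[, , z] > thr) * 1
    filled <- .as_logical_mask(EBImage::fillHull(
      EBImage::closing(bin, EBImage::makeBrush(7L, "disc"))))
    areas[z] <- sum(filled & mask$footprint)
  }
  cand <- which(areas == max(areas))
  mid <- (nz + 1) / 2
  cand[order(abs(cand - mid), cand)][1]
}

#' Filter boutons by the type-Ib size range
#'
#' Inclusive bounds: a bouton with area exactly `low` or `high` is kept. The
#' partition is exhaustive and disjoint.
#'
#' @param masks list of `bouton_mask`s (or any lists with `area_um2`).
#' @param low,high size range in um^2; defaults to the type-Ib 2.5-12 um^2.
#' @return list with `kept` and `rejected`.
#' @export
filter_by_area <- function(masks, low = 2.5, high = 12) {
  stopifnot(low < high)
  areas <- vapply(masks, `[[`, 0, "area_um2")
  keep <- areas >= low & areas <= high
  list(kept = masks[keep], rejected = masks[!keep])
}

#' Fit the bouton-size distribution with BIC model selection
#'
#' Fits Gaussian mixtures with k = 1..`max_components` components
#' (unequal variances, maximum likelihood via EM) to the area sample and
#' scores each with BIC = -2 log L + p log n, p = 3k - 1. The selected k
#' minimizes BIC, ties broken toward smaller k. The type-Ib range is reported
#' as the dominant (largest-weight) component's mean +/- 2 s.d., clipped to
#' positive values — a declared convention for turning the fitted model into
#' an interval.
#'
#' @param areas numeric vector of bouton areas (um^2), >= 10 observations.
#' @param max_components largest k to try (>= 1).
#' @param seed seed for the (deterministic, hierarchically initialized) fits;
#'   kept for interface stability.
#' @return object of class `size_model`: `areas`, `candidates` (per-k fit
#'   summaries), `bic_values`, `selected_k`, `type_ib_range`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_size_model <- function(areas, max_components = 4L, seed = 1L) {
  if (length(areas) < 10)
    .stop_validation("insufficient data: need >= 10 bouton areas")
  stopifnot(max_components >= 1)
  n <- length(areas)
  candidates <- vector("list", max_components)
  bic_values <- rep(NA_real_, max_components)
  withr::with_seed(seed, {
    for (k in seq_len(max_components)) {
      fit <- tryCatch(
        mclust::Mclust(areas, G = k,
                       modelNames = if (k == 1) "X" else "V",
                       verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit) || is.na(fit$loglik)) next
      p <- 3 * k - 1
      bic_values[k] <- -2 * fit$loglik + p * log(n)
      candidates[[k]] <- list(
        k = k, loglik = fit$loglik, n_params = p,
        means = as.numeric(fit$parameters$mean),
        sds = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
        weights = as.numeric(fit$parameters$pro) %||% 1)
    }
  })
  if (all(is.na(bic_values)))
    stop("all mixture fits failed", call. = FALSE)
  # argmin with ties toward smaller k: which.min returns the first minimum
  selected_k <- which.min(bic_values)
  sel <- candidates[[selected_k]]
  sds <- rep_len(sel$sds, selected_k)
  dom <- which.max(rep_len(sel$weights, selected_k))
  rng <- c(max(0, sel$means[dom] - 2 * sds[dom]), sel$means[dom] + 2 * sds[dom])
  structure(list(areas = areas, candidates = candidates,
                 bic_values = bic_values, selected_k = selected_k,
                 type_ib_range = rng),
            class = "size_model")
}

#' @export
print.size_model <- function(x, ...) {
  cat(sprintf("<size_model> n = %d areas; BIC-selected k = %d; type-Ib range %.2f-%.2f um^2\n",
              length(x$areas), x$selected_k, x$type_ib_range[1],
              x$type_ib_range[2]))
  cat("  BIC:", paste(sprintf("k=%d: %.1f", seq_along(x$bic_values),
                              x$bic_values), collapse = "  "), "\n")
  invisible(x)
}

#' Jaccard index between two masks
#'
#' Overlap score used to compare segmented footprints against ground truth.
#' @param a,b logical matrices of identical dimension.
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

#' Match segmented boutons to ground-truth footprints
#'
#' Greedy best-Jaccard matching; each truth footprint is matched to at most
#' one segmented mask.
#'
#' @param masks list of `bouton_mask`s.
#' @param truth_boutons list of generator bouton truths.
#' @return data.frame with `truth_id`, `mask_label`, `jaccard`.
#' @export
match_boutons <- function(masks, truth_boutons) {
  out <- data.frame(truth_id = seq_along(truth_boutons),
                    mask_label = NA_integer_, jaccard = NA_real_)
  if (length(masks) == 0) return(out)
  used <- logical(length(masks))
  for (i in seq_along(truth_boutons)) {
    js <- vapply(seq_along(masks), function(m)
      if (used[m]) -1 else jaccard(masks[[m]]$footprint,
                                   truth_boutons[[i]]$footprint), 0)
    best <- which.max(js)
    if (js[best] > 0) {
      out$mask_label[i] <- masks[[best]]$label
      out$jaccard[i] <- js[best]
      used[best] <- TRUE
    }
  }
  out
}
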
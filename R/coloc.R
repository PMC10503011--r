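# Object/threshold-based Manders colocalization between the vesicle-marker
# (CSP) channel and an endosome-marker (Rab) channel, computed in 3D inside
# the bouton mask replicated along the whole Z axis.

#' Segment a channel inside the Z-replicated bouton mask
#'
#' A voxel is positive iff it lies inside the 3D mask (the 2D footprint
#' replicated along Z) and its intensity is strictly above the threshold.
#' With `method = "otsu"` the threshold is computed from the within-mask
#' intensities only.
#'
#' @param channel `calibrated_stack` or `nmj_scene` + `role`.
#' @param mask a `bouton_mask` (non-empty footprint).
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_value threshold when `method = "fixed"`.
#' @param role channel role when a scene is passed.
#' @return list: `positive` (logical Y x X x Z array), `threshold`.
#' @export
segment_channel <- function(channel, mask, method = c("otsu", "fixed"),
                            fixed_value = NULL, role = NULL) {
  if (inherits(channel, "nmj_scene"))
    channel <- scene_channel(channel, role %||% "vesicle")
  method <- match.arg(method)
  fp <- mask$footprint
  if (!any(fp)) .stop_validation("empty mask")
  v <- channel$voxels
  nz <- dim(v)[3]
  mask3 <- array(fp, dim = dim(v))   # footprint replicated along Z
  thr <- if (method == "otsu") otsu_threshold(v[mask3]) else fixed_value
  list(positive = mask3 & (v > thr), threshold = thr)
}

#' Manders colocalization coefficients M1 and M2
#'
#' Thresholded (object-based) Manders coefficients, following the standard
#' plugin convention: M1 = sum of vesicle-channel intensity over voxels that
#' are positive in *both* channels, divided by the vesicle intensity over its
#' own positive voxels; M2 is the symmetric quantity for the endosome
#' channel. Raw (not binarized) intensities enter both sums; identical
#' channels under identical thresholds give exactly (1, 1), disjoint
#' segmented signals give (0, 0). Zero denominators are flagged undefined.
#'
#' @param vesicle,endosome `calibrated_stack`s sharing dimensions, or an
#'   `nmj_scene` passed as `vesicle` (roles `"vesicle"`/`"endosome"` used).
#' @param mask a `bouton_mask`.
#' @param method,fixed_values per-channel thresholds: `method` as in
#'   [segment_channel()], `fixed_values` a length-2 numeric
#'   (vesicle, endosome) when fixed.
#' @return object of class `coloc_result`: `m1`, `m2` in [0, 1] (NA when
#'   undefined), per-channel `thresholds`, `n_coloc_pixels`, `defined`.
#' @export
manders <- function(vesicle, endosome = NULL, mask,
                    method = c("otsu", "fixed"), fixed_values = NULL) {
  if (inherits(vesicle, "nmj_scene")) {
    sc <- vesicle
    vesicle <- scene_channel(sc, "vesicle")
    endosome <- scene_channel(sc, "endosome")
  }
  method <- match.arg(method)
  stopifnot(identical(dim(vesicle$voxels), dim(endosome$voxels)))
  fv <- if (method == "fixed") rep_len(fixed_values, 2L) else c(NA, NA)
  seg_v <- segment_channel(vesicle, mask, method, fv[1])
  seg_e <- segment_channel(endosome, mask, method, fv[2])
  v <- vesicle$voxels; e <- endosome$voxels
  both <- seg_v$positive & seg_e$positive
  den_v <- sum(v[seg_v$positive]); den_e <- sum(e[seg_e$positive])
  m1 <- if (den_v > 0) sum(v[both]) / den_v else NA_real_
  m2 <- if (den_e > 0) sum(e[both]) / den_e else NA_real_
  structure(list(bouton_label = mask$label %||% NA_integer_,
                 m1 = m1, m2 = m2,
                 thresholds = c(vesicle = seg_v$threshold,
                                endosome = seg_e$threshold),
                 n_coloc_pixels = sum(both),
                 defined = c(m1 = den_v > 0, m2 = den_e > 0)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> bouton %s: M1 = %.3f, M2 = %.3f (%d coloc voxels)\n",
              x$bouton_label, x$m1, x$m2, x$n_coloc_pixels))
  invisible(x)
}
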
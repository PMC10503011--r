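# Internal helpers shared across modules.

# Coerce an EBImage result back to a plain numeric matrix/array.
.as_num <- function(x) {
  x <- if (inherits(x, "Image")) EBImage::imageData(x) else x
  storage.mode(x) <- "double"
  x
}

.as_logical_mask <- function(x) {
  x <- if (inherits(x, "Image")) EBImage::imageData(x) else x
  array(x > 0.5, dim = dim(x))
}

# 3x3 full square structuring element: 8-connected morphology throughout.
.brush3 <- function() EBImage::makeBrush(3, shape = "box")

#' Otsu threshold of an intensity sample
#'
#' Computes the classic Otsu threshold (maximum between-class variance) on a
#' vector of intensities, binned into `levels` equal-width bins over the data
#' range. Implemented on a value vector so that thresholds can be computed
#' within a bouton mask only, which frame-based implementations cannot do.
#'
#' @param values numeric vector of intensities.
#' @param levels number of histogram bins.
#' @return the threshold (numeric scalar); pixels strictly above it are
#'   "positive". For a constant input the threshold equals that constant and a
#'   warning is raised (degenerate segmentation: nothing positive).
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 0)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("constant input: degenerate Otsu threshold, all-negative segmentation")
    return(rng[1])
  }
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, levels)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  # upper edge of the chosen bin: "positive" means strictly above
  breaks[k + 1L]
}

#' Normalized Gaussian spot kernel
#'
#' 2D isotropic Gaussian kernel sampled at pixel centers and normalized to sum
#' to 1, so that a spot of amplitude A integrates to A exactly. `sigma_px = 0`
#' returns a 1x1 identity kernel (all mass on one pixel).
#'
#' @param sigma_px standard deviation in pixels.
#' @param radius_px half-width of the kernel support; defaults to
#'   `ceiling(4 * sigma_px)`.
#' @return square numeric matrix summing to 1.
#' @export
gaussian_spot_kernel <- function(sigma_px, radius_px = NULL) {
  stopifnot(sigma_px >= 0)
  if (sigma_px == 0) return(matrix(1, 1, 1))
  if (is.null(radius_px)) radius_px <- ceiling(4 * sigma_px)
  ax <- seq(-radius_px, radius_px)
  g <- exp(-ax^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Rasterized disk mask
#'
#' Logical matrix with TRUE where the pixel center lies within `radius_px` of
#' the given center. Used for closed-form geometry checks (annulus areas) and
#' as the irregularity-0 limit of the bouton generator.
#'
#' @param radius_px disk radius in pixels.
#' @param canvas integer vector `c(ny, nx)`; defaults to a tight canvas with a
#'   2-pixel margin.
#' @param center `c(y, x)` center; defaults to the canvas center.
#' @return logical matrix.
#' @export
disk_mask <- function(radius_px, canvas = NULL, center = NULL) {
  if (is.null(canvas)) {
    side <- 2L * ceiling(radius_px) + 5L
    canvas <- c(side, side)
  }
  if (is.null(center)) center <- (canvas + 1) / 2
  yy <- matrix(seq_len(canvas[1]), canvas[1], canvas[2])
  xx <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius_px^2
}

# Max over the 8-neighborhood of each pixel (edges padded with -Inf).
.neighbor_max <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  out <- matrix(-Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)])
  }
  out
}

# Min over the 8-neighborhood (edges padded with +Inf). Used for plateau
# validity: a plateau is a maximum only if some neighbor is strictly smaller.
.neighbor_min <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  out <- matrix(Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmin(out, pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)])
  }
  out
}

# Round half toward the smaller index (top-left tie break).
.round_half_down <- function(x) ceiling(x - 0.5)

# Tiny FNV-1a hash over a canonical deparse of an R object; used only for
# provenance stamps in output tables, not for cryptographic purposes.
.param_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "niceNames")), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Bounding box of a logical mask: c(ymin, ymax, xmin, xmax).
.mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

# Area of a logical mask in um^2 given the XY pixel size in nm.
.mask_area_um2 <- function(mask, pixel_size_xy) {
  sum(mask) * (pixel_size_xy / 1000)^2
}

.stop_validation <- function(...) stop(..., call. = FALSE)
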
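# Calibrated stacks, scenes, TIFF/manifest I/O, measurement tables.

#' Calibrated intensity stack
#'
#' Container for one channel's 3D intensity volume together with its physical
#' calibration. Voxels are stored as a numeric array with dimensions
#' (Y, X, Z), 1-based indices; a matrix is accepted as a single-slice stack.
#' A pixel's physical footprint is `pixel_size_xy`^2 (nm^2); mask areas are
#' pixel counts times `(pixel_size_xy / 1000)^2` um^2.
#'
#' @param voxels numeric array (Y, X, Z) or matrix (Y, X); all values >= 0.
#' @param pixel_size_xy XY pixel size in nm (> 0).
#' @param z_step Z step in um (> 0).
#' @param channel_role one of `"membrane"`, `"vesicle"`, `"endosome"`,
#'   `"dye_load"`, `"dye_unload"`, `"other"`.
#' @param bit_depth acquisition bit depth metadata (8, 16, or 32 = float).
#' @return an object of class `calibrated_stack`.
#' @export
calibrated_stack <- function(voxels, pixel_size_xy, z_step,
                             channel_role = "other", bit_depth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  stopifnot(length(dim(voxels)) == 3L)
  if (!(pixel_size_xy > 0) || !(z_step > 0))
    .stop_validation("calibration must be positive (pixel_size_xy, z_step)")
  if (any(voxels < 0)) .stop_validation("intensities must be non-negative")
  d <- dim(voxels)
  if (d[1] < 8L || d[2] < 8L) .stop_validation("Y and X must be >= 8 pixels")
  if (d[3] < 1L) .stop_validation("at least one slice required")
  channel_role <- match.arg(channel_role,
    c("membrane", "vesicle", "endosome", "dye_load", "dye_unload", "other"))
  if (!bit_depth %in% c(8L, 16L, 32L))
    .stop_validation("bit_depth must be 8, 16 or 32")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy, z_step = z_step,
         channel_role = channel_role, bit_depth = as.integer(bit_depth)),
    class = "calibrated_stack")
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<calibrated_stack> %s: %d x %d x %d, %.4g nm/px XY, %.4g um Z-step, %d-bit\n",
              x$channel_role, d[1], d[2], d[3], x$pixel_size_xy, x$z_step,
              x$bit_depth))
  invisible(x)
}

#' Number of Z slices in a stack
#' @param stack a `calibrated_stack`.
#' @export
n_slices <- function(stack) dim(stack$voxels)[3]

#' Maximum-intensity Z projection
#'
#' @param stack a `calibrated_stack`.
#' @return numeric matrix (Y, X).
#' @export
max_projection <- function(stack) {
  v <- stack$voxels
  if (dim(v)[3] == 1L) return(v[, , 1])
  apply(v, c(1, 2), max)
}

#' Multi-channel scene
#'
#' A named collection of [calibrated_stack()] channels (by role) sharing
#' identical dimensions and calibration.
#'
#' @param channels named list of `calibrated_stack`s; names are roles.
#' @param experiment_id free-text experiment label.
#' @param condition one of `"unstimulated"`, `"stimulated"`, `"load"`,
#'   `"unload"`, `"n/a"`.
#' @return an object of class `nmj_scene`.
#' @export
nmj_scene <- function(channels, experiment_id = "exp", condition = "n/a") {
  stopifnot(is.list(channels), length(channels) >= 1)
  condition <- match.arg(condition,
    c("unstimulated", "stimulated", "load", "unload", "n/a"))
  roles <- vapply(channels, function(ch) ch$channel_role, "")
  if (is.null(names(channels)) || any(names(channels) == ""))
    names(channels) <- roles
  ref <- channels[[1]]
  for (ch in channels) {
    if (!identical(dim(ch$voxels), dim(ref$voxels)))
      .stop_validation("channel dimensions differ across the scene")
    if (ch$pixel_size_xy != ref$pixel_size_xy || ch$z_step != ref$z_step)
      .stop_validation("channel calibrations differ across the scene")
  }
  structure(list(channels = channels, experiment_id = experiment_id,
                 condition = condition),
            class = "nmj_scene")
}

#' @export
print.nmj_scene <- function(x, ...) {
  cat(sprintf("<nmj_scene> '%s' (%s): %d channel(s): %s\n", x$experiment_id,
              x$condition, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel by role
#'
#' @param scene an `nmj_scene`.
#' @param role channel role; a validation error is raised when absent so that
#'   the role mapping stays total.
#' @export
scene_channel <- function(scene, role) {
  if (!role %in% names(scene$channels))
    .stop_validation(sprintf("scene has no '%s' channel (has: %s)", role,
                             paste(names(scene$channels), collapse = ", ")))
  scene$channels[[role]]
}

# ---- TIFF + manifest I/O ----------------------------------------------------

.read_tiff_volume <- function(path, bit_depth) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = bit_depth %in% c(8L, 16L))
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) != 2L, TRUE)))
    stop("only single-sample (grayscale) TIFFs are supported: ", path)
  v <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) v[, , i] <- frames[[i]]
  v
}

.write_tiff_volume <- function(voxels, path, bit_depth) {
  nz <- dim(voxels)[3]
  if (bit_depth %in% c(8L, 16L)) {
    mx <- 2^bit_depth - 1
    if (any(voxels > mx) || any(voxels != round(voxels)))
      stop(sprintf("voxels must be integers in [0, %d] for %d-bit storage",
                   mx, bit_depth))
    frames <- lapply(seq_len(nz), function(z) voxels[, , z] / mx)
  } else {
    if (any(voxels > 1))
      stop("32-bit float TIFF storage requires intensities in [0, 1]")
    frames <- lapply(seq_len(nz), function(z) voxels[, , z])
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a multi-channel scene
#'
#' Reads one grayscale TIFF Z-stack per channel and assembles a scene. Either
#' pass the per-channel `paths`/`roles`/`calibration` explicitly, or give a
#' YAML manifest written by [write_scene()].
#'
#' @param paths character vector of TIFF paths (one per channel), or a single
#'   manifest YAML path with `roles`/`calibration` omitted.
#' @param calibration list with `pixel_size_xy` (nm) and `z_step` (um).
#' @param roles character vector of channel roles matching `paths`.
#' @param bit_depth per-channel bit depths (recycled).
#' @param experiment_id,condition scene metadata.
#' @return an [nmj_scene()]; raw integer intensities are preserved bit-exactly.
#' @export
read_scene <- function(paths, calibration = NULL, roles = NULL,
                       bit_depth = 16L, experiment_id = "exp",
                       condition = "n/a") {
  if (length(paths) == 1L && grepl("\\.ya?ml$", paths)) {
    man <- yaml::read_yaml(paths)
    base <- dirname(paths)
    paths <- file.path(base, vapply(man$channels, `[[`, "", "file"))
    roles <- vapply(man$channels, `[[`, "", "role")
    bit_depth <- vapply(man$channels, function(ch)
      as.integer(ch$bit_depth %||% 16L), 1L)
    calibration <- man$calibration
    experiment_id <- man$experiment_id %||% experiment_id
    condition <- man$condition %||% condition
  }
  stopifnot(length(paths) == length(roles))
  if (is.null(calibration))
    .stop_validation("calibration must be supplied")
  bit_depth <- rep_len(as.integer(bit_depth), length(paths))
  missing <- !file.exists(paths)
  if (any(missing)) stop("cannot read: ", paste(paths[missing], collapse = ", "))
  channels <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    v <- .read_tiff_volume(paths[i], bit_depth[i])
    channels[[i]] <- calibrated_stack(v, calibration$pixel_size_xy,
                                      calibration$z_step, roles[i],
                                      bit_depth[i])
  }
  names(channels) <- roles
  nmj_scene(channels, experiment_id = experiment_id, condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scene to per-channel TIFFs plus a YAML manifest
#'
#' One file per channel (role encoded in the manifest), 8/16-bit integer data
#' stored bit-exactly. Returns the manifest path.
#'
#' @param scene an `nmj_scene`.
#' @param dir output directory (created if needed).
#' @param name basename for the manifest and channel files.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (role in names(scene$channels)) {
    ch <- scene$channels[[role]]
    fn <- sprintf("%s_%s.tif", name, role)
    .write_tiff_volume(ch$voxels, file.path(dir, fn), ch$bit_depth)
    entries[[length(entries) + 1L]] <-
      list(file = fn, role = role, bit_depth = ch$bit_depth)
  }
  ref <- scene$channels[[1]]
  man <- list(
    experiment_id = scene$experiment_id,
    condition = scene$condition,
    calibration = list(pixel_size_xy = ref$pixel_size_xy, z_step = ref$z_step),
    channels = entries)
  man_path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(man, man_path)
  invisible(man_path)
}

# ---- measurement tables -----------------------------------------------------

.measurement_cols <- c("scene_id", "bouton_id", "metric", "value", "units")

#' Write a per-bouton measurement table
#'
#' Fixed-schema UTF-8 CSV (`scene_id, bouton_id, metric, value, units`),
#' deterministically sorted by (scene_id, bouton_id, metric); floats printed
#' with 9 significant digits so repeated runs diff bit-stably.
#'
#' @param rows data.frame with the schema columns (may have zero rows).
#' @param path output CSV path.
#' @export
write_measurements <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- data.frame(scene_id = character(), bouton_id = integer(),
                       metric = character(), value = numeric(),
                       units = character())
  }
  stopifnot(all(.measurement_cols %in% names(rows)))
  rows <- rows[, .measurement_cols]
  o <- order(rows$scene_id, rows$bouton_id, rows$metric, method = "radix")
  rows <- rows[o, , drop = FALSE]
  rows$value <- vapply(rows$value, function(v)
    if (is.na(v)) "NA" else formatC(v, digits = 9, format = "g"), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.measurement_cols, collapse = ","), con)
  if (nrow(rows))
    writeLines(do.call(paste, c(unname(as.list(rows)), sep = ",")), con)
  invisible(path)
}

#' Read back a measurement table written by [write_measurements()]
#' @param path CSV path.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(scene_id = "character",
                                       bouton_id = "integer",
                                       metric = "character",
                                       value = "numeric",
                                       units = "character"))
  df
}

#' Assemble measurement rows
#' @param scene_id,bouton_id,metric,value,units vectors (recycled).
#' @export
measurement_rows <- function(scene_id, bouton_id, metric, value, units = "") {
  data.frame(scene_id = scene_id, bouton_id = as.integer(bouton_id),
             metric = metric, value = as.numeric(value), units = units,
             stringsAsFactors = FALSE)
}
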
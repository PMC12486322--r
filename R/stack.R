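#' Two-channel 3D image stack
#'
#' Container for a raw imaging stack of a cleared spinal cord segment.
#' Arrays are stored in (z, y, x) order, i.e. (dorsoventral, rostrocaudal,
#' mediolateral): z runs from the dorsal surface downwards, y along the
#' rostrocaudal axis and x along the mediolateral axis. Channel 1 holds the
#' tracer fluorescence (e.g. CTB-Alexa), channel 2 the tissue
#' autofluorescence recorded for background correction.
#'
#' @param tracer 3D numeric array of tracer-channel intensities (z, y, x).
#' @param autofluorescence 3D numeric array of the autofluorescence channel,
#'   same shape as `tracer`, or `NULL` for a single-channel (already
#'   background-corrected) stack.
#' @param voxel_size numeric length-3, physical voxel size in micrometres
#'   per axis, in (z, y, x) order. Defaults to the 1 x 1 um pixels with
#'   2 um z-steps typical of two-photon dorsal-horn stacks.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(tracer, autofluorescence = NULL,
                       voxel_size = c(2, 1, 1)) {
  tracer <- as.array(tracer)
  if (length(dim(tracer)) != 3L)
    stop("`tracer` must be a 3D array in (z, y, x) order")
  if (!is.null(autofluorescence)) {
    autofluorescence <- as.array(autofluorescence)
    if (!identical(dim(autofluorescence), dim(tracer)))
      stop("channel shape mismatch: tracer is ",
           paste(dim(tracer), collapse = "x"), ", autofluorescence is ",
           paste(dim(autofluorescence), collapse = "x"))
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (z, y, x) in um")
  if (any(tracer < 0, na.rm = TRUE) ||
      (!is.null(autofluorescence) && any(autofluorescence < 0, na.rm = TRUE)))
    stop("intensities must be non-negative")
  structure(list(tracer = tracer, autofluorescence = autofluorescence,
                 voxel_size = voxel_size),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$tracer)
  cat("voxel_grid: ", d[1], " x ", d[2], " x ", d[3],
      " voxels (z,y,x), ",
      if (is.null(x$autofluorescence)) "1 channel" else "2 channels",
      ", voxel size ", paste(x$voxel_size, collapse = " x "), " um\n",
      sep = "")
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$tracer)

#' Binary mask of terminal-positive voxels
#'
#' @param mask 3D logical (or 0/1) array in (z, y, x) order.
#' @param voxel_size numeric length-3 voxel size in um (z, y, x).
#' @param provenance named list recording how the mask was produced
#'   (threshold used, voxels removed by denoising, configuration).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, voxel_size = c(2, 1, 1), provenance = list()) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array in (z, y, x) order")
  storage.mode(mask) <- "logical"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values (z, y, x) in um")
  if (!is.null(provenance$threshold) &&
      is.finite(provenance$threshold) && provenance$threshold < 0)
    stop("recorded threshold must be >= 0")
  structure(list(mask = mask, voxel_size = voxel_size,
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat("binary_mask: ", d[1], " x ", d[2], " x ", d[3],
      " voxels (z,y,x), ", sum(x$mask), " positive\n", sep = "")
  if (!is.null(x$provenance$threshold))
    cat("  threshold: ", format(x$provenance$threshold), "\n", sep = "")
  if (!is.null(x$provenance$removed))
    cat("  removed as isolated: ", x$provenance$removed, "\n", sep = "")
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$mask)

#' Image-processing pipeline configuration
#'
#' Thresholding and denoising parameters for the stack-processing and
#' morphometry steps. The stack binarization threshold is the stack mean
#' grey value plus `k_bin` standard deviations; the summed-projection
#' threshold used for span measurement is the projection mean plus
#' `k_span` standard deviations.
#'
#' @param k_bin positive multiplier on the stack SD for binarization
#'   (default 3).
#' @param k_span positive multiplier on the projection SD for span
#'   measurement (default 1).
#' @param connectivity 3D neighbourhood used when removing isolated voxels:
#'   6 (faces), 18 (faces+edges) or 26 (full cube, default).
#' @param strict logical; if `TRUE` (default) a voxel must strictly exceed
#'   the threshold to be positive, making a constant stack yield an empty
#'   mask.
#' @param density_on_thresholded logical; if `TRUE` the areal-density
#'   denominator uses the `k_span`-thresholded projection instead of all
#'   positive projection pixels (default `FALSE`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_bin = 3, k_span = 1, connectivity = 26L,
                            strict = TRUE, density_on_thresholded = FALSE) {
  if (!is.numeric(k_bin) || k_bin <= 0) stop("`k_bin` must be > 0")
  if (!is.numeric(k_span) || k_span <= 0) stop("`k_span` must be > 0")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(k_bin = k_bin, k_span = k_span,
                 connectivity = connectivity, strict = isTRUE(strict),
                 density_on_thresholded = isTRUE(density_on_thresholded)),
            class = "pipeline_config")
}

# population SD (divisor n), the convention of image-histogram statistics
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Subtract the autofluorescence channel from the tracer channel
#'
#' Background fluorescence is reduced by voxelwise subtraction of the
#' autofluorescence channel from the tracer channel; negative differences
#' are clamped to zero since intensities are non-negative.
#'
#' @param grid a two-channel [voxel_grid].
#' @return A single-channel `voxel_grid` with the same voxel size.
#' @export
subtract_autofluorescence <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(grid$autofluorescence))
    stop("`grid` has no autofluorescence channel to subtract")
  out <- grid$tracer - grid$autofluorescence
  out[out < 0] <- 0
  voxel_grid(out, NULL, grid$voxel_size)
}

#' Binarize a stack by stack-histogram thresholding
#'
#' The threshold is computed from the histogram of the whole stack as the
#' mean grey value plus `k_bin` times the (population) standard deviation;
#' because most voxels are background, mean + 3 SD is a high-percentile
#' cut that isolates labelled terminals. A voxel is positive iff its
#' intensity exceeds the threshold (strictly, by default).
#'
#' @param grid a single-channel [voxel_grid] (background-subtract first;
#'   see [subtract_autofluorescence]).
#' @param config a [pipeline_config].
#' @return A [binary_mask] whose provenance records the threshold.
#' @export
binarize_stack <- function(grid, config = pipeline_config()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(config, "pipeline_config"))
  if (!is.null(grid$autofluorescence))
    stop("`grid` still has two channels; subtract the autofluorescence ",
         "channel first")
  x <- grid$tracer
  if (length(x) == 0L) stop("empty stack")
  thr <- mean(x) + config$k_bin * pop_sd(x)
  mask <- if (config$strict) x > thr else x >= thr
  binary_mask(mask, grid$voxel_size,
              provenance = list(threshold = thr, k_bin = config$k_bin,
                                strict = config$strict))
}

# neighbour offsets for a given 3D connectivity
connectivity_offsets <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  ord <- abs(off$dz) + abs(off$dy) + abs(off$dx)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(off)))
  off[keep, , drop = FALSE]
}

# zero-padded shift of a 3D array
shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dim = d)
  src_z <- max(1, 1 - dz):min(d[1], d[1] - dz)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_x <- max(1, 1 - dx):min(d[3], d[3] - dx)
  out[src_z + dz, src_y + dy, src_x + dx] <- a[src_z, src_y, src_x]
  out
}

# number of positive neighbours per voxel under the given connectivity
neighbour_counts <- function(mask, connectivity = 26L) {
  off <- connectivity_offsets(connectivity)
  counts <- array(0L, dim = dim(mask))
  for (i in seq_len(nrow(off)))
    counts <- counts + shift3(mask, off$dz[i], off$dy[i], off$dx[i])
  counts
}

#' Remove isolated positive voxels
#'
#' A positive voxel with no positive neighbour under the configured 3D
#' connectivity is removed; this suppresses hot pixels and shot noise
#' without eroding connected terminal clouds. The operation is idempotent:
#' isolated voxels are nobody's neighbour, so removing them cannot isolate
#' others.
#'
#' @param mask a [binary_mask].
#' @param config a [pipeline_config]; `config$connectivity` selects the
#'   neighbourhood (6, 18 or 26-connected).
#' @return A [binary_mask] whose provenance records the removal count.
#' @export
remove_isolated_voxels <- function(mask, config = pipeline_config()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(config, "pipeline_config"))
  nb <- neighbour_counts(mask$mask, config$connectivity)
  keep <- mask$mask & nb > 0L
  prov <- mask$provenance
  prov$removed <- sum(mask$mask) - sum(keep)
  prov$connectivity <- config$connectivity
  binary_mask(keep, mask$voxel_size, prov)
}

#' Process a raw two-channel stack into a denoised binary mask
#'
#' Convenience composition of [subtract_autofluorescence],
#' [binarize_stack] and [remove_isolated_voxels].
#'
#' @param grid a two-channel [voxel_grid].
#' @param config a [pipeline_config].
#' @return A [binary_mask].
#' @export
process_stack <- function(grid, config = pipeline_config()) {
  remove_isolated_voxels(
    binarize_stack(subtract_autofluorescence(grid), config), config)
}
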
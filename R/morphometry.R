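#' Centre of mass of a binary voxel cloud
#'
#' The focus of a terminal field is the unweighted centroid of its
#' positive voxels (the stacks are binarized before this step, so no
#' intensity weighting applies). Micrometre coordinates place the first
#' voxel centre at 0 um on each axis.
#'
#' @param mask a [binary_mask] with at least one positive voxel.
#' @return A list with `voxel` (z, y, x voxel coordinates, 1-based) and
#'   `um` (z, y, x in micrometres).
#' @export
centre_of_mass <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask has no positive voxels; centre of mass undefined")
  vox <- colMeans(idx)
  names(vox) <- c("z", "y", "x")
  um <- (vox - 1) * mask$voxel_size
  list(voxel = vox, um = um)
}

# nearest-voxel rounding with ties toward negative infinity
round_half_down <- function(x) ceiling(x - 0.5)

#' Align a mask to its centre of mass
#'
#' Crops (and zero-pads where the window leaves the original grid) a mask
#' to a fixed window shape centred on the centre of mass of the voxel
#' cloud, so that specimens can be compared and averaged in register.
#'
#' @param mask a non-empty [binary_mask].
#' @param window integer length-3, the output shape (z, y, x).
#' @return A [binary_mask] of exactly the window shape.
#' @export
align_to_centre <- function(mask, window) {
  stopifnot(inherits(mask, "binary_mask"))
  window <- as.integer(window)
  if (length(window) != 3L || any(window < 1L))
    stop("`window` must be three positive integers (z, y, x)")
  com <- centre_of_mass(mask)$voxel          # errors on empty mask
  centre <- round_half_down(com)
  out <- array(FALSE, dim = window)
  # output index o maps to input index o - wc + centre
  wc <- (window + 1L) %/% 2L
  d <- dim(mask$mask)
  o_lo <- pmax(1L, wc - centre + 1L)
  o_hi <- pmin(window, wc - centre + d)
  if (all(o_lo <= o_hi)) {
    i_lo <- o_lo - wc + centre
    i_hi <- o_hi - wc + centre
    out[o_lo[1]:o_hi[1], o_lo[2]:o_hi[2], o_lo[3]:o_hi[3]] <-
      mask$mask[i_lo[1]:i_hi[1], i_lo[2]:i_hi[2], i_lo[3]:i_hi[3]]
  }
  prov <- mask$provenance
  prov$aligned_centre <- centre
  binary_mask(out, mask$voxel_size, prov)
}

#' Summed projection of a binary stack
#'
#' Collapses one anatomical axis by summing, so each pixel holds the
#' number of positive voxels along the collapsed axis. The sum over all
#' projection pixels therefore equals the positive-voxel count of the
#' mask. Axis labels name the collapsed axis: a "DV" projection collapses
#' z and shows the (RC, ML) plane; "RC" collapses y and shows (DV, ML);
#' "ML" collapses x and shows (DV, RC).
#'
#' @param mask a [binary_mask].
#' @param axis one of "DV", "RC", "ML" — the axis to collapse.
#' @return An object of class `projection2d`: an integer matrix with
#'   attributes `axis` (collapsed axis), `pixel_size` (um per remaining
#'   axis, row then column) and `plane` (remaining axis labels).
#' @export
summed_projection <- function(mask, axis = c("DV", "RC", "ML")) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.character(axis))
    stop("unknown projection axis; use \"DV\", \"RC\" or \"ML\"")
  axis <- match.arg(axis)
  m <- mask$mask
  dimn <- c(DV = 1L, RC = 2L, ML = 3L)
  collapse <- dimn[[axis]]
  keep <- setdiff(1:3, collapse)
  # colSums over the first index after rotating the collapsed axis to front
  p <- colSums(aperm(m, c(collapse, keep)))
  storage.mode(p) <- "integer"
  structure(p,
            axis = axis,
            plane = names(dimn)[keep],
            pixel_size = mask$voxel_size[keep],
            class = "projection2d")
}

#' @export
print.projection2d <- function(x, ...) {
  cat("projection2d: ", attr(x, "axis"), " projection, ",
      nrow(x), " x ", ncol(x), " pixels (",
      paste(attr(x, "plane"), collapse = ", "), "), total ",
      sum(x), " voxels\n", sep = "")
  invisible(x)
}

#' Display a summed projection
#'
#' @param x a `projection2d`.
#' @param ... passed to [graphics::image].
#' @export
plot.projection2d <- function(x, ...) {
  pl <- attr(x, "plane")
  ps <- attr(x, "pixel_size")
  graphics::image(x = (seq_len(nrow(x)) - 1) * ps[1],
                  y = (seq_len(ncol(x)) - 1) * ps[2],
                  z = unclass(x),
                  xlab = paste0(pl[1], " (um)"), ylab = paste0(pl[2], " (um)"),
                  col = grDevices::hcl.colors(16, "Spectral", rev = TRUE),
                  useRaster = TRUE, ...)
  invisible(x)
}

# threshold a projection at mean + k * population SD (strict by default)
threshold_projection <- function(p, k, strict = TRUE) {
  thr <- mean(p) + k * pop_sd(p)
  if (strict) p > thr else p >= thr
}

# extent (max - min + 1 pixels, in um) of TRUE entries along each matrix axis
bbox_extent <- function(sel, pixel_size) {
  if (!any(sel)) return(c(0, 0))
  idx <- which(sel, arr.ind = TRUE)
  (apply(idx, 2, max) - apply(idx, 2, min) + 1) * pixel_size
}

#' Terminal-field spans from thresholded summed projections
#'
#' The mediolateral and rostrocaudal spans are measured in the summed
#' dorsoventral projection, the dorsoventral span in the summed
#' rostrocaudal projection. Each projection is thresholded at its mean
#' grey value plus `k_span` standard deviations, and the span is the
#' extent of the axis-aligned bounding rectangle enclosing all surviving
#' pixels, in micrometres. A projection with no surviving pixel yields a
#' span of 0.
#'
#' @param mask a non-empty [binary_mask].
#' @param config a [pipeline_config] (`k_span`, `strict`).
#' @return Named numeric vector `c(ML =, RC =, DV =)` in um.
#' @export
measure_spans <- function(mask, config = pipeline_config()) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$mask)) stop("mask has no positive voxels; spans undefined")
  pdv <- summed_projection(mask, "DV")      # (RC, ML) plane
  prc <- summed_projection(mask, "RC")      # (DV, ML) plane
  sel_dv <- threshold_projection(pdv, config$k_span, config$strict)
  sel_rc <- threshold_projection(prc, config$k_span, config$strict)
  e_dv <- bbox_extent(sel_dv, attr(pdv, "pixel_size"))  # (RC, ML) um
  e_rc <- bbox_extent(sel_rc, attr(prc, "pixel_size"))  # (DV, ML) um
  c(ML = unname(e_dv[2]), RC = unname(e_dv[1]), DV = unname(e_rc[1]))
}

#' Areal density of a terminal field
#'
#' Total positive-voxel count divided by the area (in square micrometres)
#' occupied by positive pixels in the summed projection along the chosen
#' axis. By default every projection pixel containing at least one voxel
#' counts toward the area; set `density_on_thresholded` in the config to
#' use the span-measurement threshold instead.
#'
#' @param mask a non-empty [binary_mask].
#' @param axis projection to use: "DV" (default), "ML" or "RC".
#' @param config a [pipeline_config].
#' @return Density in voxels per um^2.
#' @export
areal_density <- function(mask, axis = c("DV", "ML", "RC"),
                          config = pipeline_config()) {
  stopifnot(inherits(mask, "binary_mask"))
  axis <- match.arg(axis)
  count <- sum(mask$mask)
  if (count == 0L) stop("mask has no positive voxels; density undefined")
  p <- summed_projection(mask, axis)
  occ <- if (config$density_on_thresholded)
    threshold_projection(p, config$k_span, config$strict)
  else p > 0
  area <- sum(occ) * prod(attr(p, "pixel_size"))
  count / area
}

#' Grey-white matter border annotation
#'
#' Manual annotations of the dorsal and medial grey-white matter borders
#' serve as the anatomical reference frame for terminal-field foci: the
#' dorsal border is a dorsoventral coordinate read from the rostrocaudal
#' projection, the medial border a mediolateral coordinate read from the
#' dorsoventral projection.
#'
#' @param dorsal_um dorsoventral (z) coordinate of the dorsal border, um.
#' @param medial_um mediolateral (x) coordinate of the medial border, um.
#' @return An object of class `border_annotation`.
#' @export
border_annotation <- function(dorsal_um, medial_um) {
  if (missing(dorsal_um) || missing(medial_um) ||
      !is.finite(dorsal_um) || !is.finite(medial_um))
    stop("both `dorsal_um` and `medial_um` must be supplied and finite")
  structure(list(dorsal_um = as.numeric(dorsal_um),
                 medial_um = as.numeric(medial_um)),
            class = "border_annotation")
}

#' Focus offsets relative to the grey-white matter borders
#'
#' Distance between the terminal-field centre of mass and the medial
#' border (mediolateral offset, as seen in the dorsoventral projection)
#' and the dorsal border (dorsoventral offset, as seen in the
#' rostrocaudal projection).
#'
#' @param mask a non-empty [binary_mask].
#' @param borders a [border_annotation].
#' @return Named numeric vector `c(ML = , DV = )`, offsets in um.
#' @export
focus_offsets <- function(mask, borders) {
  stopifnot(inherits(mask, "binary_mask"))
  if (missing(borders) || !inherits(borders, "border_annotation"))
    stop("`borders` must be a border_annotation")
  com <- centre_of_mass(mask)$um
  c(ML = unname(abs(com[["x"]] - borders$medial_um)),
    DV = unname(abs(com[["z"]] - borders$dorsal_um)))
}

#' Planar shift between two terminal-field foci
#'
#' Euclidean norm of a (mediolateral, dorsoventral) displacement, the
#' two-dimensional distance by which one group's focus is shifted
#' relative to the other.
#'
#' @param delta_ml mediolateral displacement, um.
#' @param delta_dv dorsoventral displacement, um.
#' @return Shift magnitude in um.
#' @export
planar_shift <- function(delta_ml, delta_dv) {
  if (!is.finite(delta_ml) || !is.finite(delta_dv))
    stop("displacements must be finite")
  sqrt(delta_ml^2 + delta_dv^2)
}

#' Percent change relative to a reference value
#'
#' `100 * (comparison - reference) / reference`; positive values are
#' expansions (or increases), negative values reductions.
#'
#' @param reference reference (e.g. control-group) value, non-zero.
#' @param comparison comparison (e.g. mutant-group) value.
#' @return Percent change.
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference == 0)) stop("`reference` must be non-zero")
  100 * (comparison - reference) / reference
}

#' All terminal-field metrics for one specimen
#'
#' Computes the full per-specimen measurement set: centre of mass, spans,
#' areal densities in all three projections, positive-voxel count and
#' (when borders are given) focus offsets.
#'
#' @param mask a non-empty [binary_mask].
#' @param borders optional [border_annotation].
#' @param config a [pipeline_config].
#' @return An object of class `terminal_field_metrics` (a list).
#' @export
terminal_field_metrics <- function(mask, borders = NULL,
                                   config = pipeline_config()) {
  com <- centre_of_mass(mask)
  spans <- measure_spans(mask, config)
  dens <- c(DV = areal_density(mask, "DV", config),
            ML = areal_density(mask, "ML", config),
            RC = areal_density(mask, "RC", config))
  off <- if (!is.null(borders)) focus_offsets(mask, borders) else
    c(ML = NA_real_, DV = NA_real_)
  structure(list(com_voxel = com$voxel, com_um = com$um,
                 spans_um = spans, density_vox_um2 = dens,
                 offsets_um = off, voxel_count = sum(mask$mask)),
            class = "terminal_field_metrics")
}

#' @export
print.terminal_field_metrics <- function(x, ...) {
  cat("terminal_field_metrics\n")
  cat("  voxels:   ", x$voxel_count, "\n", sep = "")
  cat("  focus um: z=", round(x$com_um[["z"]], 2),
      " y=", round(x$com_um[["y"]], 2),
      " x=", round(x$com_um[["x"]], 2), "\n", sep = "")
  cat("  spans um: ML=", round(x$spans_um[["ML"]], 1),
      " RC=", round(x$spans_um[["RC"]], 1),
      " DV=", round(x$spans_um[["DV"]], 1), "\n", sep = "")
  cat("  density:  DV=", signif(x$density_vox_um2[["DV"]], 4),
      " ML=", signif(x$density_vox_um2[["ML"]], 4),
      " RC=", signif(x$density_vox_um2[["RC"]], 4), " voxels/um^2\n",
      sep = "")
  if (is.finite(x$offsets_um[["ML"]]))
    cat("  offsets:  ML=", round(x$offsets_um[["ML"]], 2),
        " DV=", round(x$offsets_um[["DV"]], 2), " um\n", sep = "")
  invisible(x)
}

# one data.frame row per specimen, used by run_pipeline and the writers
metrics_row <- function(m) {
  data.frame(com_z_um = m$com_um[["z"]], com_y_um = m$com_um[["y"]],
             com_x_um = m$com_um[["x"]],
             span_ml_um = m$spans_um[["ML"]], span_rc_um = m$spans_um[["RC"]],
             span_dv_um = m$spans_um[["DV"]],
             density_dv = m$density_vox_um2[["DV"]],
             density_ml = m$density_vox_um2[["ML"]],
             density_rc = m$density_vox_um2[["RC"]],
             offset_ml_um = m$offsets_um[["ML"]],
             offset_dv_um = m$offsets_um[["DV"]],
             voxel_count = m$voxel_count)
}
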
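#' Parameters for a synthetic terminal-field phantom stack
#'
#' Describes a two-channel phantom stack: one or more anisotropic
#' Gaussian intensity blobs (diffuse voxel clouds standing in for
#' labelled terminal fields) over an autofluorescent background with
#' additive Gaussian noise and sparse hot pixels. The ground-truth
#' support of the field is defined as the voxels whose noise-free
#' intensity exceeds half of the maximum noise-free intensity, which
#' makes the truth unambiguous for parameter-recovery tests.
#'
#' Defaults follow two-photon dorsal-horn stacks: 1 x 1 um pixels with a
#' 2 um z-step. Blob centres are in voxel coordinates (z, y, x, 1-based),
#' spreads are Gaussian SDs in micrometres per axis.
#'
#' @param shape integer length-3 grid shape (z, y, x), each >= 3.
#' @param voxel_size voxel size in um (z, y, x).
#' @param blobs data.frame with columns `cz, cy, cx` (centre, voxels),
#'   `sz, sy, sx` (spread, um) and `peak` (peak intensity). The default is
#'   a single centred blob whose geometry makes the stack-histogram
#'   mean + 3 SD threshold fall near the blob half-maximum.
#' @param background_mean,background_sd autofluorescence level and
#'   additive noise SD, identical in both channels.
#' @param hot_pixel_rate fraction of voxels replaced by hot pixels, in
#'   `[0, 1]`.
#' @param hot_pixel_intensity intensity of hot pixels.
#' @param seed integer random seed; identical seed and parameters
#'   reproduce the stack exactly.
#' @return An object of class `stack_phantom_params`.
#' @export
stack_phantom_params <- function(shape = c(24L, 100L, 50L),
                                 voxel_size = c(2, 1, 1),
                                 blobs = NULL,
                                 background_mean = 10, background_sd = 2,
                                 hot_pixel_rate = 1e-4,
                                 hot_pixel_intensity = 200,
                                 seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 3L))
    stop("degenerate grid: every dimension must be at least 3 voxels")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive values")
  if (is.null(blobs))
    blobs <- data.frame(cz = (shape[1] + 1) / 2, cy = (shape[2] + 1) / 2,
                        cx = (shape[3] + 1) / 2,
                        sz = 7, sy = 12.5, sx = 12.5, peak = 100)
  need <- c("cz", "cy", "cx", "sz", "sy", "sx", "peak")
  if (!all(need %in% names(blobs)))
    stop("`blobs` needs columns ", paste(need, collapse = ", "))
  if (any(blobs[, c("sz", "sy", "sx")] <= 0)) stop("blob spreads must be > 0")
  if (any(blobs$peak <= 0)) stop("blob peaks must be > 0")
  if (!is.numeric(hot_pixel_rate) || hot_pixel_rate < 0 || hot_pixel_rate > 1)
    stop("`hot_pixel_rate` must be in [0, 1]")
  if (background_sd < 0) stop("`background_sd` must be >= 0")
  structure(list(shape = shape, voxel_size = voxel_size, blobs = blobs,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_intensity = hot_pixel_intensity,
                 seed = as.integer(seed)),
            class = "stack_phantom_params")
}

# noise-free Gaussian blob field on the voxel grid
render_blobs <- function(shape, voxel_size, blobs) {
  field <- array(0, dim = shape)
  z <- seq_len(shape[1]); y <- seq_len(shape[2]); x <- seq_len(shape[3])
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    gz <- exp(-0.5 * ((z - b$cz) * voxel_size[1] / b$sz)^2)
    gy <- exp(-0.5 * ((y - b$cy) * voxel_size[2] / b$sy)^2)
    gx <- exp(-0.5 * ((x - b$cx) * voxel_size[3] / b$sx)^2)
    field <- field + b$peak * (gz %o% gy %o% gx)
  }
  field
}

# additive background: Gaussian noise clipped at zero, plus hot pixels
render_background <- function(shape, mean, sd, hot_rate, hot_intensity) {
  n <- prod(shape)
  bg <- array(pmax(0, stats::rnorm(n, mean, sd)), dim = shape)
  if (hot_rate > 0) {
    nhot <- stats::rbinom(1L, n, hot_rate)
    if (nhot > 0) bg[sample.int(n, nhot)] <- hot_intensity
  }
  bg
}

# ground truth computed from a noise-free support array
support_truth <- function(support, voxel_size) {
  idx <- which(support, arr.ind = TRUE)
  count <- nrow(idx)
  if (count == 0L) {
    return(list(centre_voxel = rep(NA_real_, 3), centre_um = rep(NA_real_, 3),
                count = 0L, extent_um = c(DV = 0, RC = 0, ML = 0),
                projection_area_um2 = c(DV = 0, RC = 0, ML = 0)))
  }
  centre <- colMeans(idx)
  names(centre) <- c("z", "y", "x")
  extent <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * voxel_size
  d <- dim(support)
  area <- function(keep) {
    px <- (idx[, keep[1]] - 1) * d[keep[2]] + idx[, keep[2]]
    length(unique(px)) * prod(voxel_size[keep])
  }
  list(centre_voxel = centre, centre_um = (centre - 1) * voxel_size,
       count = count,
       extent_um = c(DV = unname(extent[1]), RC = unname(extent[2]),
                     ML = unname(extent[3])),
       projection_area_um2 = c(DV = area(c(2, 3)), RC = area(c(1, 3)),
                               ML = area(c(1, 2))))
}

#' Generate a synthetic two-channel terminal-field stack
#'
#' Channel 1 holds the blob intensities plus background noise and hot
#' pixels; channel 2 holds background noise of identical statistics (its
#' own hot pixels included) without the blobs, emulating the
#' autofluorescence channel so that channel subtraction is meaningful.
#' The ground truth is computed from the noise-free blob field: its
#' support is the set of voxels above half the maximum noise-free
#' intensity.
#'
#' @param params a [stack_phantom_params].
#' @return A list with `grid` (a [voxel_grid]) and `truth` (centre of
#'   mass in voxel and um coordinates, positive-voxel count, per-axis
#'   extent in um, per-axis occupied projection areas in um^2).
#' @export
generate_terminal_stack <- function(params = stack_phantom_params()) {
  stopifnot(inherits(params, "stack_phantom_params"))
  set.seed(params$seed)
  field <- render_blobs(params$shape, params$voxel_size, params$blobs)
  support <- field > max(field) / 2
  truth <- support_truth(support, params$voxel_size)
  ch1 <- field + render_background(params$shape, params$background_mean,
                                   params$background_sd,
                                   params$hot_pixel_rate,
                                   params$hot_pixel_intensity)
  ch2 <- render_background(params$shape, params$background_mean,
                           params$background_sd, params$hot_pixel_rate,
                           params$hot_pixel_intensity)
  list(grid = voxel_grid(ch1, ch2, params$voxel_size), truth = truth)
}

#' Parameters for a synthetic two-group imaging cohort
#'
#' Describes paired control and mutant cohorts of terminal-field
#' phantoms. Each specimen's field is an elliptical rostrocaudal band:
#' an elliptical footprint in the horizontal (ML-RC) plane of uniform
#' dorsoventral thickness, partially filled with contiguous columns of
#' labelled boutons (each image column inside the footprint carries a
#' contiguous run of positive voxels covering a configurable fill
#' fraction of the band thickness, at a random depth). This emulates the
#' narrow rostrocaudal band in which a single digit is represented, and
#' makes the configured effect multipliers act linearly on the measured
#' quantities: span multipliers scale the footprint axes, the density
#' multiplier scales the column fill fraction, and the focus shift
#' displaces the band centre in the ML-DV plane.
#'
#' Default effect sizes mirror the terminal-field phenotype they emulate:
#' mutant fields extend 14% further mediolaterally and 30% further
#' rostrocaudally, are 22% less dense, and their foci are displaced
#' laterally by 18.75 um and ventrally by 1.42 um.
#'
#' @param n_per_group specimens per group, length 1 or 2 (control,
#'   mutant), each >= 2. Defaults to the 8 control / 6 mutant design.
#' @param span_multipliers named numeric `c(ML=, RC=, DV=)`, mutant/control
#'   span ratios, all > 0.
#' @param density_multiplier mutant/control areal-density ratio, > 0.
#' @param focus_shift_um named numeric `c(ML=, DV=)`, mutant focus
#'   displacement in um (lateral = +ML, ventral = +DV).
#' @param shape,voxel_size grid geometry as in [stack_phantom_params].
#' @param semi_axes_um control-field semi-axes `c(ML=, RC=, DV=)` in um
#'   (the DV semi-axis is half the band thickness).
#' @param centre_um control band centre `c(z=, y=, x=)` in um; `NULL`
#'   centres the band in the grid with the ML centre placed so that the
#'   shifted mutant band still fits.
#' @param fill_fraction fraction of each column's thickness occupied by
#'   the bouton run in controls, in (0, 1).
#' @param peak intensity of labelled voxels.
#' @param background_mean,background_sd,hot_pixel_rate,hot_pixel_intensity
#'   background model, as in [stack_phantom_params].
#' @param centre_jitter_um per-specimen SD of the band-centre jitter (um).
#' @param span_jitter,density_jitter per-specimen lognormal SDs of the
#'   specimen's axis scales and fill fraction.
#' @param seed integer seed. Specimen-level seeds are drawn once and
#'   shared between the two groups (seed-matched pairing), so identity
#'   parameters yield bit-identical paired specimens.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = c(8L, 6L),
                          span_multipliers = c(ML = 1.14, RC = 1.30, DV = 1),
                          density_multiplier = 0.78,
                          focus_shift_um = c(ML = 18.75, DV = 1.42),
                          shape = c(24L, 180L, 96L),
                          voxel_size = c(2, 1, 1),
                          semi_axes_um = c(ML = 20, RC = 60, DV = 16),
                          centre_um = NULL,
                          fill_fraction = 0.35,
                          peak = 100,
                          background_mean = 10, background_sd = 2,
                          hot_pixel_rate = 1e-4, hot_pixel_intensity = 200,
                          centre_jitter_um = 1.5,
                          span_jitter = 0.03, density_jitter = 0.04,
                          seed = 1L) {
  n_per_group <- as.integer(rep_len(n_per_group, 2L))
  if (any(n_per_group < 2L))
    stop("at least 2 specimens per group are required (statistics are ",
         "undefined below that)")
  if (any(span_multipliers <= 0) || density_multiplier <= 0)
    stop("multipliers must be > 0")
  stopifnot(all(c("ML", "RC", "DV") %in% names(span_multipliers)),
            all(c("ML", "DV") %in% names(focus_shift_um)),
            all(c("ML", "RC", "DV") %in% names(semi_axes_um)))
  if (fill_fraction <= 0 || fill_fraction >= 1)
    stop("`fill_fraction` must be in (0, 1)")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 3L))
    stop("degenerate grid: every dimension must be at least 3 voxels")
  if (is.null(centre_um)) {
    ext <- shape * voxel_size
    # leave room on the lateral side for the mutant shift
    centre_um <- c(z = (shape[1] - 1) * voxel_size[1] / 2,
                   y = (shape[2] - 1) * voxel_size[2] / 2,
                   x = (ext[3] - max(0, focus_shift_um[["ML"]])) / 2)
  }
  structure(list(n_per_group = n_per_group,
                 span_multipliers = span_multipliers,
                 density_multiplier = density_multiplier,
                 focus_shift_um = focus_shift_um,
                 shape = shape, voxel_size = as.numeric(voxel_size),
                 semi_axes_um = semi_axes_um, centre_um = centre_um,
                 fill_fraction = fill_fraction, peak = peak,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 hot_pixel_rate = hot_pixel_rate,
                 hot_pixel_intensity = hot_pixel_intensity,
                 centre_jitter_um = centre_jitter_um,
                 span_jitter = span_jitter, density_jitter = density_jitter,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# one cohort specimen: band support + optional noisy two-channel stack
generate_band_specimen <- function(params, group, specimen_seed,
                                   stacks = TRUE) {
  set.seed(specimen_seed)
  mut <- group == "mutant"
  sm <- if (mut) params$span_multipliers else c(ML = 1, RC = 1, DV = 1)
  dm <- if (mut) params$density_multiplier else 1
  shift <- if (mut) params$focus_shift_um else c(ML = 0, DV = 0)
  vs <- params$voxel_size
  # specimen-level biological variability
  scale_j <- exp(stats::rnorm(3, 0, params$span_jitter))   # ML, RC, DV
  fill <- params$fill_fraction * dm *
    exp(stats::rnorm(1, 0, params$density_jitter))
  fill <- min(fill, 0.95)
  a_ml <- params$semi_axes_um[["ML"]] * sm[["ML"]] * scale_j[1]
  a_rc <- params$semi_axes_um[["RC"]] * sm[["RC"]] * scale_j[2]
  a_dv <- params$semi_axes_um[["DV"]] * sm[["DV"]] * scale_j[3]
  jit <- stats::rnorm(3, 0, params$centre_jitter_um)        # z, y, x
  cz_um <- params$centre_um[["z"]] + shift[["DV"]] + jit[1]
  cy_um <- params$centre_um[["y"]] + jit[2]
  cx_um <- params$centre_um[["x"]] + shift[["ML"]] + jit[3]
  # voxel-centre coordinates: voxel i sits at (i-1)*voxel_size um
  shp <- params$shape
  zc <- 1 + cz_um / vs[1]; yc <- 1 + cy_um / vs[2]; xc <- 1 + cx_um / vs[3]
  y <- seq_len(shp[2]); x <- seq_len(shp[3])
  # elliptical ML-RC footprint
  u2 <- outer(((y - yc) * vs[2] / a_rc)^2, ((x - xc) * vs[3] / a_ml)^2, "+")
  cols <- which(u2 < 1, arr.ind = TRUE)                    # (y, x) columns
  support <- array(FALSE, dim = shp)
  if (nrow(cols) > 0) {
    half_vox <- a_dv / vs[1]
    run_mean <- fill * 2 * half_vox
    nrun <- as.integer(pmax(1, floor(run_mean) +
                   stats::rbinom(nrow(cols), 1L, run_mean - floor(run_mean))))
    lo <- zc - half_vox
    start <- lo + stats::runif(nrow(cols)) * pmax(0, 2 * half_vox - nrun)
    s0 <- round_half_down(start)                           # nearest voxel
    zz <- sequence(nrun, from = s0)
    yy <- rep.int(cols[, 1L], nrun)
    xx <- rep.int(cols[, 2L], nrun)
    ok <- zz >= 1L & zz <= shp[1]
    support[cbind(zz[ok], yy[ok], xx[ok])] <- TRUE
  }
  truth <- support_truth(support, vs)
  out <- list(group = group, truth = truth, seed = specimen_seed)
  if (stacks) {
    ch1 <- params$peak * support +
      render_background(shp, params$background_mean, params$background_sd,
                        params$hot_pixel_rate, params$hot_pixel_intensity)
    ch2 <- render_background(shp, params$background_mean,
                             params$background_sd, params$hot_pixel_rate,
                             params$hot_pixel_intensity)
    out$grid <- voxel_grid(ch1, ch2, vs)
  } else {
    out$support <- binary_mask(support, vs,
                               provenance = list(source = "ground truth"))
  }
  out
}

# per-specimen seeds shared between groups (seed-matched pairing)
cohort_specimen_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a paired control/mutant cohort of phantom stacks
#'
#' Draws `n_per_group` specimens for each group with seed-matched
#' pairing: specimen j of both groups shares a specimen-level seed, so
#' with identity multipliers and zero displacement the two groups are
#' bit-identical, and any group difference is attributable to the
#' configured effects.
#'
#' @param params a [cohort_params].
#' @param stacks if `TRUE` (default) each specimen carries a noisy
#'   two-channel [voxel_grid]; if `FALSE` only the ground-truth support
#'   mask and truth summaries are returned (fast, for truth-level
#'   checks).
#' @return A list of specimens; each has `group` ("control" or
#'   "mutant"), `truth` (see [generate_terminal_stack]), and `grid` or
#'   `support`.
#' @export
generate_cohort <- function(params = cohort_params(), stacks = TRUE) {
  stopifnot(inherits(params, "cohort_params"))
  seeds <- cohort_specimen_seeds(params$seed, max(params$n_per_group))
  out <- list()
  for (g in c("control", "mutant")) {
    n <- params$n_per_group[if (g == "control") 1L else 2L]
    for (j in seq_len(n))
      out[[length(out) + 1L]] <-
        generate_band_specimen(params, g, seeds[j], stacks = stacks)
  }
  out
}
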
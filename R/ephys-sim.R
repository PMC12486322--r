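#' Mechanical stimulation protocol
#'
#' An ordered, non-overlapping sequence of stimulus epochs as delivered
#' in an ex vivo skin-nerve experiment. Epoch kinds are:
#' \describe{
#'   \item{ramp}{dynamic phase of a ramp-and-hold stimulus; `velocity_mm_s`
#'     is the probe velocity, `force_mN` the force reached.}
#'   \item{hold}{static phase at constant `force_mN`.}
#'   \item{vibration-ramp}{sinusoidal vibration of linearly increasing
#'     amplitude; the force envelope rises linearly from 0 to `force_mN`
#'     over the epoch and is used to read mechanical thresholds.}
#'   \item{manual-tap}{manually delivered brisk tap: a force step faster
#'     than the 1.5 mm/s ceiling of the electromechanical stimulator.}
#'   \item{none}{inter-stimulus gap.}
#' }
#'
#' @param epochs data.frame with columns `epoch` (id), `kind`, `start`,
#'   `end` (seconds) and the parameter columns `velocity_mm_s`,
#'   `force_mN`, `freq_Hz` (NA where not applicable).
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(epochs) {
  need <- c("epoch", "kind", "start", "end")
  if (!all(need %in% names(epochs)))
    stop("`epochs` needs columns ", paste(need, collapse = ", "))
  kinds <- c("ramp", "hold", "vibration-ramp", "manual-tap", "none")
  if (!all(epochs$kind %in% kinds))
    stop("unknown epoch kind; use ", paste(kinds, collapse = ", "))
  for (col in c("velocity_mm_s", "force_mN", "freq_Hz"))
    if (is.null(epochs[[col]])) epochs[[col]] <- NA_real_
  if (any(epochs$end <= epochs$start)) stop("epochs must have end > start")
  ord <- order(epochs$start)
  epochs <- epochs[ord, , drop = FALSE]
  if (any(epochs$start[-1] < epochs$end[-nrow(epochs)] - 1e-12))
    stop("epochs must be non-overlapping and ordered")
  rownames(epochs) <- NULL
  structure(list(epochs = epochs), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("stimulus_protocol: ", nrow(x$epochs), " epochs, ",
      format(max(x$epochs$end)), " s total\n", sep = "")
  print(x$epochs)
  invisible(x)
}

#' Standard stimulus battery
#'
#' The default protocol used for afferent classification: a 50 Hz
#' vibration of linearly increasing amplitude (0 to `vib_max_mN` over 5 s,
#' for mechanical thresholds), four ramp-and-hold stimuli at the standard
#' probe velocities 0.075, 0.15, 0.45 and 1.5 mm/s (96 um displacement,
#' ~40 mN, 2 s holds), one static series step with a fast force ramp
#' (1.75 mN/ms) to `static_force_mN` held for 2 s, and a final manual
#' tap. Epochs are separated by 0.5 s gaps.
#'
#' @param velocities_mm_s ramp velocities (mm/s).
#' @param displacement_um ramp displacement; ramp duration is
#'   `displacement_um / velocity`.
#' @param ramp_force_mN force reached by the velocity-series ramps.
#' @param hold_s hold duration.
#' @param static_force_mN force of the static-series hold.
#' @param vib_max_mN final amplitude of the vibration envelope.
#' @param vib_s vibration epoch duration.
#' @return A [stimulus_protocol].
#' @export
standard_protocol <- function(velocities_mm_s = c(0.075, 0.15, 0.45, 1.5),
                              displacement_um = 96,
                              ramp_force_mN = 40, hold_s = 2,
                              static_force_mN = 75,
                              vib_max_mN = 50, vib_s = 5) {
  gap <- 0.5
  rows <- list()
  t0 <- 0
  add <- function(kind, dur, velocity = NA, force = NA, freq = NA) {
    rows[[length(rows) + 1L]] <<-
      data.frame(epoch = length(rows) + 1L, kind = kind,
                 start = t0, end = t0 + dur,
                 velocity_mm_s = velocity, force_mN = force, freq_Hz = freq)
    t0 <<- t0 + dur + gap
  }
  add("vibration-ramp", vib_s, force = vib_max_mN, freq = 50)
  for (v in velocities_mm_s) {
    add("ramp", displacement_um / 1000 / v, velocity = v,
        force = ramp_force_mN)
    t0 <- t0 - gap                       # hold follows its ramp directly
    add("hold", hold_s, force = ramp_force_mN)
  }
  add("ramp", static_force_mN / 1.75 / 1000, velocity = 1.5,
      force = static_force_mN)           # fast force ramp, 1.75 mN/ms
  t0 <- t0 - gap
  add("hold", hold_s, force = static_force_mN)
  add("manual-tap", 0.05, force = 500)
  stimulus_protocol(do.call(rbind, rows))
}

#' Spike train of one fibre
#'
#' @param times numeric vector of spike times in seconds, strictly
#'   increasing, all >= 0.
#' @param id fibre identifier.
#' @param trace optional list(time, voltage) raw trace for detector tests.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, id = NA_character_, trace = NULL) {
  times <- as.numeric(times)
  if (any(times < 0)) stop("spike times must be >= 0")
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("spike times must be strictly increasing")
  structure(list(times = times, id = id, trace = trace),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train", if (!is.na(x$id)) paste0(" [", x$id, "]"), ": ",
      length(x$times), " spikes",
      if (length(x$times)) paste0(" over ",
                                  format(signif(max(x$times), 4)), " s"),
      "\n", sep = "")
  invisible(x)
}

#' Generative model of a single afferent fibre
#'
#' A seeded inhomogeneous-Poisson model, thinned by an absolute
#' refractory period, of the six afferent classes: during ramps the
#' firing rate is `dynamic_gain * velocity` provided the epoch force
#' exceeds the fibre's threshold; during holds it is
#' `static_gain * (force - threshold)` (zero for purely dynamic
#' receptors); during a vibration-ramp the fibre starts firing (at
#' `vib_rate_hz`) once the linearly rising force envelope crosses its
#' threshold; a manual tap elicits at most one spike. Tap-units respond
#' only to the manual tap; mechano-insensitive fibres never fire to
#' mechanical stimulation.
#'
#' @param class one of "RAM", "SAM", "D-hair", "AM", "tap-unit",
#'   "mechano-insensitive".
#' @param cv conduction velocity in m/s, > 0. Class default draws are
#'   not made here; supply the value (e.g. `runif(1, 11, 18)` for an
#'   A-beta fibre).
#' @param threshold_mN force threshold in mN, >= 0.
#' @param dynamic_gain firing-rate gain during ramps, Hz per mm/s, >= 0.
#' @param static_gain firing-rate gain during holds, Hz per suprathreshold
#'   mN, >= 0.
#' @param tap_prob probability that a manual tap elicits the single tap
#'   spike.
#' @param vib_rate_hz firing rate once the vibration envelope exceeds
#'   threshold.
#' @param refractory_ms absolute refractory period.
#' @param seed integer seed for response generation.
#' @return An object of class `fiber_model`.
#' @export
fiber_model <- function(class = c("RAM", "SAM", "D-hair", "AM", "tap-unit",
                                  "mechano-insensitive"),
                        cv = 14, threshold_mN = 7.5,
                        dynamic_gain = 80, static_gain = 0.5,
                        tap_prob = 0.95, vib_rate_hz = 50,
                        refractory_ms = 2, seed = 1L) {
  class <- match.arg(class)
  if (cv <= 0) stop("`cv` must be > 0")
  if (threshold_mN < 0) stop("`threshold_mN` must be >= 0")
  if (dynamic_gain < 0 || static_gain < 0) stop("gains must be >= 0")
  structure(list(class = class, cv = cv, threshold_mN = threshold_mN,
                 dynamic_gain = dynamic_gain, static_gain = static_gain,
                 tap_prob = tap_prob, vib_rate_hz = vib_rate_hz,
                 refractory_ms = refractory_ms, seed = as.integer(seed)),
            class = "fiber_model")
}

#' Class-typical fibre model
#'
#' Convenience constructor drawing class-typical parameters: RAMs and
#' SAMs are A-beta fibres (CV 11-18 m/s) with ~7 mN thresholds; SAMs add
#' a static gain sustaining ~30 Hz during suprathreshold holds; D-hairs
#' are ultra-sensitive A-delta fibres (threshold below 1 mN, high dynamic
#' gain); AMs are A-delta nociceptors with ~30 mN thresholds and no
#' static response; tap-units respond only to the manual tap;
#' mechano-insensitive fibres never respond to mechanical stimulation.
#' Parameter draws use `seed`; the model keeps the same seed for its
#' response generation.
#'
#' @param class afferent class label.
#' @param seed integer seed.
#' @return A [fiber_model].
#' @export
class_typical_fiber <- function(class = c("RAM", "SAM", "D-hair", "AM",
                                          "tap-unit",
                                          "mechano-insensitive"),
                                seed = 1L) {
  class <- match.arg(class)
  set.seed(seed)
  lmn <- function(m, s) stats::rlnorm(1, log(m), s)
  switch(class,
    "RAM" = fiber_model("RAM", cv = stats::runif(1, 11, 18),
                        threshold_mN = lmn(7, 0.3),
                        dynamic_gain = lmn(80, 0.2), static_gain = 0,
                        seed = seed),
    "SAM" = fiber_model("SAM", cv = stats::runif(1, 11, 18),
                        threshold_mN = lmn(7.5, 0.3),
                        dynamic_gain = lmn(80, 0.2),
                        static_gain = lmn(0.5, 0.2), seed = seed),
    "D-hair" = fiber_model("D-hair", cv = stats::runif(1, 3, 9),
                           threshold_mN = lmn(0.5, 0.3),
                           dynamic_gain = lmn(300, 0.2), static_gain = 0,
                           vib_rate_hz = 200, seed = seed),
    "AM" = fiber_model("AM", cv = stats::runif(1, 1.6, 9),
                       threshold_mN = lmn(30, 0.3),
                       dynamic_gain = lmn(30, 0.2), static_gain = 0,
                       seed = seed),
    "tap-unit" = fiber_model("tap-unit", cv = stats::runif(1, 11, 18),
                             threshold_mN = 500, dynamic_gain = 0,
                             static_gain = 0, seed = seed),
    "mechano-insensitive" = fiber_model("mechano-insensitive",
                                        cv = stats::runif(1, 2, 18),
                                        threshold_mN = Inf,
                                        dynamic_gain = 0, static_gain = 0,
                                        tap_prob = 0, seed = seed))
}

# homogeneous Poisson spike times within [t0, t1)
poisson_times <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1L, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate the spike response of a fibre to a protocol
#'
#' Draws spike times from the inhomogeneous rate implied by the fibre
#' model and the protocol epochs (see [fiber_model]), then enforces the
#' absolute refractory period by thinning. Identical model (seed
#' included) and protocol reproduce the train exactly.
#'
#' @param model a [fiber_model].
#' @param protocol a [stimulus_protocol].
#' @return A [spike_train].
#' @export
generate_fiber_response <- function(model, protocol) {
  stopifnot(inherits(model, "fiber_model"),
            inherits(protocol, "stimulus_protocol"))
  set.seed(model$seed)
  ep <- protocol$epochs
  times <- numeric(0)
  insensitive <- model$class == "mechano-insensitive"
  tap_only <- model$class == "tap-unit"
  for (i in seq_len(nrow(ep))) {
    e <- ep[i, ]
    if (insensitive) next
    tt <- switch(e$kind,
      "ramp" = if (!tap_only && is.finite(e$force_mN) &&
                   e$force_mN > model$threshold_mN)
        poisson_times(model$dynamic_gain * e$velocity_mm_s, e$start, e$end)
      else numeric(0),
      "hold" = if (!tap_only && is.finite(e$force_mN) &&
                   e$force_mN > model$threshold_mN)
        poisson_times(model$static_gain * (e$force_mN - model$threshold_mN),
                      e$start, e$end)
      else numeric(0),
      "vibration-ramp" = if (!tap_only && is.finite(e$force_mN) &&
                             e$force_mN > model$threshold_mN) {
        # linear envelope 0 -> force_mN: silent until threshold crossing
        t_cross <- e$start +
          (e$end - e$start) * model$threshold_mN / e$force_mN
        poisson_times(model$vib_rate_hz, t_cross, e$end)
      } else numeric(0),
      "manual-tap" = if (stats::runif(1) < model$tap_prob)
        e$start + stats::runif(1) * min(0.005, e$end - e$start)
      else numeric(0),
      "none" = numeric(0))
    times <- c(times, tt)
  }
  times <- sort(times)
  # absolute refractory period
  refr <- model$refractory_ms / 1000
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refr) {
      keep <- c(keep, t)
      last <- t
    }
  }
  spike_train(keep)
}
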
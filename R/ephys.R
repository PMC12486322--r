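#' Classifier configuration for afferent recordings
#'
#' @param abeta_cutoff conduction velocity (m/s) strictly above which a
#'   fibre is an A-beta fibre (default 10, strict).
#' @param adelta_band inclusive CV band for A-delta fibres (default
#'   1.5 to 10 m/s).
#' @param sam_min_hold_spikes minimum number of spikes during the static
#'   (hold) phase of a suprathreshold ramp-and-hold stimulus for a fibre
#'   to count as slowly adapting (default 1).
#' @param dhair_max_threshold_mN maximal mechanical threshold for a
#'   D-hair receptor (default 1 mN).
#' @param tap_ceiling_mm_s probe-velocity ceiling of the
#'   electromechanical stimulator; taps are faster than this (default
#'   1.5 mm/s).
#' @param detect_sd_mult spike-detector threshold in baseline SD
#'   multiples (default 5).
#' @param detect_refractory_ms spike-detector refractory period
#'   (default 1 ms).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(abeta_cutoff = 10, adelta_band = c(1.5, 10),
                              sam_min_hold_spikes = 1L,
                              dhair_max_threshold_mN = 1,
                              tap_ceiling_mm_s = 1.5,
                              detect_sd_mult = 5,
                              detect_refractory_ms = 1) {
  if (abeta_cutoff <= 0) stop("`abeta_cutoff` must be > 0")
  if (length(adelta_band) != 2L || adelta_band[1] >= adelta_band[2])
    stop("`adelta_band` must be an increasing pair")
  structure(list(abeta_cutoff = abeta_cutoff, adelta_band = adelta_band,
                 sam_min_hold_spikes = as.integer(sam_min_hold_spikes),
                 dhair_max_threshold_mN = dhair_max_threshold_mN,
                 tap_ceiling_mm_s = tap_ceiling_mm_s,
                 detect_sd_mult = detect_sd_mult,
                 detect_refractory_ms = detect_refractory_ms),
            class = "classifier_config")
}

#' Conduction velocity from distance and latency
#'
#' Distance between the receptive field and the stimulating electrode
#' divided by the response delay; mm/ms is numerically identical to m/s.
#'
#' @param distance_mm distance in mm, > 0.
#' @param delay_ms latency in ms, > 0.
#' @return Conduction velocity in m/s.
#' @export
conduction_velocity <- function(distance_mm, delay_ms) {
  if (any(distance_mm <= 0) || any(delay_ms <= 0))
    stop("distance and delay must be > 0")
  distance_mm / delay_ms
}

#' Classify a fibre by conduction velocity
#'
#' Fibres conducting strictly faster than 10 m/s are A-beta fibres;
#' fibres between 1.5 and 10 m/s (inclusive) are A-delta fibres; slower
#' fibres are left unclassified (C fibres are outside the scope of this
#' analysis). The boundary value of exactly 10 m/s falls in the A-delta
#' band.
#'
#' @param cv conduction velocity in m/s (vectorized).
#' @param config a [classifier_config].
#' @return Character vector: "Abeta", "Adelta" or "unclassified".
#' @export
classify_by_cv <- function(cv, config = classifier_config()) {
  if (any(cv <= 0)) stop("`cv` must be > 0")
  out <- rep("unclassified", length(cv))
  out[cv > config$abeta_cutoff] <- "Abeta"
  out[cv >= config$adelta_band[1] & cv <= config$adelta_band[2]] <- "Adelta"
  out
}

#' Detect spikes in a voltage trace
#'
#' Threshold-crossing detector for synthetic traces: spikes are upward
#' crossings of baseline mean + `detect_sd_mult` baseline SDs, with the
#' detector refractory period suppressing re-crossings. Intended for
#' testing on toy traces; real spike sorting is out of scope.
#'
#' @param time,voltage uniformly sampled trace.
#' @param config a [classifier_config].
#' @return A [spike_train].
#' @export
detect_spikes <- function(time, voltage, config = classifier_config()) {
  if (length(time) != length(voltage) || length(time) < 2L)
    stop("`time` and `voltage` must be equal-length, length >= 2")
  dt <- diff(time)
  if (any(dt <= 0)) stop("sampling interval must be > 0")
  thr <- mean(voltage) + config$detect_sd_mult * stats::sd(voltage)
  above <- voltage > thr
  crossings <- which(above & !c(FALSE, above[-length(above)]))
  keep <- numeric(0)
  last <- -Inf
  refr <- config$detect_refractory_ms / 1000
  for (i in crossings) {
    if (time[i] - last >= refr) {
      keep <- c(keep, time[i])
      last <- time[i]
    }
  }
  spike_train(keep)
}

#' Spike counts and rates per protocol epoch
#'
#' Counts the spikes falling in each epoch (membership is half-open,
#' `start <= t < end`, so boundary spikes are never double-counted) and
#' converts to rates by the epoch duration.
#'
#' @param spikes a [spike_train].
#' @param protocol a [stimulus_protocol].
#' @return The protocol's epoch data.frame with `count` and `rate_hz`
#'   columns appended.
#' @export
phase_spike_rates <- function(spikes, protocol) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(protocol, "stimulus_protocol"))
  ep <- protocol$epochs
  ep$count <- vapply(seq_len(nrow(ep)), function(i)
    sum(spikes$times >= ep$start[i] & spikes$times < ep$end[i]), integer(1))
  ep$rate_hz <- ep$count / (ep$end - ep$start)
  ep
}

#' Mechanical threshold of a fibre
#'
#' The minimal force needed to evoke an action potential, read as the
#' instantaneous stimulus force at the time of the first spike during
#' the dynamic phase of a force-bearing epoch (a vibration-ramp with a
#' linearly rising envelope, or a force ramp). Returns `NA` when the
#' fibre never fired inside such an epoch.
#'
#' @param spikes a [spike_train].
#' @param protocol a [stimulus_protocol] containing at least one
#'   vibration-ramp or ramp epoch.
#' @return Threshold in mN, or `NA_real_` (with a warning if spikes
#'   exist but none in a force-bearing epoch).
#' @export
mechanical_threshold <- function(spikes, protocol) {
  stopifnot(inherits(spikes, "spike_train"),
            inherits(protocol, "stimulus_protocol"))
  ep <- protocol$epochs
  fb <- ep[ep$kind %in% c("vibration-ramp", "ramp") &
             is.finite(ep$force_mN), , drop = FALSE]
  if (nrow(fb) == 0L)
    stop("protocol has no force-bearing dynamic epoch")
  for (i in seq_len(nrow(fb))) {
    e <- fb[i, ]
    inside <- spikes$times[spikes$times >= e$start & spikes$times < e$end]
    if (length(inside) > 0) {
      # force envelope rises linearly from 0 to force_mN over the epoch
      return(e$force_mN * (inside[1] - e$start) / (e$end - e$start))
    }
  }
  if (length(spikes$times) > 0)
    warning("fibre fired, but never inside a force-bearing dynamic epoch; ",
            "threshold undefined")
  NA_real_
}

#' Assign an afferent class from stimulus-response features
#'
#' Decision order: (1) a fibre with no spikes to any controlled stimulus
#' nor to the manual tap is mechano-insensitive; (2) a fibre responding
#' only to the manual tap (at most one spike) and not to any controlled
#' stimulus at the stimulator's velocity ceiling is a tap-unit; (3) an
#' A-beta fibre with at least `sam_min_hold_spikes` spikes during a
#' suprathreshold static (hold) phase is a SAM, otherwise a RAM; (4) an
#' A-delta fibre with mechanical threshold at or below
#' `dhair_max_threshold_mN` and a dynamic response at the slowest ramp
#' velocity is a D-hair receptor, otherwise an AM.
#'
#' @param rates epoch table with `kind`, `velocity_mm_s` and `count`
#'   columns, as returned by [phase_spike_rates].
#' @param cv_class "Abeta" or "Adelta" (see [classify_by_cv]).
#' @param threshold_mN mechanical threshold (mN) or `NA`
#'   (see [mechanical_threshold]).
#' @param config a [classifier_config].
#' @return One of "RAM", "SAM", "D-hair", "AM", "tap-unit",
#'   "mechano-insensitive" (or `NA` for an unclassified CV with a
#'   mechanosensitive response).
#' @export
classify_afferent <- function(rates, cv_class, threshold_mN = NA_real_,
                              config = classifier_config()) {
  if (missing(cv_class) || is.null(cv_class) || is.na(cv_class))
    stop("`cv_class` is required")
  if (!all(c("kind", "count") %in% names(rates)))
    stop("`rates` needs `kind` and `count` columns (see phase_spike_rates)")
  controlled <- rates$kind %in% c("ramp", "hold", "vibration-ramp")
  tap <- rates$kind == "manual-tap"
  n_controlled <- sum(rates$count[controlled])
  n_tap <- sum(rates$count[tap])
  if (n_controlled == 0L && n_tap == 0L) return("mechano-insensitive")
  if (n_controlled == 0L && n_tap >= 1L) return("tap-unit")
  if (cv_class == "Abeta") {
    n_hold <- sum(rates$count[rates$kind == "hold"])
    if (n_hold >= config$sam_min_hold_spikes) return("SAM") else return("RAM")
  }
  if (cv_class == "Adelta") {
    ramps <- rates[rates$kind == "ramp" & is.finite(rates$velocity_mm_s), ,
                   drop = FALSE]
    slow_resp <- nrow(ramps) > 0 &&
      sum(ramps$count[ramps$velocity_mm_s == min(ramps$velocity_mm_s)]) > 0
    if (!is.na(threshold_mN) &&
        threshold_mN <= config$dhair_max_threshold_mN && slow_resp)
      return("D-hair")
    return("AM")
  }
  NA_character_
}

#' End-to-end classification of one recorded fibre
#'
#' Convenience wrapper: computes CV class, per-epoch rates, mechanical
#' threshold and the afferent class for one fibre.
#'
#' @param spikes a [spike_train].
#' @param protocol a [stimulus_protocol].
#' @param cv conduction velocity in m/s.
#' @param config a [classifier_config].
#' @return A one-row data.frame (a fibre record): cv, cv_class,
#'   afferent_class, threshold_mN, spike counts.
#' @export
classify_fiber <- function(spikes, protocol, cv,
                           config = classifier_config()) {
  rates <- phase_spike_rates(spikes, protocol)
  thr <- suppressWarnings(mechanical_threshold(spikes, protocol))
  cvc <- classify_by_cv(cv, config)
  cls <- classify_afferent(rates, cvc, thr, config)
  data.frame(cv = cv, cv_class = cvc, afferent_class = cls,
             threshold_mN = thr,
             n_spikes = length(spikes$times),
             n_controlled = sum(rates$count[rates$kind %in%
                                  c("ramp", "hold", "vibration-ramp")]),
             n_tap = sum(rates$count[rates$kind == "manual-tap"]))
}

#' Proportion of mechano-insensitive fibres per group
#'
#' Builds the 2x2 group-by-sensitivity contingency table from per-fibre
#' records (as produced during an electrical search protocol) and
#' computes the mechano-insensitive percentage per group. The table can
#' be passed straight to [fisher_exact].
#'
#' @param records data.frame with a `group` column and either an
#'   `insensitive` logical column or an `afferent_class` column in which
#'   mechano-insensitive fibres are labelled "mechano-insensitive".
#' @return A list with `table` (a [contingency_table]) and `percent`
#'   (named vector of insensitive percentages per group).
#' @export
insensitive_proportion <- function(records) {
  if (!"group" %in% names(records)) stop("`records` needs a `group` column")
  ins <- if ("insensitive" %in% names(records)) records$insensitive
  else if ("afferent_class" %in% names(records))
    records$afferent_class == "mechano-insensitive"
  else stop("`records` needs an `insensitive` or `afferent_class` column")
  groups <- unique(records$group)
  if (length(groups) != 2L) stop("exactly two groups are required")
  counts <- t(vapply(groups, function(g) {
    sel <- records$group == g
    if (!any(sel)) stop("empty group: ", g)
    c(insensitive = sum(ins[sel]), sensitive = sum(!ins[sel]))
  }, numeric(2)))
  tab <- contingency_table(counts)
  pct <- 100 * counts[, 1] / rowSums(counts)
  names(pct) <- groups
  list(table = tab, percent = pct)
}
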
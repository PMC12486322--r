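# Conduction velocity, spike detection, phase statistics, classification

test_that("conduction velocity is distance over delay in m/s", {
  expect_equal(conduction_velocity(10, 1), 10)
  expect_equal(round(conduction_velocity(12, 0.77), 2), 15.58)
  expect_equal(conduction_velocity(8, 1.6), 5)
  expect_error(conduction_velocity(0, 1), "> 0")
  expect_error(conduction_velocity(10, -1), "> 0")
})

test_that("CV classes partition the axis with a strict A-beta cutoff", {
  expect_equal(classify_by_cv(15.58), "Abeta")
  expect_equal(classify_by_cv(5.14), "Adelta")
  expect_equal(classify_by_cv(10.0), "Adelta")   # boundary goes to A-delta
  expect_equal(classify_by_cv(1.5), "Adelta")
  expect_equal(classify_by_cv(1.4), "unclassified")
  # every CV above 1.5 lands in exactly one of the two classes
  cvs <- seq(1.5, 30, by = 0.01)
  cls <- classify_by_cv(cvs)
  expect_true(all(cls %in% c("Abeta", "Adelta")))
  expect_equal(cls == "Abeta", cvs > 10)
})

test_that("the threshold-crossing detector finds injected spikes", {
  dt <- 5e-5                                  # 20 kHz
  t <- seq(0, 0.2, by = dt)
  set.seed(8)
  v <- rnorm(length(t), 0, 0.05)
  flat <- detect_spikes(t, rep(0, length(t)))
  expect_length(flat$times, 0)
  inject <- function(v, at) {
    i <- round(at / dt) + 1
    v[i:(i + 2)] <- 5
    v
  }
  v3 <- inject(inject(inject(v, 0.05), 0.1), 0.15)
  det <- detect_spikes(t, v3)
  expect_length(det$times, 3)
  expect_equal(det$times, c(0.05, 0.1, 0.15), tolerance = 1e-6)
  # two spikes 0.5 ms apart collapse to one under the 1 ms refractory
  v2 <- inject(inject(v, 0.1), 0.1005)
  expect_length(detect_spikes(t, v2)$times, 1)
  expect_error(detect_spikes(c(0, 0, 1), c(1, 2, 3)), "interval")
})

test_that("phase spike counts use half-open epochs and conserve totals", {
  proto <- stimulus_protocol(data.frame(
    epoch = 1:3, kind = c("ramp", "hold", "none"),
    start = c(0, 1, 3.5), end = c(1, 3, 4),
    velocity_mm_s = c(1.5, NA, NA), force_mN = c(40, 40, NA),
    freq_Hz = NA))
  # 10 spikes inside the 2 s hold -> 5 Hz; boundary spike at t = 1
  # belongs to the hold, not the ramp
  spk <- spike_train(c(0.5, seq(1, 2.8, by = 0.2)))
  rates <- phase_spike_rates(spk, proto)
  expect_equal(rates$count, c(1L, 10L, 0L))
  expect_equal(rates$rate_hz[2], 5)
  # conservation against a brute-force count, outside-epoch spikes included
  set.seed(9)
  spk2 <- spike_train(sort(runif(40, 0, 4.5)))
  r2 <- phase_spike_rates(spk2, proto)
  brute <- sapply(seq_len(nrow(proto$epochs)), function(i)
    sum(spk2$times >= proto$epochs$start[i] &
          spk2$times < proto$epochs$end[i]))
  expect_equal(r2$count, as.integer(brute))
  outside <- sum(!sapply(spk2$times, function(t)
    any(t >= proto$epochs$start & t < proto$epochs$end)))
  expect_equal(sum(r2$count) + outside, length(spk2$times))
})

test_that("mechanical threshold reads the envelope force at the first spike", {
  proto <- stimulus_protocol(data.frame(
    epoch = 1, kind = "vibration-ramp", start = 0, end = 5,
    velocity_mm_s = NA, force_mN = 50, freq_Hz = 50))
  expect_true(is.na(mechanical_threshold(spike_train(numeric(0)), proto)))
  # linear envelope 0 -> 50 mN over 5 s; first spike at 0.75 s -> 7.5 mN
  expect_equal(mechanical_threshold(spike_train(c(0.75, 1.2)), proto), 7.5)
  expect_warning(
    out <- mechanical_threshold(spike_train(6.5), proto), "undefined")
  expect_true(is.na(out))
})

test_that("synthetic SAM thresholds are recovered within 1 mN (seed-averaged)", {
  proto <- standard_protocol()
  rec <- vapply(1:60, function(s) {
    fm <- fiber_model("SAM", threshold_mN = 7.5, seed = 1000 + s)
    mechanical_threshold(generate_fiber_response(fm, proto), proto)
  }, numeric(1))
  expect_equal(mean(rec), 7.5, tolerance = 1 / 7.5)
})

test_that("recovered thresholds rise monotonically with the model threshold", {
  proto <- standard_protocol()
  mean_thr <- function(thr) {
    mean(vapply(1:40, function(s) {
      fm <- fiber_model("SAM", threshold_mN = thr, seed = 5000 + s)
      mechanical_threshold(generate_fiber_response(fm, proto), proto)
    }, numeric(1)), na.rm = TRUE)
  }
  rec <- vapply(c(2, 5, 10, 20), mean_thr, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("the decision rules assign the canonical classes", {
  mk_rates <- function(ramp, hold, tap, vib = 0) data.frame(
    kind = c("vibration-ramp", "ramp", "hold", "manual-tap"),
    velocity_mm_s = c(NA, 0.075, NA, NA),
    count = c(vib, ramp, hold, tap))
  cfg <- classifier_config()
  # A-beta firing only during ramps -> RAM
  expect_equal(classify_afferent(mk_rates(8, 0, 1), "Abeta", 7.5, cfg), "RAM")
  # A-beta sustaining spikes through the hold -> SAM
  expect_equal(classify_afferent(mk_rates(8, 30, 1), "Abeta", 7.5, cfg), "SAM")
  # no controlled response, one tap spike -> tap-unit
  expect_equal(classify_afferent(mk_rates(0, 0, 1), "Abeta", NA, cfg),
               "tap-unit")
  # nothing at all -> mechano-insensitive
  expect_equal(classify_afferent(mk_rates(0, 0, 0), "Adelta", NA, cfg),
               "mechano-insensitive")
  # A-delta, sub-mN threshold, slow-ramp response -> D-hair; else AM
  expect_equal(classify_afferent(mk_rates(12, 0, 1, vib = 5), "Adelta",
                                 0.5, cfg), "D-hair")
  expect_equal(classify_afferent(mk_rates(12, 0, 1, vib = 5), "Adelta",
                                 25, cfg), "AM")
  expect_error(classify_afferent(mk_rates(1, 0, 0), NA), "required")
})

test_that("generated fibres are recovered by the end-to-end classifier", {
  proto <- standard_protocol()
  for (cl in c("RAM", "SAM", "D-hair", "AM", "tap-unit",
               "mechano-insensitive")) {
    hits <- 0
    for (s in 1:25) {
      fm <- class_typical_fiber(cl, seed = 300 * match(cl, c(
        "RAM", "SAM", "D-hair", "AM", "tap-unit",
        "mechano-insensitive")) + s)
      rec <- classify_fiber(generate_fiber_response(fm, proto), proto, fm$cv)
      hits <- hits + identical(rec$afferent_class, cl)
    }
    expect_gte(hits / 25, 0.84)
  }
})

test_that("insensitive proportions and the 2x2 table follow the counts", {
  rec <- data.frame(
    group = rep(c("control", "mutant"), c(38, 53)),
    insensitive = c(rep(c(TRUE, FALSE), c(10, 28)),
                    rep(c(TRUE, FALSE), c(33, 20))))
  out <- insensitive_proportion(rec)
  expect_equal(unclass(out$table), matrix(c(10L, 33L, 28L, 20L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(round(unname(out$percent), 1), c(26.3, 62.3))
  expect_error(insensitive_proportion(data.frame(group = "a",
                                                 insensitive = TRUE)),
               "two groups")
})
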
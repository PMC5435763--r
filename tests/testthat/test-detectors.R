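# The six simplex detectors and the double-reading hybrids, exercised on
# fixtures with planted ground truth.

fx <- planted_burst()          # 13 Hz, 1 s, 40 uV burst at 30 s in noise

x_fuzzy <- c(5, 10, 40, 30, 2, 10, 4, 3, 0.5, 0.1, 0.4, 2)

test_that("each simplex detector recovers the planted burst", {
  cases <- list(
    d1 = detector_spec("d1", c(0.25, 4, 0.4, 2)),
    d2 = detector_spec("d2", c(0.1, 0.25, 3, 0.4, 2)),
    d3 = detector_spec("d3", c(95, 0.4, 2)),
    d5 = detector_spec("d5", x_fuzzy),
    d6 = detector_spec("d6", x_fuzzy))
  for (id in names(cases)) {
    ev <- detect_spindles(fx$rec, cases[[id]])
    expect_gt(max_overlap_with(ev, fx$burst_interval), 0.5, label = id)
  }
  # d4 with mid-range defaults finds the burst and honors its lower gate
  spec4 <- detector_spec("d4")
  ev4 <- detect_spindles(fx$rec, spec4)
  expect_gte(nrow(ev4), 1)
  expect_gt(max_overlap_with(ev4, fx$burst_interval), 0.5)
  expect_true(all(ev4$duration >= spec4$x[14] - 1e-9))
})

test_that("duration gates and extreme thresholds silence detectors", {
  # d1: lower duration above the burst length
  ev <- detect_spindles(fx$rec, detector_spec("d1", c(0.25, 4, 1.4, 2),
                                              upper = c(20, 30, 2, 3)))
  expect_equal(nrow(ev), 0)
  # d1 on pure noise with the upper threshold ratio at its maximum
  set.seed(12)
  noise <- recording(rnorm(6000, sd = 5), 100)
  expect_equal(nrow(detect_spindles(noise, detector_spec("d1", c(0.5, 30, 0.3, 3)))), 0)
  # d6: burst shorter than the lower duration gate
  short <- planted_burst(dur = 0.3, seed = 8)
  x <- x_fuzzy; x[11] <- 0.5
  expect_equal(nrow(detect_spindles(short$rec, detector_spec("d6", x))), 0)
  # d4: estimate threshold at its maximum bound on noise only
  x4 <- detector_spec("d4")$x; x4[4] <- 0.8
  expect_equal(nrow(detect_spindles(noise, detector_spec("d4", x4))), 0)
})

test_that("raising the primary threshold never increases event counts", {
  scans <- list(
    d1 = list(idx = 2, vals = c(1, 2, 4, 8, 16), base = c(0.25, 4, 0.4, 2)),
    d2 = list(idx = 3, vals = c(1, 2, 3, 5, 8), base = c(0.1, 0.25, 3, 0.4, 2)),
    d3 = list(idx = 1, vals = c(80, 90, 95, 98, 99), base = c(95, 0.4, 2)),
    d5 = list(idx = 9, vals = c(0.1, 0.3, 0.5, 0.7, 0.9), base = x_fuzzy),
    d6 = list(idx = 9, vals = c(0.1, 0.3, 0.5, 0.7, 0.9), base = x_fuzzy))
  for (id in names(scans)) {
    s <- scans[[id]]
    sf <- spindle_features(fx$rec, detector_spec(id))
    counts <- vapply(s$vals, function(v) {
      x <- s$base; x[s$idx] <- v
      nrow(detect_with_features(sf, x))
    }, 0L)
    expect_true(all(diff(counts) <= 0), label = id)
  }
})

test_that("d3 percentile thresholding stays quiet on white noise", {
  # With a 0.25 s RMS window on a 0.1 s grid, adjacent cells share 60% of
  # their samples, so >= 0.5 s supra-95th-percentile runs are rarer than
  # independent cells would suggest but not negligible (~0.2 per minute of
  # noise); the 99th percentile silences them entirely.
  with_events_95 <- 0L; total_95 <- 0L; with_events_99 <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    noise <- recording(rnorm(6000, sd = 5), 100)
    e95 <- detect_spindles(noise, detector_spec("d3", c(95, 0.5, 3)))
    e99 <- detect_spindles(noise, detector_spec("d3", c(99, 0.5, 3)))
    if (nrow(e95) > 0) with_events_95 <- with_events_95 + 1L
    total_95 <- total_95 + nrow(e95)
    if (nrow(e99) > 0) with_events_99 <- with_events_99 + 1L
  }
  expect_lte(with_events_95, 4L)
  expect_lte(total_95, 6L)
  expect_identical(with_events_99, 0L)
})

test_that("normalization demands NREM sleep", {
  rem <- stage_series(rep("REM", 2), 30)
  rec <- recording(rnorm(6000, sd = 5), 100)
  expect_error(detect_spindles(rec, detector_spec("d2", c(0.1, 0.25, 3, 0.4, 2)), rem),
               "normalization error")
})

test_that("fuzzy estimates stay within [0, 1]", {
  for (id in c("d5", "d6")) {
    sf <- spindle_features(fx$rec, detector_spec(id))
    f <- sf$feat
    if (id == "d5") {
      for (im in f$imfs) {
        e <- trapezoid_membership(im$amp, 5, 10, 40, 30) *
          trapezoid_membership(im$freq, 2, 10, 4, 3)
        expect_true(all(e >= 0 & e <= 1))
      }
    } else {
      fm <- Reduce(pmax, lapply(f$freqs, trapezoid_membership, 2, 10, 4, 3))
      e <- trapezoid_membership(f$amp, 5, 10, 40, 30) * fm
      expect_true(all(e >= 0 & e <= 1))
    }
  }
  est <- cwt_probability_estimate(fx$rec, 11, 16)
  expect_true(all(est$values >= 0 & est$values <= 1))
})

test_that("detector output is sorted, disjoint, duration-gated, deterministic", {
  specs <- list(detector_spec("d2", c(0.1, 0.25, 2, 0.4, 2)),
                detector_spec("d5", x_fuzzy),
                detector_spec("d6", x_fuzzy))
  for (spec in specs) {
    ev1 <- detect_spindles(fx$rec, spec)
    ev2 <- detect_spindles(fx$rec, spec)
    expect_identical(ev1, ev2)
    if (nrow(ev1) > 1) {
      expect_true(all(diff(ev1$onset) > 0))
      expect_true(all(ev1$onset[-1] >= (ev1$onset + ev1$duration)[-nrow(ev1)]))
    }
    gate <- spindlefront:::.duration_gate(spec$id, spec$x)
    expect_true(all(ev1$duration >= gate[1] - 1e-9 & ev1$duration <= gate[2] + 1e-9))
  }
})

test_that("hybrids compose screening and review", {
  first <- detector_spec("d2", c(0.1, 0.25, 3, 0.4, 2))
  accept_all <- detector_spec("d2", c(0.1, 0.25, 0.1, 0.3, 3))
  hy <- detect_hybrid(first, accept_all, fx$rec)
  ref <- detect_spindles(fx$rec, first)
  expect_equal(hy$onset, ref$onset, tolerance = 1e-6)
  expect_equal(hy$duration, ref$duration, tolerance = 1e-6)

  # first detector silent: second never runs
  silent <- detector_spec("d2", c(0.1, 0.25, 10, 0.4, 2))
  expect_equal(nrow(detect_hybrid(silent, accept_all, fx$rec)), 0)

  # screening-then-review cannot increase false positives: fixture with
  # bursts plus K-complex-like confounders
  sim <- simulate_psg(sim_config(duration = 300, kcomplex_rate = 4, seed = 99))
  g <- sim$truth[, c("onset", "duration")]
  class(g) <- c("event_list", "data.frame")
  d2_spec <- detector_spec("d2", c(0.1, 0.25, 1.5, 0.4, 2))
  alone <- match_events(g, detect_spindles(sim$rec, d2_spec, sim$stages))
  hy2 <- detect_hybrid(d2_spec, detector_spec("d6", x_fuzzy), sim$rec, sim$stages)
  reviewed <- match_events(g, hy2)
  expect_lte(reviewed$fp, alone$fp)
})

test_that("hybrid parameter vectors split into their components", {
  b7 <- detector_bounds("d7")
  expect_length(b7$lower, 17)
  expect_identical(b7$lower[1:12], detector_bounds("d6")$lower)
  expect_identical(b7$lower[13:17], detector_bounds("d2")$lower)
  expect_length(detector_bounds("d8")$lower, 17)
  expect_length(detector_bounds("d9")$lower, 27)
  x7 <- c(x_fuzzy, 0.1, 0.25, 3, 0.4, 2)
  ev <- detect_spindles(fx$rec, detector_spec("d7", x7))
  expect_gt(max_overlap_with(ev, fx$burst_interval), 0.2)
})

test_that("hand-tuned detectors clear the high-SNR smoke bar", {
  sim <- simulate_psg(sim_config(duration = 600, snr = 6, seed = 55))
  g <- sim$truth[, c("onset", "duration")]
  class(g) <- c("event_list", "data.frame")
  stats <- norm_stats(sim$rec, sim$stages)
  tuned <- list(
    d1 = c(0.12, 4, 0.4, 2.5),
    d2 = c(0.1, 0.25, 2, 0.4, 2.5),
    d3 = c(93, 0.4, 2.5),
    d4 = c(10.5, 16.5, 0.2, 0.3, 0.05, 0.15, 0.7, 0.15, 0.3, 0.5, 0.2, 0.3,
           0.2, 0.4, 3),
    d5 = c(10, 14.8, 40, 20, 2, 10.5, 5, 3, 0.5, 0.2, 0.4, 2.5),
    d6 = c(10, 14.8, 40, 20, 2, 10.5, 5, 3, 0.5, 0.2, 0.4, 2.5))
  for (id in names(tuned)) {
    ev <- detect_spindles(sim$rec, detector_spec(id, tuned[[id]]),
                          sim$stages, stats)
    prf <- prf_metrics(match_events(g, ev))
    expect_gte(prf[["recall"]], 0.9, label = id)
    expect_gte(prf[["precision"]], 0.8, label = id)
  }
})

test_that("sliced features reproduce full-recording detection locally", {
  spec <- detector_spec("d2", c(0.1, 0.25, 3, 0.4, 2))
  sf <- spindle_features(fx$rec, spec)
  i0 <- 25 * 200 + 1L; i1 <- 35 * 200
  sub <- slice_features(sf, i0, i1)
  ev <- detect_with_features(sub, spec$x)
  expect_equal(nrow(ev), 1)
  expect_gt(max_overlap_with(ev, fx$burst_interval - 25), 0.5)
})
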
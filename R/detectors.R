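# The six simplex spindle detectors (d1-d6) and the sequential
# double-reading hybrids (d7-d9). Each detector is split into a
# recording-dependent feature stage (filtering, scalograms, sifting,
# envelopes -- everything independent of the operating parameters) and a
# cheap parameter-application stage, so that evolutionary optimization can
# re-apply thousands of parameter vectors to one set of features.

.DETECTOR_IDS <- paste0("d", 1:9)

.bounds_table <- list(
  d1 = list(lower = c(0.1, 0.1, 0.3, 0.3),
            upper = c(20, 30, 1, 3),
            names = c("lower_ratio", "upper_ratio", "dur_min_s", "dur_max_s")),
  d2 = list(lower = c(0.05, 0.05, 0.1, 0.3, 0.3),
            upper = c(0.5, 0.5, 10, 1, 3),
            names = c("rms_res_s", "rms_win_s", "sd_ratio", "dur_min_s", "dur_max_s")),
  d3 = list(lower = c(0.1, 0.3, 0.3),
            upper = c(99, 1, 3),
            names = c("percentile", "dur_min_s", "dur_max_s")),
  d4 = list(lower = c(8, 14, 0.05, 0.1, 0.01, 0.05, 0.3, 0.05, 0.1, 0.3,
                      0.05, 0.05, 0.1, 0.3, 0.3),
            upper = c(12, 18, 0.25, 0.8, 0.1, 0.25, 0.9, 0.25, 0.5, 0.8,
                      0.25, 0.5, 0.5, 1, 3),
            names = c("freq_lo_hz", "freq_hi_hz", "smooth_s", "threshold",
                      "init_min_s", "gap_s", "strong_mean", "pairA_dur1_s",
                      "pairA_dur2_s", "pairA_mean", "pairB_dur1_s",
                      "pairB_dur2_s", "final_gap_s", "dur_min_s", "merge_cap_s")),
  d5 = list(lower = c(1, 5, 10, 1, 0.1, 8, 1, 0.1, 0.01, 0.05, 0.3, 0.3),
            upper = c(10, 40, 120, 50, 4, 13.5, 8, 4, 0.99, 0.5, 1, 3),
            names = c("amp_rise_uv", "amp_onset_uv", "amp_plateau_uv",
                      "amp_fall_uv", "freq_rise_hz", "freq_onset_hz",
                      "freq_plateau_hz", "freq_fall_hz", "threshold",
                      "gap_s", "dur_min_s", "dur_max_s"))
)
.bounds_table$d6 <- .bounds_table$d5
.hybrid_parts <- list(d7 = c("d6", "d2"), d8 = c("d2", "d6"), d9 = c("d4", "d6"))

#' Default parameter bounds of a detector
#'
#' Box bounds for the operating-parameter vectors of the six simplex
#' detectors; hybrids concatenate the bounds of their two components in
#' screening order.
#'
#' @param id detector id, `"d1"` .. `"d9"`.
#' @return list with `lower`, `upper`, `names`.
#' @export
detector_bounds <- function(id) {
  id <- match.arg(id, .DETECTOR_IDS)
  if (id %in% names(.bounds_table)) return(.bounds_table[[id]])
  parts <- .hybrid_parts[[id]]
  a <- .bounds_table[[parts[1]]]; b <- .bounds_table[[parts[2]]]
  list(lower = c(a$lower, b$lower), upper = c(a$upper, b$upper),
       names = c(paste0(parts[1], ".", a$names), paste0(parts[2], ".", b$names)))
}

#' Detector specification
#'
#' Bundles a detector id with an operating-parameter vector and its box
#' bounds. With `x = NULL` the midpoint of the bounds is used.
#'
#' @param id detector id, `"d1"` .. `"d9"`.
#' @param x numeric parameter vector (length 4, 5, 3, 15, 12, 12, 17, 17,
#'   27 for d1..d9), or `NULL` for the bounds midpoint.
#' @param lower,upper optional replacement bounds.
#' @return object of class `detector_spec`.
#' @export
detector_spec <- function(id, x = NULL, lower = NULL, upper = NULL) {
  id <- match.arg(id, .DETECTOR_IDS)
  b <- detector_bounds(id)
  if (!is.null(lower)) b$lower <- lower
  if (!is.null(upper)) b$upper <- upper
  if (length(b$lower) != length(b$upper)) stop("bound length mismatch")
  if (is.null(x)) x <- (b$lower + b$upper) / 2
  if (length(x) != length(b$lower))
    stop(sprintf("%s expects %d parameters, got %d", id, length(b$lower), length(x)))
  if (any(x < b$lower - 1e-12) || any(x > b$upper + 1e-12))
    stop("parameter vector violates bounds")
  structure(list(id = id, x = as.numeric(x), lower = b$lower, upper = b$upper,
                 names = b$names), class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  cat(sprintf("<detector_spec> %s (%d parameters)\n", x$id, length(x$x)))
  print(data.frame(name = x$names, value = x$x, lower = x$lower, upper = x$upper),
        row.names = FALSE)
  invisible(x)
}

# duration gate [lo, hi] of a simplex detector's parameter vector
.duration_gate <- function(id, x) {
  switch(id,
         d1 = x[3:4], d2 = x[4:5], d3 = x[2:3],
         d4 = c(x[14], Inf), d5 = x[11:12], d6 = x[11:12],
         stop("no duration gate for ", id))
}

# ---- shared post-processing helpers ------------------------------------

# boolean per-sample vector -> events, duration-gated and stage-filtered
.samples_to_gated_events <- function(above, rate, gate, nrem = NULL) {
  ev <- mask_to_events(sample_mask(above, rate))
  .gate_and_filter(ev, rate, gate, nrem)
}

.gate_and_filter <- function(ev, rate, gate = NULL, nrem = NULL) {
  if (!nrow(ev)) return(ev)
  on <- ev$onset; dur <- ev$duration
  if (!is.null(gate)) {
    keep <- dur >= gate[1] - 1e-9 & dur <= gate[2] + 1e-9
    on <- on[keep]; dur <- dur[keep]
  }
  if (!is.null(nrem) && length(on)) {
    keep <- vapply(seq_along(on), function(i) {
      i0 <- max(1L, floor(on[i] * rate) + 1L)
      i1 <- min(length(nrem), ceiling((on[i] + dur[i]) * rate))
      i1 >= i0 && any(nrem[i0:i1])
    }, TRUE)
    on <- on[keep]; dur <- dur[keep]
  }
  .ev(on, dur)
}

# RMS-grid runs above a threshold -> events (grid cell j covers
# [(j-1)*res, j*res))
.grid_runs_to_events <- function(above, res, gate, rate = NULL, nrem = NULL) {
  if (!any(above)) return(event_list())
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  ev <- .ev((starts[keep] - 1L) * res, r$lengths[keep] * res)
  .gate_and_filter(ev, rate, gate, nrem)
}

# ---- feature builders ---------------------------------------------------

.need_stats <- function(rec, stages, stats) {
  if (is.null(stats)) stats <- norm_stats(rec, stages)
  stats
}

# re-filter when the supplied stats came from a longer parent recording
# (hybrid review windows keep the parent's normalization scalars)
.local_filtered <- function(rec, stats) {
  if (!is.null(stats) && length(stats$filtered$samples) == length(rec$samples))
    stats$filtered
  else bandpass_sigma(rec)
}

.features <- function(id, rec, stages = NULL, stats = NULL) {
  rate <- rec$rate
  nrem <- if (is.null(stages)) NULL else stage_mask(rec, stages, c("N2", "N3", "N4"))
  f <- switch(
    id,
    d1 = {
      stats <- .need_stats(rec, stages, stats)
      filt <- .local_filtered(rec, stats)
      list(env = peak_envelope(abs(filt$samples)), A1 = stats$A1, A2 = stats$A2)
    },
    d2 = {
      stats <- .need_stats(rec, stages, stats)
      list(filtered = .local_filtered(rec, stats), sigma_n2 = stats$sigma_n2)
    },
    d3 = {
      stats <- .need_stats(rec, stages, stats)
      filt <- .local_filtered(rec, stats)
      list(grid = moving_rms(filt, 0.1, 0.25), rms_values = stats$rms_values)
    },
    d4 = {
      freqs <- exp(seq(log(0.5), log(min(30, rate / 2 * 0.99)), length.out = 120))
      P <- .morlet_cwt_power(rec$samples, rate, freqs)
      list(top = cwt_top_frequencies(P, freqs))
    },
    d5 = {
      dec <- emd_sift(rec, 3L)
      list(imfs = lapply(dec$imfs, function(im) list(
        amp = spline_envelope(im),
        freq = suppressWarnings(zero_crossing_frequency(im, rate, 1L)))))
    },
    d6 = {
      comp <- rolling_ball_highpass(rec, 10)
      list(amp = spline_envelope(comp$samples),
           freqs = lapply(c(1L, 3L, 5L, 7L, 9L), function(k)
             suppressWarnings(zero_crossing_frequency(comp$samples, rate, k))))
    },
    stop("unknown simplex detector: ", id))
  c(f, list(rate = rate, n = length(rec$samples), nrem = nrem))
}

# ---- parameter application ---------------------------------------------

.apply_params <- function(id, f, x, gated = TRUE) {
  if (!gated) f$no_gate <- TRUE
  switch(
    id,
    d1 = {
      above <- f$env > x[1] * f$A1
      if (any(above)) {
        r <- rle(above)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (j in which(r$values)) {
          if (!any(f$env[starts[j]:ends[j]] > x[2] * f$A2))
            above[starts[j]:ends[j]] <- FALSE
        }
      }
      .samples_to_gated_events(above, f$rate, .maybe_gate(f, x[3:4]), f$nrem)
    },
    d2 = {
      g <- moving_rms(f$filtered, x[1], x[2])
      .grid_runs_to_events(g$rms > x[3] * f$sigma_n2, x[1], .maybe_gate(f, x[4:5]),
                           f$rate, f$nrem)
    },
    d3 = {
      thr <- stats::quantile(f$rms_values, min(x[1], 100) / 100, names = FALSE)
      .grid_runs_to_events(f$grid$rms > thr, 0.1, .maybe_gate(f, x[2:3]),
                           f$rate, f$nrem)
    },
    d4 = .apply_d4(f, x),
    d5 = {
      est <- rep(0, f$n)
      for (im in f$imfs) {
        e <- trapezoid_membership(im$amp, x[1], x[2], x[3], x[4]) *
          trapezoid_membership(im$freq, x[5], x[6], x[7], x[8])
        est <- pmax(est, e)
      }
      .estimate_to_events(est, f, x)
    },
    d6 = {
      fm <- rep(0, f$n)
      for (fr in f$freqs)
        fm <- pmax(fm, trapezoid_membership(fr, x[5], x[6], x[7], x[8]))
      est <- trapezoid_membership(f$amp, x[1], x[2], x[3], x[4]) * fm
      .estimate_to_events(est, f, x)
    },
    stop("unknown simplex detector: ", id))
}

# the hybrid review stage suppresses the component's internal duration
# gate; the gate is re-applied after clipping to candidate windows
.maybe_gate <- function(f, gate) if (isTRUE(f$no_gate)) c(0, Inf) else gate

# d5/d6 tail: threshold, gap merge, duration gate, stage filter
.estimate_to_events <- function(est, f, x) {
  ev <- mask_to_events(sample_mask(est > x[9], f$rate))
  if (nrow(ev) > 1) ev <- merge_events(ev, gap = x[10])
  .gate_and_filter(ev, f$rate, .maybe_gate(f, x[11:12]), f$nrem)
}

# centered moving average with edge truncation
.moving_avg <- function(v, k) {
  if (k <= 1) return(v)
  n <- length(v)
  cs <- c(0, cumsum(v))
  h <- k %/% 2
  i0 <- pmax(1L, seq_len(n) - h); i1 <- pmin(n, seq_len(n) + h)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

.apply_d4 <- function(f, x) {
  est <- colSums(f$top >= x[1] & f$top <= x[2]) / nrow(f$top)
  est <- .moving_avg(est, max(1L, round(x[3] * f$rate)))
  cs <- c(0, cumsum(est))
  mean_est <- function(i0, i1) (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
  ev <- mask_to_events(sample_mask(est > x[4], f$rate))
  if (!nrow(ev)) return(ev)
  ev <- as_event_list(ev[ev$duration > x[5], , drop = FALSE])     # initial length
  if (nrow(ev) > 1) ev <- merge_events(ev, gap = x[6])
  pair_rule <- function(dL, dR, a, b) (dL >= a && dR >= b) || (dL >= b && dR >= a)
  group_pass <- function(ev, mean_thr, dur1, dur2) {
    if (nrow(ev) <= 1) return(ev)
    on <- ev$onset; off <- ev$onset + ev$duration
    i <- 1L
    while (i < length(on)) {
      i0 <- max(1L, floor(on[i] * f$rate) + 1L)
      i1 <- min(f$n, ceiling(off[i + 1L] * f$rate))
      if (mean_est(i0, i1) >= mean_thr &&
          pair_rule(off[i] - on[i], off[i + 1L] - on[i + 1L], dur1, dur2)) {
        off[i] <- off[i + 1L]
        on <- on[-(i + 1L)]; off <- off[-(i + 1L)]
      } else i <- i + 1L
    }
    event_list(onset = on, duration = off - on)
  }
  ev <- group_pass(ev, x[10], x[8], x[9])       # intermediate candidates
  ev <- group_pass(ev, x[7], x[11], x[12])      # strong candidates
  # final gap merge, capped at the upper mergeable duration
  if (nrow(ev) > 1) {
    on <- ev$onset; off <- ev$onset + ev$duration
    i <- 1L
    while (i < length(on)) {
      if (on[i + 1L] - off[i] < x[13] && off[i + 1L] - on[i] <= x[15]) {
        off[i] <- off[i + 1L]
        on <- on[-(i + 1L)]; off <- off[-(i + 1L)]
      } else i <- i + 1L
    }
    ev <- event_list(onset = on, duration = off - on)
  }
  .gate_and_filter(ev, f$rate, .maybe_gate(f, c(x[14], Inf)), f$nrem)
}

# restrict precomputed per-sample features to a sample range [i0, i1]
# (1-based, inclusive). Signals are preprocessed once on the full
# recording; segment evaluation slices the results, so segment boundaries
# introduce no spline/sifting edge artifacts.
.slice_feat <- function(id, f, i0, i1) {
  rate <- f$rate
  g <- list(rate = rate, n = i1 - i0 + 1L,
            nrem = if (is.null(f$nrem)) NULL else f$nrem[i0:i1])
  switch(
    id,
    d1 = c(g, list(env = f$env[i0:i1], A1 = f$A1, A2 = f$A2)),
    d2 = c(g, list(filtered = recording(f$filtered$samples[i0:i1], rate),
                   sigma_n2 = f$sigma_n2)),
    d3 = {
      # grid cell j covers [(j-1)*0.1, j*0.1); keep cells inside the slice
      t0 <- (i0 - 1L) / rate; t1 <- i1 / rate
      j <- which(f$grid$time - 0.05 >= t0 - 1e-9 & f$grid$time + 0.05 <= t1 + 1e-9)
      c(g, list(grid = f$grid[j, , drop = FALSE], rms_values = f$rms_values))
    },
    d4 = c(g, list(top = f$top[, i0:i1, drop = FALSE])),
    d5 = c(g, list(imfs = lapply(f$imfs, function(im)
      list(amp = im$amp[i0:i1], freq = im$freq[i0:i1])))),
    d6 = c(g, list(amp = f$amp[i0:i1],
                   freqs = lapply(f$freqs, function(v) v[i0:i1]))),
    stop("cannot slice features for ", id))
}

#' Restrict precomputed detector features to a sample window
#'
#' Used by subsampled training: the detector's signal preprocessing is done
#' once on the complete recording and segment evaluation works on slices,
#' matching how detection on the whole night behaves.
#'
#' @param sf a [spindle_features()] object.
#' @param i0,i1 1-based inclusive sample range.
#' @return a [spindle_features()] object over the window.
#' @export
slice_features <- function(sf, i0, i1) {
  if (!is.null(sf$parts)) {
    first <- .slice_feat(sf$parts[1], sf$first, i0, i1)
    rec <- recording(sf$rec$samples[i0:i1], sf$rec$rate, sf$rec$channel)
    structure(list(id = sf$id, parts = sf$parts, first = first, rec = rec,
                   stages = NULL, stats = sf$stats), class = "spindle_features")
  } else {
    structure(list(id = sf$id, feat = .slice_feat(sf$id, sf$feat, i0, i1)),
              class = "spindle_features")
  }
}

# ---- public surface -----------------------------------------------------

#' Precompute the parameter-independent features of a detector
#'
#' Everything a detector derives from the recording alone (sigma-filtered
#' traces, scalograms, IMFs, envelopes, instantaneous frequencies,
#' normalization statistics) is computed once here; [detect_with_features()]
#' then applies an operating-parameter vector cheaply. This split is what
#' makes evolutionary optimization over thousands of parameter vectors
#' affordable.
#'
#' @param rec a [recording()].
#' @param spec a [detector_spec()] (only the id and bounds are used).
#' @param stages optional [stage_series()].
#' @param stats optional precomputed [norm_stats()] (e.g. full-recording
#'   statistics reused for a segment).
#' @return object of class `spindle_features`.
#' @export
spindle_features <- function(rec, spec, stages = NULL, stats = NULL) {
  id <- spec$id
  if (id %in% names(.hybrid_parts)) {
    parts <- .hybrid_parts[[id]]
    if (parts[1] %in% c("d1", "d2", "d3") || parts[2] %in% c("d1", "d2", "d3"))
      stats <- .need_stats(rec, stages, stats)
    first_feat <- .features(parts[1], rec, stages, stats)
    structure(list(id = id, parts = parts, first = first_feat, rec = rec,
                   stages = stages, stats = stats), class = "spindle_features")
  } else {
    structure(list(id = id, feat = .features(id, rec, stages, stats)),
              class = "spindle_features")
  }
}

#' Apply an operating-parameter vector to precomputed features
#'
#' @param sf a [spindle_features()] object.
#' @param x parameter vector for the detector the features were built for.
#' @return an [event_list()] of detections (sorted, pairwise disjoint).
#' @export
detect_with_features <- function(sf, x) {
  id <- sf$id
  if (!id %in% names(.hybrid_parts)) return(.apply_params(id, sf$feat, x))
  parts <- sf$parts
  n1 <- length(.bounds_table[[parts[1]]]$lower)
  x1 <- x[seq_len(n1)]; x2 <- x[-seq_len(n1)]
  cand <- .apply_params(parts[1], sf$first, x1)
  .hybrid_review(cand, parts[2], x2, sf$rec, sf$stages, sf$stats)
}

#' Detect sleep spindles with one of the nine detectors
#'
#' Runs the detector named by `spec$id` with parameter vector `spec$x`.
#' Detectors d1--d3 normalize their amplitude thresholds by NREM 2/3/4 (or
#' N2) statistics of the recording; when `stages` is `NULL` the whole
#' recording is treated as NREM 2 (the convention for stage-less
#' excerpts). When a hypnogram is provided, events entirely outside
#' NREM 2/3/4 epochs are discarded. Hybrids d7--d9 run their first
#' component on the full recording, pad each candidate by 2.5 s, and let
#' the second component review only the padded candidate segments.
#'
#' @param rec a [recording()].
#' @param spec a [detector_spec()].
#' @param stages optional [stage_series()].
#' @param stats optional precomputed [norm_stats()].
#' @return an [event_list()] of detections.
#' @export
detect_spindles <- function(rec, spec, stages = NULL, stats = NULL) {
  detect_with_features(spindle_features(rec, spec, stages, stats), spec$x)
}

#' Sequential double-reading hybrid of two detectors
#'
#' The first detector screens the full recording; each candidate is padded
#' by `pad` seconds on both ends (overlaps merged) and the second detector
#' reviews each padded segment independently, with normalization
#' statistics still taken from the full recording. The second detector's
#' detections are clipped back to the unpadded candidate windows and
#' re-checked against its duration gate.
#'
#' @param first,second [detector_spec()] objects (parameter vectors set).
#' @param rec a [recording()].
#' @param stages optional [stage_series()].
#' @param pad candidate dilation in seconds.
#' @param stats optional precomputed [norm_stats()].
#' @return an [event_list()].
#' @export
detect_hybrid <- function(first, second, rec, stages = NULL, pad = 2.5,
                          stats = NULL) {
  if (first$id %in% c("d1", "d2", "d3") || second$id %in% c("d1", "d2", "d3"))
    stats <- .need_stats(rec, stages, stats)
  cand <- detect_spindles(rec, first, stages, stats)
  .hybrid_review(cand, second$id, second$x, rec, stages, stats, pad)
}

.hybrid_review <- function(cand, second_id, x2, rec, stages, stats, pad = 2.5) {
  if (!nrow(cand)) return(event_list())
  n <- length(rec$samples); rate <- rec$rate
  total <- n / rate
  padded <- event_list(onset = pmax(0, cand$onset - pad),
                       duration = pmin(total, cand$onset + cand$duration + pad) -
                         pmax(0, cand$onset - pad))
  padded <- merge_events(padded)
  det_mask <- logical(n)
  for (i in seq_len(nrow(padded))) {
    i0 <- max(1L, floor(padded$onset[i] * rate) + 1L)
    i1 <- min(n, ceiling((padded$onset[i] + padded$duration[i]) * rate))
    seg <- recording(rec$samples[i0:i1], rate, rec$channel)
    ev <- .apply_params(second_id, .features(second_id, seg, NULL, stats), x2,
                        gated = FALSE)
    if (nrow(ev)) {
      m <- events_to_mask(ev, rate, length(seg$samples))$mask
      det_mask[i0:i1] <- det_mask[i0:i1] | m
    }
  }
  cand_mask <- events_to_mask(cand, rate, n)$mask
  out <- mask_to_events(sample_mask(det_mask & cand_mask, rate))
  nrem <- if (is.null(stages)) NULL else stage_mask(rec, stages, c("N2", "N3", "N4"))
  .gate_and_filter(out, rate, .duration_gate(second_id, x2), nrem)
}
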
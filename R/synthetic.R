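# Synthetic polysomnography generator: NREM-like 1/f background, planted
# sigma bursts with waxing-waning envelopes, K-complex-like confounders,
# an alternating N2/N3 hypnogram, and simulated scorers of differing
# sensitivity. Every output is a deterministic function of (config, seed).

#' Simulation settings for synthetic polysomnography
#'
#' Defaults emulate a stage-2-dominated recording: 1/f^1.5 background at
#' 15 uV broadband RMS (flat below the 0.5 Hz acquisition high-pass),
#' spindles at 3 per minute with frequencies uniform
#' in 11-16 Hz, durations uniform in 0.5-2 s, Hann (waxing-waning)
#' envelopes, and K-complex-like biphasic transients at 1 per minute.
#' Spindle peak amplitudes are drawn uniformly from `amp_range`; when
#' `amp_range` is `NULL` it is derived at simulation time so that the
#' sigma-band RMS of a mid-amplitude spindle is `snr` times the
#' background's sigma-band RMS (+-15% spread).
#'
#' @param duration recording length (s).
#' @param rate sampling rate (Hz).
#' @param density spindles per minute.
#' @param freq_range spindle frequency range (Hz).
#' @param dur_range spindle duration range (s); lower bound >= 0.5.
#' @param amp_range spindle peak amplitude range (uV) or `NULL` to derive
#'   from `snr`.
#' @param snr target sigma-band RMS ratio of a mid-amplitude spindle over
#'   background (used only when `amp_range` is `NULL`).
#' @param noise_exponent spectral slope of the 1/f^a background.
#' @param background_rms broadband background RMS (uV).
#' @param kcomplex_rate K-complex-like transients per minute.
#' @param scorers list of scorer models, each
#'   `list(threshold = uV or NULL, style = "true_duration"|"fixed_1s")`;
#'   `NULL` thresholds resolve at simulation time to the 35% (scorer 1)
#'   and 10% (later scorers) points of the realized amplitude range.
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration = 600, rate = 100, density = 3,
                       freq_range = c(11, 16), dur_range = c(0.5, 2),
                       amp_range = NULL, snr = 4, noise_exponent = 1.5,
                       background_rms = 15, kcomplex_rate = 1,
                       scorers = list(
                         list(threshold = NULL, style = "true_duration"),
                         list(threshold = NULL, style = "fixed_1s")),
                       seed = 1L) {
  if (dur_range[1] < 0.5) stop("spindles are at least 0.5 s: dur_range[1] >= 0.5")
  if (freq_range[1] <= 0 || freq_range[2] >= rate / 2)
    stop("freq_range must lie within (0, rate/2)")
  structure(as.list(environment()), class = "sim_config")
}

# 1/f^a noise via spectral shaping of white Gaussian noise, scaled to rms.
# The spectrum is flat below 0.5 Hz, mimicking the acquisition high-pass of
# clinical EEG; without the shelf a steep slope would concentrate nearly
# all power in sub-0.1 Hz drift.
.pink_noise <- function(n, rate, exponent, rms) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- c(1e-12, seq_len(n - 1))
  k <- pmin(k, n - k)                      # fold to two-sided frequencies
  f_hz <- k * rate / n
  shape <- pmax(f_hz, 0.5)^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE) / n)
  x * rms / stats::sd(x)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

#' Simulate a polysomnography recording with planted spindles
#'
#' Spindle onsets come from a Poisson process at the configured density,
#' thinned to forbid overlap (0.5 s guard); each spindle is a Hann-windowed
#' sinusoid with frequency, duration, and peak amplitude drawn uniformly
#' from the configured ranges. K-complex-like confounders are single-cycle
#' low-frequency biphasic transients. The stage series alternates N2/N3 in
#' 30 s epochs. Fully deterministic given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return object of class `psg_sim`: `rec` ([recording()]), `stages`
#'   ([stage_series()]), `truth` ([event_list()] with per-event `amplitude`
#'   and `frequency` metadata), resolved `scorer_models`, the resolved
#'   config, and the measured background sigma-band RMS.
#' @export
simulate_psg <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$rate)
  bg <- .pink_noise(n, cfg$rate, cfg$noise_exponent, cfg$background_rms)
  sigma_bg <- stats::sd(bandpass_sigma(recording(bg, cfg$rate))$samples)
  amp_range <- cfg$amp_range
  if (is.null(amp_range)) {
    # Hann-windowed sinusoid of peak A has RMS A * sqrt(3/8) / sqrt(2)
    a_mid <- cfg$snr * sigma_bg / (sqrt(3 / 8) / sqrt(2))
    amp_range <- a_mid * c(0.85, 1.15)
  }
  # Poisson spindle count, uniform proposals, thinned to forbid overlap
  n_prop <- stats::rpois(1, cfg$density * cfg$duration / 60)
  ons <- numeric(0); durs <- numeric(0); amps <- numeric(0); freqs <- numeric(0)
  if (n_prop > 0) {
    p_dur <- stats::runif(n_prop, cfg$dur_range[1], cfg$dur_range[2])
    p_on <- stats::runif(n_prop, 1, pmax(1, cfg$duration - p_dur - 1))
    o <- order(p_on)
    p_on <- p_on[o]; p_dur <- p_dur[o]
    rejected <- 0L
    last_end <- -Inf
    for (i in seq_len(n_prop)) {
      if (p_on[i] > last_end + 0.5) {
        ons <- c(ons, p_on[i]); durs <- c(durs, p_dur[i])
        last_end <- p_on[i] + p_dur[i]
      } else rejected <- rejected + 1L
    }
    if (rejected > 0.5 * n_prop)
      stop("spindle density too high: overlap thinning rejected > 50% of proposals")
    freqs <- stats::runif(length(ons), cfg$freq_range[1], cfg$freq_range[2])
    amps <- stats::runif(length(ons), amp_range[1], amp_range[2])
  }
  x <- bg
  for (i in seq_along(ons)) {
    i0 <- floor(ons[i] * cfg$rate) + 1L
    len <- max(2L, round(durs[i] * cfg$rate))
    i1 <- min(n, i0 + len - 1L)
    tt <- (seq.int(i0, i1) - i0) / cfg$rate
    ph <- stats::runif(1, 0, 2 * pi)
    x[i0:i1] <- x[i0:i1] +
      amps[i] * .hann(i1 - i0 + 1L) * sin(2 * pi * freqs[i] * tt + ph)
  }
  n_kc <- stats::rpois(1, cfg$kcomplex_rate * cfg$duration / 60)
  kc_on <- sort(stats::runif(n_kc, 1, cfg$duration - 2))
  for (on in kc_on) {
    i0 <- floor(on * cfg$rate) + 1L
    len <- round(1.0 * cfg$rate)
    i1 <- min(n, i0 + len - 1L)
    tt <- (seq.int(i0, i1) - i0) / cfg$rate
    x[i0:i1] <- x[i0:i1] + 75 * sin(2 * pi * tt / 1.0) * .hann(i1 - i0 + 1L)
  }
  n_epochs <- ceiling(cfg$duration / 30)
  stages <- stage_series(rep(c("N2", "N3"), length.out = n_epochs), 30)
  truth <- event_list(onset = ons, duration = durs,
                      amplitude = amps, frequency = freqs)
  scorer_models <- lapply(seq_along(cfg$scorers), function(i) {
    m <- cfg$scorers[[i]]
    if (is.null(m$threshold))
      m$threshold <- amp_range[1] +
        (if (i == 1) 0.35 else 0.10) * diff(amp_range)
    m
  })
  cfg$amp_range <- amp_range
  structure(list(rec = recording(x, cfg$rate, "C3-A1"), stages = stages,
                 truth = truth, scorer_models = scorer_models, config = cfg,
                 background_sigma_rms = sigma_bg, kcomplex_onsets = kc_on),
            class = "psg_sim")
}

#' @export
print.psg_sim <- function(x, ...) {
  cat(sprintf("<psg_sim> %.0f s @ %g Hz: %d spindles, %d K-complexes, sigma bg RMS %.1f uV\n",
              x$config$duration, x$config$rate, nrow(x$truth),
              length(x$kcomplex_onsets), x$background_sigma_rms))
  invisible(x)
}

#' Derive a simulated scorer's annotation from ground truth
#'
#' Keeps events whose peak amplitude reaches the scorer's sensitivity
#' threshold, with a seeded logistic miss probability near the threshold
#' (0.7 uV scale). Duration style `"fixed_1s"` replaces every duration by a
#' 1 s interval centered on the event midpoint, mimicking scorers who mark
#' occurrences but not extents.
#'
#' @param truth [event_list()] with an `amplitude` metadata column.
#' @param model `list(threshold = uV, style = "true_duration"|"fixed_1s")`.
#' @param seed RNG seed.
#' @return an [event_list()], sorted.
#' @export
apply_scorer_model <- function(truth, model, seed = 1L) {
  if (is.null(truth$amplitude)) stop("truth events need an 'amplitude' column")
  set.seed(seed)
  amp <- truth$amplitude
  keep <- amp >= model$threshold &
    stats::runif(length(amp)) < stats::plogis((amp - model$threshold) / 0.7)
  ev <- truth[keep, , drop = FALSE]
  on <- ev$onset; dur <- ev$duration
  if (identical(model$style, "fixed_1s")) {
    mid <- on + dur / 2
    on <- pmax(0, mid - 0.5)
    dur <- rep(1.0, length(on))
  }
  o <- order(on)
  event_list(onset = on[o], duration = dur[o])
}

#' Export a simulated recording in the formats the readers ingest
#'
#' Writes the EDF signal, the plain-text truth and per-scorer annotation
#' files, and the hypnogram, so the full file-based pipeline can run on
#' generated data.
#'
#' @param sim a [simulate_psg()] result.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return named list of file paths.
#' @export
write_psg <- function(sim, dir, basename = "psg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(basename, suffix))
  write_edf(sim$rec, p(".edf"), physical_range = 500)
  write_annotations(sim$truth, p("_truth.txt"))
  paths <- list(edf = p(".edf"), truth = p("_truth.txt"),
                hypnogram = p("_hypnogram.txt"))
  for (i in seq_along(sim$scorer_models)) {
    sc <- apply_scorer_model(sim$truth, sim$scorer_models[[i]],
                             seed = sim$config$seed + i)
    f <- p(sprintf("_scorer%d.txt", i))
    write_annotations(sc, f)
    paths[[sprintf("scorer%d", i)]] <- f
  }
  write_hypnogram(sim$stages, p("_hypnogram.txt"))
  paths
}
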
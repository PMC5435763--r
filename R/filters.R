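#' Zero-phase sigma-band FIR filter
#'
#' Band-limits an EEG recording to the spindle (sigma) band with a
#' linear-phase Hamming-window FIR filter applied with group-delay
#' compensation and reflection padding, i.e. zero phase overall. The filter
#' length targets a 1 Hz transition band; Hamming sidelobes give > 50 dB
#' stopband rejection.
#'
#' @param rec a [recording()].
#' @param lo,hi passband edges in Hz (defaults 11 and 16).
#' @return A [recording()] of the filtered signal, same length and rate.
#' @export
bandpass_sigma <- function(rec, lo = 11, hi = 16) {
  fs <- rec$rate
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("upper passband edge must be below Nyquist")
  # Hamming transition width ~ 3.3 / L (normalized); aim at 1 Hz
  L <- ceiling(3.3 * fs)
  L <- min(L, max(9, 2 * floor((length(rec$samples) - 1) / 2) - 1))
  if (L %% 2 == 0) L <- L + 1
  b <- signal::fir1(L - 1, c(lo, hi) / (fs / 2), type = "pass")
  half <- (L - 1) / 2
  x <- rec$samples
  n <- length(x)
  # reflect-pad, causal FIR, then undo the (L-1)/2 linear-phase delay
  lp <- x[pmin(n, half + 1):2]
  rp <- x[(n - 1):pmax(1, n - half)]
  if (half == 0) lp <- rp <- numeric(0)
  xp <- c(lp, x, rp)
  yp <- as.numeric(signal::filter(as.numeric(b), 1, xp))
  y <- yp[(2 * half + 1):(2 * half + n)]
  recording(y, fs, rec$channel)
}

#' Moving RMS on a regular time grid
#'
#' One value per `resolution`-second step; each value is the RMS of the
#' samples inside a centered window of `window` seconds, truncated at the
#' recording edges.
#'
#' @param sig a [recording()] (normally the sigma-filtered signal).
#' @param resolution output grid step (s).
#' @param window RMS window length (s).
#' @return A data frame with columns `time` (window centers, s) and `rms`.
#' @export
moving_rms <- function(sig, resolution, window) {
  if (resolution <= 0 || window <= 0) stop("resolution and window must be positive")
  if (window * sig$rate < 2) stop("window must cover at least 2 samples")
  x <- sig$samples
  n <- length(x)
  tt <- seq(resolution / 2, n / sig$rate - resolution / 2 + 1e-12, by = resolution)
  cs <- c(0, cumsum(x^2))
  i0 <- pmax(0L, as.integer(ceiling((tt - window / 2) * sig$rate - 1e-9)))
  i1 <- pmin(n - 1L, as.integer(ceiling((tt + window / 2) * sig$rate - 1e-9)) - 1L)
  cnt <- i1 - i0 + 1L
  data.frame(time = tt, rms = sqrt((cs[i1 + 2L] - cs[i0 + 1L]) / cnt))
}

# indices (1-based) of strict-ish local maxima of x
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Peak envelope via linear interpolation through local maxima
#'
#' @param x numeric signal (typically a rectified sigma-filtered trace).
#' @return numeric vector of the same length.
#' @export
peak_envelope <- function(x) {
  pk <- local_maxima(x)
  if (length(pk) < 2) return(rep(max(x), length(x)))
  stats::approx(pk, x[pk], xout = seq_along(x), rule = 2)$y
}

# cubic-spline envelope through local maxima of |x| (instantaneous
# amplitude for the fuzzy-logic detectors); constant fallback when the
# signal carries fewer than 2 interior peaks
spline_envelope <- function(x) {
  ax <- abs(x)
  pk <- local_maxima(ax)
  if (length(pk) < 2) return(rep(max(ax), length(x)))
  f <- stats::splinefun(pk, ax[pk], method = "natural")
  env <- f(seq_along(x))
  env[env < 0] <- 0
  env
}

#' Amplitude normalization statistics for the Fourier-based detectors
#'
#' Computes, from the sigma-filtered signal restricted by the hypnogram:
#' the peak (`A1`) and mean (`A2`) rectified amplitude over NREM 2/3/4
#' samples, the standard deviation of the filtered N2 signal (`sigma_n2`),
#' and the moving-RMS series over NREM 2/3/4 (0.1 s grid, 0.25 s window)
#' from which percentile thresholds are drawn. Statistics are computed once
#' per recording and reused across segments so that thresholds stay stable
#' under subsampled training.
#'
#' @param rec a [recording()].
#' @param stages a [stage_series()] or `NULL` (whole recording treated as N2).
#' @param band sigma passband (Hz).
#' @return An object of class `norm_stats` with fields `A1`, `A2`,
#'   `sigma_n2`, `rms_values`, plus the filtered recording as `filtered`.
#' @export
norm_stats <- function(rec, stages = NULL, band = c(11, 16)) {
  filt <- bandpass_sigma(rec, band[1], band[2])
  nrem <- stage_mask(rec, stages, c("N2", "N3", "N4"))
  n2 <- stage_mask(rec, stages, "N2")
  if (!any(nrem)) stop("normalization error: recording has no NREM 2/3/4 samples")
  if (!any(n2)) stop("normalization error: recording has no NREM 2 samples")
  rectified <- abs(filt$samples[nrem])
  grid <- moving_rms(filt, 0.1, 0.25)
  gi <- pmin(length(nrem), pmax(1L, as.integer(floor(grid$time * rec$rate)) + 1L))
  structure(list(A1 = max(rectified),
                 A2 = mean(rectified),
                 sigma_n2 = stats::sd(filt$samples[n2]),
                 rms_values = grid$rms[nrem[gi]],
                 filtered = filt),
            class = "norm_stats")
}
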
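# Morlet continuous wavelet transform and the top-scale probabilistic
# estimate behind the wavelet detector.

# analytic Morlet (omega0 = 6) CWT via FFT convolution; returns the
# power matrix (n_scales x n_samples). Amplitude (L1) normalization: every
# scale responds with the same magnitude to a unit sinusoid at its center
# frequency, so the top-scale ranking reflects component amplitudes rather
# than the 1/f power bias of EEG spectra.
.morlet_cwt_power <- function(x, rate, freqs) {
  n <- length(x)
  omega0 <- 6
  xh <- stats::fft(x)
  w <- 2 * pi * rate * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n  # rad/s
  pos <- w > 0
  P <- matrix(0, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])        # scale in seconds
    psi <- numeric(n)
    psi[pos] <- 2 * exp(-(s * w[pos] - omega0)^2 / 2)
    wt <- stats::fft(xh * psi, inverse = TRUE) / n
    P[k, ] <- Mod(wt)^2
  }
  P
}

#' Instantaneous spindle-probability estimate from top wavelet scales
#'
#' Computes a Morlet scalogram over a geometric grid of scales whose center
#' frequencies cover 0.5--30 Hz, normalizes power across scales to
#' percentages at each time instant, and reports the fraction of the 10
#' largest-power scales whose center frequency lies inside `[lo, hi]`. Ties
#' (including the all-zero signal) are broken by lower scale index, i.e.
#' lower center frequency first. The default grid density (120 scales)
#' places more than 10 scale center frequencies inside any plausible
#' spindle band, so the estimate can reach 1 over a sustained sigma burst.
#'
#' @param rec a [recording()].
#' @param lo,hi frequency band of interest (Hz).
#' @param n_scales number of scales on the geometric grid (>= 10).
#' @return A list of class `fuzzy_estimate` with `values` (per-sample, in
#'   `[0, 1]`) and `rate`.
#' @export
cwt_probability_estimate <- function(rec, lo = 11, hi = 16, n_scales = 120L) {
  if (n_scales < 10L) stop("need at least 10 scales")
  if (!(lo > 0 && lo < hi && hi < rec$rate / 2)) stop("band must satisfy 0 < lo < hi < rate/2")
  freqs <- exp(seq(log(0.5), log(min(30, rec$rate / 2 * 0.99)), length.out = n_scales))
  P <- .morlet_cwt_power(rec$samples, rec$rate, freqs)
  est <- cwt_band_fraction(P, freqs, lo, hi)
  structure(list(values = est, rate = rec$rate), class = "fuzzy_estimate")
}

# given a power matrix and its scale frequencies, the per-time fraction of
# the 10 strongest scales falling in [lo, hi]; exposed internally so the
# wavelet detector can reuse one scalogram across parameter vectors
cwt_band_fraction <- function(P, freqs, lo, hi) {
  top <- cwt_top_frequencies(P, freqs)
  colSums(top >= lo & top <= hi) / nrow(top)
}

# 10 x n matrix of the center frequencies of the 10 strongest scales at
# each time instant (ties by lower scale index)
cwt_top_frequencies <- function(P, freqs, n_top = 10L) {
  apply(P, 2, function(p) freqs[order(-p)[seq_len(n_top)]])
}
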
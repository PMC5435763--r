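# Empirical mode decomposition and related instantaneous-frequency tools
# used by the Hilbert-Huang detectors.

# cubic-spline envelope through extrema with mirror extension at the ends;
# returns the envelope evaluated on 1..n
.spline_through <- function(idx, val, n) {
  if (length(idx) < 2) return(rep(if (length(idx)) val else 0, n))
  k <- min(2L, length(idx))
  li <- 2 - rev(idx[seq_len(k)]); lv <- rev(val[seq_len(k)])
  ri <- 2 * n - rev(rev(idx)[seq_len(k)]); rv <- rev(rev(val)[seq_len(k)])
  keep_l <- li < idx[1]; keep_r <- ri > idx[length(idx)]
  xi <- c(li[keep_l], idx, ri[keep_r])
  yi <- c(lv[keep_l], val, rv[keep_r])
  stats::splinefun(xi, yi, method = "natural")(seq_len(n))
}

# one round of sifting: returns the IMF extracted from x, or NULL when x
# carries too few extrema to oscillate
.sift_imf <- function(x, max_sift = 10L, tol = 0.2) {
  h <- x
  n <- length(x)
  for (it in seq_len(max_sift)) {
    mx <- local_maxima(h); mn <- local_minima(h)
    if (length(mx) + length(mn) < 3L) {
      if (it == 1L) return(NULL) else break
    }
    up <- .spline_through(mx, h[mx], n)
    lo <- .spline_through(mn, h[mn], n)
    m <- (up + lo) / 2
    h_new <- h - m
    sd_it <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_it < tol) break
  }
  h
}

#' Empirical mode decomposition by sifting
#'
#' Standard EMD: cubic-spline upper/lower envelopes through local
#' maxima/minima (mirror-extended at the boundaries), subtract the mean
#' envelope, iterate until the normalized squared difference between
#' successive sifts drops below 0.2 (or 10 sift iterations), then repeat on
#' the residual. The sum of the returned IMFs plus the residual equals the
#' input exactly (up to floating-point round-off).
#'
#' @param sig a [recording()] or numeric vector.
#' @param k maximum number of intrinsic mode functions to extract.
#' @return A list of class `imf_set` with elements `imfs` (list of numeric
#'   vectors) and `residual`.
#' @export
emd_sift <- function(sig, k = 3L) {
  x <- if (inherits(sig, "recording")) sig$samples else as.numeric(sig)
  if (k < 1) stop("k must be >= 1")
  if (length(x) < 8) stop("signal too short for sifting")
  imfs <- list()
  res <- x
  for (j in seq_len(k)) {
    h <- .sift_imf(res)
    if (is.null(h)) break
    imfs[[j]] <- h
    res <- res - h
  }
  structure(list(imfs = imfs, residual = res), class = "imf_set")
}

#' One-ball rolling-ball high-pass sifting
#'
#' Extracts a single oscillatory component whose energy sits above a cutoff
#' frequency by rolling a flat ball of half-width `1 / (2 * f_cut)` seconds
#' over and under the signal: the roll over the top (morphological
#' closing) fills every valley narrower than the ball, the roll underneath
#' (opening) shaves every crest narrower than the ball, and the average of
#' the two, lightly smoothed, is the sub-cutoff trend. Oscillations faster
#' than `f_cut` fit entirely under the ball and survive in the component;
#' slower structure (delta waves, K-complex transients) is tracked by both
#' rolls and removed. The trend removal is iterated a few times to sharpen
#' the separation. By construction `component + remainder == input`
#' exactly.
#'
#' @param sig a [recording()].
#' @param f_cut cutoff frequency (Hz), default 10.
#' @param max_iter number of trend-removal refinements.
#' @return A [recording()] holding the high-frequency component.
#' @export
rolling_ball_highpass <- function(sig, f_cut = 10, max_iter = 8L) {
  if (f_cut <= 0 || f_cut >= sig$rate / 2) stop("f_cut must lie in (0, rate/2)")
  x <- sig$samples
  h <- max(1L, round(sig$rate / (2 * f_cut)))  # ball half-width in samples
  comp <- x
  for (it in seq_len(max_iter)) {
    closing <- .roll_extreme(.roll_extreme(comp, h, pmax), h, pmin)
    opening <- .roll_extreme(.roll_extreme(comp, h, pmin), h, pmax)
    trend <- .moving_avg((closing + opening) / 2, h)
    if (sum(trend^2) / max(sum(comp^2), .Machine$double.eps) < 1e-6) break
    comp <- comp - trend
  }
  recording(comp, sig$rate, sig$channel)
}

# running max (f = pmax) or min (f = pmin) over the +-w window
.roll_extreme <- function(x, w, f) {
  n <- length(x)
  out <- x
  pad <- if (identical(f, pmax)) -Inf else Inf
  for (s in c(-(w:1), 1:w)) {
    if (s > 0) idx <- c((s + 1):n, rep(NA, s)) else idx <- c(rep(NA, -s), 1:(n + s))
    shifted <- x[idx]
    shifted[is.na(shifted)] <- pad
    out <- f(out, shifted)
  }
  out
}

#' Instantaneous frequency from zero-crossing intervals
#'
#' For each sample, the window spanning the nearest `n_crossings`
#' consecutive zero-crossing intervals gives
#' `f = n_crossings / (2 * window duration)`. Samples before the first /
#' after the last crossing take the nearest defined value. Odd window sizes
#' 1, 3, 5, 7, 9 provide progressively smoother estimates.
#'
#' @param imf numeric vector (an IMF or oscillatory component).
#' @param rate sampling rate (Hz).
#' @param n_crossings odd number of crossing intervals per window.
#' @return numeric vector of per-sample frequency estimates (Hz).
#' @export
zero_crossing_frequency <- function(imf, rate, n_crossings = 1L) {
  if (n_crossings %% 2 != 1) stop("n_crossings must be odd")
  x <- as.numeric(imf)
  n <- length(x)
  s <- sign(x)
  # carry the previous sign over exact zeros so each crossing counts once
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  ch <- which(s[-n] != s[-1])
  if (length(ch) < n_crossings + 1L) {
    warning("too few zero crossings; returning all-zero frequency estimate")
    return(numeric(n))
  }
  # linear-interpolated crossing times (seconds, 0-based sample times)
  tc <- (ch - 1 + x[ch] / (x[ch] - x[ch + 1L])) / rate
  m <- length(tc)
  n_win <- m - n_crossings
  wfreq <- n_crossings / (2 * (tc[(1 + n_crossings):m] - tc[1:n_win]))
  ts <- (seq_len(n) - 1) / rate
  iv <- findInterval(ts, tc)                 # 0 before first crossing
  j <- iv - (n_crossings - 1L) %/% 2L
  j[iv == 0L] <- 1L
  j <- pmin(pmax(j, 1L), n_win)
  wfreq[j]
}

#' Trapezoidal fuzzy membership function
#'
#' Breakpoints are parameterized as `(b - rise, b, b + plateau,
#' b + plateau + fall)`: membership is 0 up to the first breakpoint, rises
#' linearly to 1 at `b`, stays 1 across the plateau, and falls linearly
#' back to 0. Zero-width edges degenerate to step/indicator functions.
#'
#' @param v value(s) to evaluate.
#' @param p_a rise width (>= 0).
#' @param p_b plateau onset.
#' @param p_c plateau width (>= 0).
#' @param p_d falloff width (>= 0).
#' @return membership value(s) in `[0, 1]`.
#' @export
trapezoid_membership <- function(v, p_a, p_b, p_c, p_d) {
  if (p_a < 0 || p_c < 0 || p_d < 0) stop("widths must be non-negative")
  a <- p_b - p_a; b <- p_b; cc <- p_b + p_c; d <- cc + p_d
  m <- numeric(length(v))
  if (p_a > 0) {
    i <- v > a & v < b
    m[i] <- (v[i] - a) / (b - a)
  }
  if (p_d > 0) {
    i <- v > cc & v < d
    m[i] <- (d - v[i]) / (d - cc)
  }
  m[v >= b & v <= cc] <- 1
  m
}
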
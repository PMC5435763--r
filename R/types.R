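#' Single-channel EEG recording
#'
#' A uniformly sampled single-channel EEG signal with amplitudes in
#' microvolts. All detection code in the package works in physical units
#' (seconds, Hz, uV) and only touches sample indices at the mask boundary,
#' so recordings at any native rate (50--256 Hz clinical material) are
#' handled without resampling.
#'
#' @param samples numeric vector of amplitudes (uV); must be finite.
#' @param rate sampling frequency in Hz; must be positive.
#' @param channel channel label, e.g. `"C3-A1"`.
#' @return An object of class `recording`: a list with elements
#'   `samples`, `rate`, `channel`.
#' @export
recording <- function(samples, rate, channel = "EEG") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording needs at least one sample")
  if (!all(is.finite(samples))) stop("recording samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(list(samples = samples, rate = rate, channel = as.character(channel)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$rate, duration(x)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$rate

#' Per-epoch sleep stage series
#'
#' Hypnogram companion to a [recording()]: one stage label per fixed-length
#' epoch. Stage labels follow the usual scoring vocabulary
#' (W, N1, N2, N3, N4, REM, UNKNOWN).
#'
#' @param stages character vector of per-epoch labels.
#' @param epoch_length epoch duration in seconds (commonly 30).
#' @return An object of class `stage_series`.
#' @export
stage_series <- function(stages, epoch_length = 30) {
  stages <- toupper(as.character(stages))
  ok <- c("W", "N1", "N2", "N3", "N4", "REM", "UNKNOWN")
  if (!all(stages %in% ok))
    stop("unknown stage label(s): ", paste(unique(setdiff(stages, ok)), collapse = ", "))
  if (epoch_length <= 0) stop("epoch_length must be positive")
  structure(list(stages = stages, epoch_length = epoch_length),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("<stage_series> %d epochs x %g s: %s\n",
              length(x$stages), x$epoch_length,
              paste(names(table(x$stages)), table(x$stages), sep = ":", collapse = " ")))
  invisible(x)
}

#' Ordered list of spindle events
#'
#' Events are half-open intervals `[onset, onset + duration)` in continuous
#' seconds. Durations must be positive and onsets non-decreasing.
#'
#' @param onset numeric vector of onsets (s).
#' @param duration numeric vector of durations (s), recycled to length of
#'   `onset`.
#' @param ... further per-event metadata columns (e.g. amplitude), each
#'   recycled to the number of events.
#' @return A `data.frame` of class `event_list` with columns `onset`,
#'   `duration`, and any metadata.
#' @export
event_list <- function(onset = numeric(0), duration = numeric(0), ...) {
  onset <- as.numeric(onset)
  duration <- rep_len(as.numeric(duration), length(onset))
  if (length(onset) && any(duration <= 0)) stop("event durations must be positive")
  if (is.unsorted(onset)) stop("event onsets must be non-decreasing")
  extra <- list(...)
  df <- data.frame(onset = onset, duration = duration)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], length(onset))
  class(df) <- c("event_list", "data.frame")
  df
}

# fast internal constructor: bare onset/duration event list without the
# validation overhead of event_list() (hot path in detection loops)
.ev <- function(onset, duration) {
  structure(list(onset = onset, duration = duration),
            class = c("event_list", "data.frame"),
            row.names = if (length(onset)) seq_along(onset) else integer(0))
}

as_event_list <- function(df) {
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events", nrow(x)))
  if (nrow(x))
    cat(sprintf(", spanning %.2f-%.2f s, median duration %.2f s",
                min(x$onset), max(x$onset + x$duration), stats::median(x$duration)))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

n_events <- function(ev) nrow(ev)

#' Boolean sample mask aligned to a recording grid
#'
#' @param mask logical vector, one entry per sample.
#' @param rate sampling rate in Hz.
#' @return An object of class `sample_mask`.
#' @export
sample_mask <- function(mask, rate) {
  structure(list(mask = as.logical(mask), rate = rate), class = "sample_mask")
}

#' Convert events to a by-sample mask
#'
#' Sample `i` (0-based) covers time `i / rate`; it is marked true when that
#' time falls inside some half-open event interval `[onset, onset + dur)`.
#' Events running past the end of the grid are clipped with a warning.
#'
#' @param events an [event_list()].
#' @param rate sampling rate (Hz).
#' @param n_samples number of samples on the grid.
#' @return A [sample_mask()] of length `n_samples`.
#' @export
events_to_mask <- function(events, rate, n_samples) {
  stopifnot(rate > 0, n_samples >= 1)
  m <- logical(n_samples)
  if (nrow(events)) {
    t_end <- n_samples / rate
    for (i in seq_len(nrow(events))) {
      on <- events$onset[i]; off <- on + events$duration[i]
      if (off > t_end) {
        warning(sprintf("event at %.3f s extends beyond recording end (%.3f s); clipped",
                        on, t_end))
        off <- t_end
      }
      # first sample with i/rate >= on; last with i/rate < off
      i0 <- ceiling(on * rate - 1e-9)
      i1 <- ceiling(off * rate - 1e-9) - 1
      i0 <- max(i0, 0); i1 <- min(i1, n_samples - 1)
      if (i1 >= i0) m[(i0:i1) + 1L] <- TRUE
    }
  }
  sample_mask(m, rate)
}

#' Convert a by-sample mask back to events
#'
#' One event per maximal run of true samples; no minimum-duration filter is
#' applied, so sub-0.5 s regroupings survive (by-sample fusion semantics).
#'
#' @param mask a [sample_mask()].
#' @return An [event_list()]; events are disjoint and sorted.
#' @export
mask_to_events <- function(mask) {
  m <- mask$mask
  if (!length(m) || !any(m)) return(event_list())
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  .ev((starts[keep] - 1L) / mask$rate, r$lengths[keep] / mask$rate)
}

#' Merge overlapping or touching intervals
#'
#' @param events an [event_list()].
#' @param gap intervals separated by less than `gap` seconds are merged
#'   (default 0: only overlapping/abutting intervals merge).
#' @return An [event_list()] of pairwise disjoint events.
#' @export
merge_events <- function(events, gap = 0) {
  if (nrow(events) <= 1L) return(events)
  o <- order(events$onset)
  on <- events$onset[o]; off <- on + events$duration[o]
  res_on <- on[1]; res_off <- off[1]; k <- 1L
  for (i in 2:length(on)) {
    if (on[i] < res_off[k] + gap) {
      res_off[k] <- max(res_off[k], off[i])
    } else {
      k <- k + 1L; res_on[k] <- on[i]; res_off[k] <- off[i]
    }
  }
  .ev(res_on, res_off - res_on)
}

#' Per-sample stage mask
#'
#' Marks each sample of a recording with whether its epoch's stage is in
#' `which`. A `NULL` stage series treats the whole recording as N2 (the
#' convention for 30-min excerpts distributed without hypnograms).
#'
#' @param rec a [recording()].
#' @param stages a [stage_series()] or `NULL`.
#' @param which character vector of stage labels to select.
#' @return logical vector of `length(rec$samples)`.
#' @export
stage_mask <- function(rec, stages, which = c("N2", "N3", "N4")) {
  n <- length(rec$samples)
  if (is.null(stages)) return(rep(TRUE, n))
  idx <- floor((seq_len(n) - 1L) / rec$rate / stages$epoch_length) + 1L
  idx[idx > length(stages$stages)] <- length(stages$stages)
  stages$stages[idx] %in% which
}
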
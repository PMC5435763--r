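# Event-by-event scoring: overlap-rate matching, precision/recall/F-beta,
# and gold-standard fusion across scorers.

#' Overlap rate (intersection over union) of two intervals
#'
#' @param ss,d numeric length-2 vectors `c(start, end)` in seconds, both
#'   with positive duration.
#' @return ratio in `[0, 1]`.
#' @export
overlap_rate <- function(ss, d) {
  if (diff(ss) <= 0 || diff(d) <= 0) stop("intervals must have positive duration")
  inter <- max(0, min(ss[2], d[2]) - max(ss[1], d[1]))
  inter / (max(ss[2], d[2]) - min(ss[1], d[1]))
}

#' Match detections to gold events under the overlap-rate rule
#'
#' Greedy one-to-one matching: all gold/detection pairs with overlap rate
#' strictly above `r_ov` are sorted by descending overlap rate (ties broken
#' by earlier gold onset, then earlier detection onset) and accepted when
#' neither member is already matched. Each gold event and each detection is
#' used at most once, so `tp + fn = |gold|` and `tp + fp = |detections|`.
#'
#' @param gold,det [event_list()] objects.
#' @param r_ov overlap-rate threshold; a pair qualifies when its
#'   intersection-over-union exceeds this value (default 0.2).
#' @return object of class `match_result`: counts `tp`, `fn`, `fp` and a
#'   data frame `pairs` of matched (gold, detection) indices.
#' @export
match_events <- function(gold, det, r_ov = 0.2) {
  ng <- nrow(gold); nd <- nrow(det)
  p_gold <- integer(0); p_det <- integer(0); p_rate <- numeric(0)
  if (ng && nd) {
    g_on <- gold$onset; g_off <- gold$onset + gold$duration
    d_on <- det$onset; d_off <- det$onset + det$duration
    inter <- pmax(0, outer(g_off, d_off, pmin) - outer(g_on, d_on, pmax))
    uni <- outer(g_off, d_off, pmax) - outer(g_on, d_on, pmin)
    rov <- inter / uni
    cand <- which(rov > r_ov, arr.ind = TRUE, useNames = FALSE)
    if (nrow(cand)) {
      o <- order(-rov[cand], g_on[cand[, 1]], d_on[cand[, 2]])
      cg <- cand[o, 1]; cd <- cand[o, 2]
      g_used <- logical(ng); d_used <- logical(nd)
      k <- 0L
      p_gold <- integer(length(cg)); p_det <- integer(length(cg))
      p_rate <- numeric(length(cg))
      for (i in seq_along(cg)) {
        gi <- cg[i]; di <- cd[i]
        if (!g_used[gi] && !d_used[di]) {
          g_used[gi] <- TRUE; d_used[di] <- TRUE
          k <- k + 1L
          p_gold[k] <- gi; p_det[k] <- di; p_rate[k] <- rov[gi, di]
        }
      }
      length(p_gold) <- k; length(p_det) <- k; length(p_rate) <- k
    }
  }
  tp <- length(p_gold)
  structure(list(tp = tp, fn = ng - tp, fp = nd - tp,
                 pairs = data.frame(gold = p_gold, det = p_det, rate = p_rate)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FN=%d FP=%d\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' Precision, recall, and F-beta from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
#' `F_beta = (1+beta^2) P R / (R + beta^2 P)`. Zero denominators resolve to
#' 0 so the empty detector and the empty gold standard are well defined.
#'
#' @param m a [match_events()] result, or a list with `tp`, `fn`, `fp`.
#' @param beta recall weight (`beta = 1` weighs precision and recall
#'   equally; `beta = 2` favors recall).
#' @return named numeric vector `c(precision, recall, f_score)`.
#' @export
prf_metrics <- function(m, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  p <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  r <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  c(precision = p, recall = r, f_score = f_beta(p, r, beta))
}

#' F-beta score from precision and recall
#'
#' `F_beta = (1+beta^2) P R / (R + beta^2 P)`; returns 0 when both inputs
#' are 0. Useful for recomputing F-scores from published
#' precision/recall pairs.
#'
#' @param precision,recall values in `[0, 1]`.
#' @param beta recall weight.
#' @return the F-beta score.
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  ifelse(precision > 0 | recall > 0,
         (1 + beta^2) * precision * recall / (recall + beta^2 * precision),
         0)
}

#' By-sample fusion of two annotation sets
#'
#' Rasterizes both event lists onto a sample grid, combines the masks with
#' boolean OR (union) or AND (intersection), and regroups the result into
#' events with no duration filter -- so fragments shorter than any spindle
#' duration criterion survive, as by-sample fusion semantics require.
#'
#' @param a,b [event_list()] objects.
#' @param rate sample grid rate (Hz); annotation-only fusion conventionally
#'   uses a 256 Hz virtual grid.
#' @param n_samples grid length; defaults to cover both lists.
#' @param mode `"union"` or `"intersection"`.
#' @return an [event_list()].
#' @export
fuse_by_sample <- function(a, b, rate = 256, n_samples = NULL,
                           mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.null(n_samples)) {
    t_end <- max(0, a$onset + a$duration, b$onset + b$duration)
    n_samples <- max(1L, ceiling(t_end * rate))
  }
  ma <- events_to_mask(a, rate, n_samples)$mask
  mb <- events_to_mask(b, rate, n_samples)$mask
  m <- if (mode == "union") ma | mb else ma & mb
  mask_to_events(sample_mask(m, rate))
}

#' Combine two scorers' annotations, keeping expert 1's durations
#'
#' Partial/total-agreement fusion for annotation sets where the second
#' scorer's durations are unreliable (e.g. uniformly assigned 1 s): in
#' union mode, all expert-1 events are kept plus expert-2 events that
#' overlap no expert-1 event; in intersection mode, expert-1 events that
#' overlap at least one expert-2 event are kept. Overlap means any positive
#' temporal intersection.
#'
#' @param a expert-1 [event_list()] (durations trusted).
#' @param b expert-2 [event_list()].
#' @param mode `"union"` or `"intersection"`.
#' @return an [event_list()].
#' @export
dreams_combine_scorers <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  overlaps_any <- function(on, off, ref) {
    if (!nrow(ref)) return(rep(FALSE, length(on)))
    r_on <- ref$onset; r_off <- ref$onset + ref$duration
    vapply(seq_along(on), function(i)
      any(pmin(off[i], r_off) - pmax(on[i], r_on) > 0), TRUE)
  }
  if (mode == "intersection") {
    if (!nrow(a)) return(event_list())
    keep <- overlaps_any(a$onset, a$onset + a$duration, b)
    return(as_event_list(a[keep, c("onset", "duration"), drop = FALSE]))
  }
  extra <- if (nrow(b)) !overlaps_any(b$onset, b$onset + b$duration, a) else logical(0)
  out <- rbind(as.data.frame(a)[, c("onset", "duration"), drop = FALSE],
               as.data.frame(b)[extra, c("onset", "duration"), drop = FALSE])
  as_event_list(out)
}
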
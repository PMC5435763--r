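# Training protocol: subsample construction, hold-out and k-fold drivers,
# and Monte-Carlo confidence intervals for F1.

#' Subsample-building settings
#'
#' @param dilation seconds added to both ends of every collected event
#'   before merging segments (default 2.5).
#' @param target_total target cumulative subsample length in seconds
#'   (default 3600, i.e. 60 min).
#' @param collector_beta F-score weight used when selecting the collector
#'   operating point from a reference front (recall-weighted F2 by
#'   default).
#' @param seed RNG seed for the random segment draw.
#' @return list of class `subsample_spec`.
#' @export
subsample_spec <- function(dilation = 2.5, target_total = 3600,
                           collector_beta = 2, seed = 1L) {
  stopifnot(dilation >= 0, target_total > 0)
  structure(list(dilation = dilation, target_total = target_total,
                 collector_beta = collector_beta, seed = seed),
            class = "subsample_spec")
}

# a dataset is list(rec = recording, stages = stage_series or NULL,
# gold = event_list)
.check_dataset <- function(d) {
  stopifnot(inherits(d$rec, "recording"), inherits(d$gold, "event_list"))
  d
}

#' Build a detector-dependent training subsample
#'
#' Runs the collector detector on every training recording, collects its
#' false positives (detections with no overlap-rate match to gold) together
#' with all gold events, dilates each by `spec$dilation` seconds on both
#' ends, merges overlaps into a pool of segments, and draws segments at
#' random (seeded, without replacement) until the cumulative length reaches
#' `spec$target_total` seconds. Returned segments carry clipped
#' segment-local gold annotations and the full-recording normalization
#' statistics, and are processed independently downstream.
#'
#' @param datasets list of datasets, each `list(rec, stages, gold)`.
#' @param collector a [detector_spec()] with its parameter vector set.
#' @param spec a [subsample_spec()].
#' @param r_ov overlap-rate threshold for the FP definition.
#' @return list of segments `list(rec, gold, stats, source, start)`.
#' @export
build_subsample <- function(datasets, collector, spec = subsample_spec(),
                            r_ov = 0.2) {
  pool <- list()
  for (k in seq_along(datasets)) {
    d <- .check_dataset(datasets[[k]])
    stats <- norm_stats(d$rec, d$stages)
    det <- detect_spindles(d$rec, collector, d$stages, stats)
    m <- match_events(d$gold, det, r_ov)
    fp_idx <- setdiff(seq_len(nrow(det)), m$pairs$det)
    seeds_ev <- rbind(as.data.frame(d$gold)[, c("onset", "duration")],
                      as.data.frame(det)[fp_idx, c("onset", "duration")])
    if (!nrow(seeds_ev)) next
    seeds_ev <- as_event_list(seeds_ev)
    total <- duration(d$rec)
    dil <- event_list(onset = pmax(0, seeds_ev$onset - spec$dilation),
                      duration = pmin(total, seeds_ev$onset + seeds_ev$duration +
                                        spec$dilation) -
                        pmax(0, seeds_ev$onset - spec$dilation))
    dil <- merge_events(dil)
    for (i in seq_len(nrow(dil)))
      pool[[length(pool) + 1L]] <- list(source = k, start = dil$onset[i],
                                        end = dil$onset[i] + dil$duration[i],
                                        stats = stats)
    datasets[[k]]$stats <- stats
  }
  if (!length(pool)) stop("no events or false positives to build a subsample from")
  lens <- vapply(pool, function(s) s$end - s$start, 0)
  if (sum(lens) < spec$target_total)
    warning(sprintf("segment pool (%.0f s) shorter than target (%.0f s); using all",
                    sum(lens), spec$target_total))
  set.seed(spec$seed)
  ord <- sample.int(length(pool))
  cum <- cumsum(lens[ord])
  take <- ord[seq_len(min(length(ord), which(cum >= spec$target_total)[1],
                          na.rm = TRUE))]
  if (sum(lens) < spec$target_total) take <- ord
  segments <- lapply(take, function(i) {
    s <- pool[[i]]
    d <- datasets[[s$source]]
    rate <- d$rec$rate
    i0 <- max(1L, floor(s$start * rate) + 1L)
    i1 <- min(length(d$rec$samples), ceiling(s$end * rate))
    t0 <- (i0 - 1L) / rate
    seg_end <- i1 / rate
    g <- d$gold
    keep <- g$onset < seg_end & g$onset + g$duration > t0
    g <- g[keep, , drop = FALSE]
    on <- pmax(g$onset, t0) - t0
    off <- pmin(g$onset + g$duration, seg_end) - t0
    list(rec = recording(d$rec$samples[i0:i1], rate, d$rec$channel),
         gold = event_list(onset = on, duration = off - on),
         stats = s$stats, source = s$source, start = t0, i0 = i0, i1 = i1)
  })
  attr(segments, "datasets") <- datasets
  segments
}

#' Pooled (FN, FP) objective over subsample segments
#'
#' Precomputes detector features per segment and returns an evaluator
#' suitable for [spea2()]: for a parameter vector it sums false negatives
#' and false positives of the detector across all segments.
#'
#' @param segments output of [build_subsample()].
#' @param spec a [detector_spec()] (id/bounds define the detector).
#' @param r_ov overlap-rate matching threshold.
#' @return function mapping a parameter vector to `c(fn, fp)`.
#' @export
subsample_objective <- function(segments, spec, r_ov = 0.2) {
  datasets <- attr(segments, "datasets")
  if (!is.null(datasets)) {
    # preprocess each source recording once, then slice per segment
    sources <- sort(unique(vapply(segments, `[[`, 0L, "source")))
    full <- list()
    for (k in sources) {
      d <- datasets[[k]]
      full[[k]] <- spindle_features(d$rec, spec, d$stages,
                                    stats = if (!is.null(d$stats)) d$stats
                                            else segments[[which(vapply(
                                              segments, `[[`, 0L, "source") == k)[1]]]$stats)
    }
    feats <- lapply(segments, function(s) slice_features(full[[s$source]], s$i0, s$i1))
  } else {
    feats <- lapply(segments, function(s)
      spindle_features(s$rec, spec, stages = NULL, stats = s$stats))
  }
  golds <- lapply(segments, `[[`, "gold")
  function(x) {
    fn <- 0L; fp <- 0L
    for (i in seq_along(feats)) {
      m <- match_events(golds[[i]], detect_with_features(feats[[i]], x), r_ov)
      fn <- fn + m$fn; fp <- fp + m$fp
    }
    c(fn, fp)
  }
}

# pooled counts of a parameter vector over complete datasets; features may
# be precomputed once per dataset for repeated application
.dataset_features <- function(datasets, spec) {
  lapply(datasets, function(d) {
    d <- .check_dataset(d)
    spindle_features(d$rec, spec, d$stages, d$stats)
  })
}

.counts_on_features <- function(feats, golds, x, r_ov = 0.2) {
  tp <- 0L; fn <- 0L; fp <- 0L
  for (i in seq_along(feats)) {
    m <- match_events(golds[[i]], detect_with_features(feats[[i]], x), r_ov)
    tp <- tp + m$tp; fn <- fn + m$fn; fp <- fp + m$fp
  }
  list(tp = tp, fn = fn, fp = fp)
}

# select the max-F1 front member by re-evaluation on complete datasets
.select_on_datasets <- function(front, datasets, spec, r_ov = 0.2) {
  feats <- .dataset_features(datasets, spec)
  golds <- lapply(datasets, `[[`, "gold")
  best <- NULL
  for (i in seq_len(nrow(front$X))) {
    cnt <- .counts_on_features(feats, golds, front$X[i, ], r_ov)
    prf <- prf_metrics(cnt)
    if (is.null(best) || prf["f_score"] > best$prf["f_score"] + 1e-12 ||
        (abs(prf["f_score"] - best$prf["f_score"]) <= 1e-12 && cnt$fp < best$counts$fp)) {
      best <- list(index = i, x = front$X[i, ], counts = cnt, prf = prf)
    }
  }
  best
}

#' Hold-out training and single-shot testing of a detector
#'
#' Builds a subsample from the training group, optimizes the detector's
#' (FN, FP) trade-off on it with SPEA2, re-evaluates every Pareto solution
#' on the complete training recordings to pick the max-F1 operating
#' parameters, and applies that single parameter vector to the held-out
#' test group exactly once. The report records the test-access count so the
#' single-shot discipline is auditable.
#'
#' @param train,test lists of datasets (`list(rec, stages, gold)` each),
#'   disjoint by subject.
#' @param spec a [detector_spec()] naming the detector to optimize.
#' @param control a [spea2_control()] list.
#' @param sspec a [subsample_spec()].
#' @param collector_params parameter vector for the subsample collector run
#'   (defaults to the midpoint of the detector's bounds).
#' @param r_ov overlap-rate matching threshold.
#' @return object of class `validation_report`.
#' @export
run_holdout <- function(train, test, spec, control = spea2_control(),
                        sspec = subsample_spec(), collector_params = NULL,
                        r_ov = 0.2) {
  if (!length(train) || !length(test)) stop("train and test groups must be non-empty")
  collector <- detector_spec(spec$id, collector_params)
  segments <- build_subsample(train, collector, sspec, r_ov)
  front <- spea2(subsample_objective(segments, spec, r_ov),
                 spec$lower, spec$upper, control)
  sel <- .select_on_datasets(front, train, spec, r_ov)
  test_evaluations <- 0L
  test_feats <- .dataset_features(test, spec)
  test_counts <- .counts_on_features(test_feats, lapply(test, `[[`, "gold"),
                                     sel$x, r_ov)
  test_evaluations <- test_evaluations + 1L
  structure(list(detector = spec$id, front = front, best_x = sel$x,
                 selected_index = sel$index,
                 train = c(sel$counts, as.list(sel$prf)),
                 test = c(test_counts, as.list(prf_metrics(test_counts))),
                 n_segments = length(segments),
                 test_evaluations = test_evaluations),
            class = "validation_report")
}

#' k-fold cross-validation of a detector
#'
#' Randomly partitions subjects into `k` near-equal groups (seeded). Each
#' fold trains on the other groups (subsample, SPEA2, max-F1 selection on
#' the complete training recordings) and evaluates on its validation
#' group; the pooled result micro-averages the summed TP/FN/FP.
#'
#' @param datasets list of datasets (one per subject).
#' @param spec a [detector_spec()].
#' @param k number of folds.
#' @param control a [spea2_control()] list.
#' @param sspec a [subsample_spec()].
#' @param collector_params collector parameters (see [run_holdout()]).
#' @param seed seed for the subject partition.
#' @param r_ov overlap-rate matching threshold.
#' @return object of class `validation_report` with per-fold reports, the
#'   fold assignment, and pooled metrics.
#' @export
run_kfold <- function(datasets, spec, k = 3L, control = spea2_control(),
                      sspec = subsample_spec(), collector_params = NULL,
                      seed = 1L, r_ov = 0.2) {
  n <- length(datasets)
  if (n < k) stop("need at least k subjects")
  folds <- kfold_partition(n, k, seed)
  per_fold <- vector("list", k)
  tp <- 0L; fn <- 0L; fp <- 0L
  for (f in seq_len(k)) {
    ctl <- control; ctl$seed <- control$seed + f
    ssp <- sspec; ssp$seed <- sspec$seed + f
    rep_f <- run_holdout(datasets[folds != f], datasets[folds == f],
                         spec, ctl, ssp, collector_params, r_ov)
    per_fold[[f]] <- rep_f
    tp <- tp + rep_f$test$tp; fn <- fn + rep_f$test$fn; fp <- fp + rep_f$test$fp
  }
  pooled <- list(tp = tp, fn = fn, fp = fp)
  structure(list(detector = spec$id, k = k, folds = folds,
                 per_fold = per_fold,
                 pooled = c(pooled, as.list(prf_metrics(pooled)))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> detector %s\n", x$detector))
  if (!is.null(x$pooled)) {
    cat(sprintf("  %d-fold pooled: TP=%d FN=%d FP=%d  P=%.3f R=%.3f F1=%.3f\n",
                x$k, x$pooled$tp, x$pooled$fn, x$pooled$fp,
                x$pooled$precision, x$pooled$recall, x$pooled$f_score))
  } else {
    cat(sprintf("  train: TP=%d FN=%d FP=%d  P=%.3f R=%.3f F1=%.3f\n",
                x$train$tp, x$train$fn, x$train$fp,
                x$train$precision, x$train$recall, x$train$f_score))
    cat(sprintf("  test:  TP=%d FN=%d FP=%d  P=%.3f R=%.3f F1=%.3f  (test touched %d time)\n",
                x$test$tp, x$test$fn, x$test$fp,
                x$test$precision, x$test$recall, x$test$f_score,
                x$test_evaluations))
  }
  invisible(x)
}

#' Random near-equal partition of subjects into folds
#'
#' @param n number of subjects.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold assignment of length `n`; fold sizes differ by at
#'   most one.
#' @export
kfold_partition <- function(n, k, seed = 1L) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Monte-Carlo confidence interval for F1
#'
#' Treats precision and recall as independent Beta posteriors under a
#' uniform prior -- `P ~ Beta(TP+1, FP+1)`, `R ~ Beta(TP+1, FN+1)` -- draws
#' them `draws` times, computes `F1 = 2PR/(P+R)` per draw, and returns the
#' empirical central interval at the requested level.
#'
#' @param tp,fn,fp event counts; `tp+fp` and `tp+fn` must be positive.
#' @param draws number of Monte-Carlo draws (default 10000).
#' @param level interval coverage (default 0.95).
#' @param seed RNG seed.
#' @return numeric `c(lower, upper)`.
#' @export
f1_confidence_interval <- function(tp, fn, fp, draws = 10000L, level = 0.95,
                                   seed = 1L) {
  if (tp + fp <= 0 || tp + fn <= 0) stop("tp+fp and tp+fn must be positive")
  set.seed(seed)
  p <- stats::rbeta(draws, tp + 1, fp + 1)
  r <- stats::rbeta(draws, tp + 1, fn + 1)
  f1 <- 2 * p * r / (p + r)
  unname(stats::quantile(f1, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Reconstruct TP/FN/FP counts from printed precision/recall
#'
#' Inverts three-decimal precision/recall values against a known gold count:
#' `TP = round(R * n_gold)`, `FN = n_gold - TP`, `FP = round(TP / P) - TP`.
#'
#' @param precision,recall printed values.
#' @param n_gold total gold-standard events.
#' @return list with `tp`, `fn`, `fp`.
#' @export
counts_from_rates <- function(precision, recall, n_gold) {
  tp <- round(recall * n_gold)
  list(tp = tp, fn = n_gold - tp, fp = round(tp / precision) - tp)
}
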
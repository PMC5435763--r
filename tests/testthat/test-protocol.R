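# Subsample construction, hold-out / k-fold discipline, and the
# Beta-posterior Monte-Carlo confidence interval for F1.

test_that("subsample segments dilate and merge collected events", {
  # one planted burst at 10 s that d2 will flag; gold placed at 12 s, so
  # the detection is a false positive and both seed a segment
  fx <- planted_burst(fs = 100, total = 60, onset = 10, dur = 1, seed = 5)
  ds <- list(list(rec = fx$rec, stages = NULL, gold = event_list(12, 1)))
  segs <- suppressWarnings(
    build_subsample(ds, detector_spec("d2", c(0.1, 0.25, 3, 0.4, 2)),
                    subsample_spec(dilation = 2.5, target_total = 10, seed = 1)))
  expect_equal(length(segs), 1L)
  # dilated detection (~[7.5, 13.5+]) and gold ([9.5, 15.5]) merge into one
  # segment; the detected onset carries the RMS grid granularity
  expect_lt(abs(segs[[1]]$start - 7.5), 0.5)
  expect_lt(abs((segs[[1]]$i1 / 100) - 15.5), 0.5)
  # gold clipped to segment-local time
  expect_equal(segs[[1]]$gold$onset, 12 - segs[[1]]$start, tolerance = 0.02)
})

test_that("subsample drawing respects the stopping rule and seed", {
  subj <- make_subject(201, duration = 300)
  ds <- list(subj[c("rec", "stages", "gold")])
  sp <- subsample_spec(target_total = 60, seed = 4)
  segs <- build_subsample(ds, detector_spec("d2"), sp)
  lens <- vapply(segs, function(s) (s$i1 - s$i0 + 1) / s$rec$rate, 0)
  expect_gte(sum(lens), 60)
  expect_lt(sum(lens), 60 + max(lens))
  segs2 <- build_subsample(ds, detector_spec("d2"), sp)
  expect_identical(lapply(segs, `[[`, "start"), lapply(segs2, `[[`, "start"))
  # pool shorter than the target: everything is returned, with a warning
  expect_warning(
    all_segs <- build_subsample(ds, detector_spec("d2"),
                                subsample_spec(target_total = 3600, seed = 4)),
    "shorter than target")
})

test_that("hold-out touches the test group exactly once and selects from the front", {
  train <- lapply(c(301, 302), make_subject, duration = 180)
  test_grp <- list(make_subject(303, duration = 180))
  rep <- run_holdout(lapply(train, `[`, c("rec", "stages", "gold")),
                     lapply(test_grp, `[`, c("rec", "stages", "gold")),
                     detector_spec("d2"),
                     spea2_control(pop_size = 12, max_gen = 8, seed = 2),
                     subsample_spec(target_total = 60, seed = 2))
  expect_identical(rep$test_evaluations, 1L)
  # the selected vector is a member of the subsample-derived front
  expect_true(any(apply(rep$front$X, 1, function(x)
    isTRUE(all.equal(unname(x), unname(rep$best_x))))))
  expect_identical(rep$train$tp + rep$train$fn,
                   sum(vapply(train, function(d) nrow(d$gold), 0L)))
})

test_that("a degenerate search space reproduces its own gold standard", {
  # bounds collapsed to one parameter vector: optimization must return it,
  # and gold built from that detector's output scores F1 = 1 on test
  x0 <- c(0.1, 0.25, 3, 0.4, 2)
  subj <- lapply(c(311, 312, 313), make_subject, duration = 180)
  ds <- lapply(subj, function(s) {
    det <- detect_spindles(s$rec, detector_spec("d2", x0), s$stages)
    list(rec = s$rec, stages = s$stages, gold = det)
  })
  spec0 <- detector_spec("d2", x0, lower = x0, upper = x0)
  rep <- suppressWarnings(            # pool may fall just short of target
    run_holdout(ds[1:2], ds[3], spec0,
                spea2_control(pop_size = 4, max_gen = 2, seed = 1),
                subsample_spec(target_total = 60, seed = 1),
                collector_params = x0))
  expect_equal(rep$test$f_score, 1)
  expect_equal(rep$train$f_score, 1)
})

test_that("k-fold partitions are balanced and cover every subject once", {
  f <- kfold_partition(19, 3, seed = 8)
  expect_equal(sort(as.integer(table(f))), c(6L, 6L, 7L))
  expect_equal(length(f), 19)
  expect_setequal(unique(f), 1:3)
})

test_that("k-fold pools per-fold counts by summation", {
  subj <- lapply(320 + 1:3, make_subject, duration = 180)
  ds <- lapply(subj, `[`, c("rec", "stages", "gold"))
  rep <- run_kfold(ds, detector_spec("d2"), k = 3,
                   control = spea2_control(pop_size = 8, max_gen = 4, seed = 3),
                   sspec = subsample_spec(target_total = 45, seed = 3), seed = 3)
  expect_equal(rep$pooled$tp, sum(vapply(rep$per_fold, function(f) f$test$tp, 0L)))
  expect_equal(rep$pooled$fn, sum(vapply(rep$per_fold, function(f) f$test$fn, 0L)))
  expect_equal(rep$pooled$fp, sum(vapply(rep$per_fold, function(f) f$test$fp, 0L)))
  # every subject validates exactly once
  expect_setequal(rep$folds, 1:3)
  # pooled gold count equals the union of subjects
  expect_equal(rep$pooled$tp + rep$pooled$fn,
               sum(vapply(ds, function(d) nrow(d$gold), 0L)))
})

test_that("subsample training approximates full-data training", {
  # the front trained on subsample segments, re-scored on complete
  # recordings, should sit close to a front trained on the full data
  for (s in 1:3) {
    subj <- lapply(500 + 10 * s + 1:2, make_subject, duration = 240)
    ds <- lapply(subj, `[`, c("rec", "stages", "gold"))
    golds <- lapply(ds, `[[`, "gold")
    spec <- detector_spec("d2")
    ctl <- spea2_control(pop_size = 24, max_gen = 16, seed = s)
    segs <- suppressWarnings(build_subsample(ds, detector_spec("d2"),
                                             subsample_spec(target_total = 90,
                                                            seed = s)))
    fr_sub <- spea2(subsample_objective(segs, spec), spec$lower, spec$upper, ctl)
    sel <- spindlefront:::.select_on_datasets(fr_sub, ds, spec)
    feats <- spindlefront:::.dataset_features(ds, spec)
    ev_full <- function(x) {
      fn <- 0L; fp <- 0L
      for (i in seq_along(feats)) {
        m <- match_events(golds[[i]], detect_with_features(feats[[i]], x))
        fn <- fn + m$fn; fp <- fp + m$fp
      }
      c(fn, fp)
    }
    fr_full <- spea2(ev_full, spec$lower, spec$upper, ctl)
    fm_full <- front_metrics(fr_full, sum(vapply(golds, nrow, 0L)))
    expect_lte(fm_full$best$f_score - sel$prf[["f_score"]], 0.05 + 1e-9)
  }
})

test_that("F1 confidence interval matches concentration and quadrature oracles", {
  # huge counts concentrate the posterior
  ci <- f1_confidence_interval(1e7, 1, 1, draws = 5000, seed = 1)
  expect_lt(diff(ci), 1e-3)

  # tp=fn=fp=1: P,R ~ Beta(2,2); quadrature over the product density
  p <- seq(0.0005, 0.9995, by = 0.001)
  wp <- dbeta(p, 2, 2); wr <- dbeta(p, 2, 2)
  f1 <- outer(p, p, function(a, b) 2 * a * b / (a + b))
  w <- outer(wp, wr)
  o <- order(f1)
  cdf <- cumsum(w[o]) / sum(w)
  q <- function(level) f1[o][which(cdf >= level)[1]]
  ci2 <- f1_confidence_interval(1, 1, 1, draws = 20000, seed = 2)
  expect_lt(abs(ci2[1] - q(0.025)), 0.01)
  expect_lt(abs(ci2[2] - q(0.975)), 0.01)

  # quantiles are monotone in level; doubling draws barely moves bounds
  cnt <- counts_from_rates(0.697, 0.783, 5165)
  ci90 <- f1_confidence_interval(cnt$tp, cnt$fn, cnt$fp, level = 0.90, seed = 3)
  ci95 <- f1_confidence_interval(cnt$tp, cnt$fn, cnt$fp, level = 0.95, seed = 3)
  expect_lt(ci95[1], ci90[1])
  expect_gt(ci95[2], ci90[2])
  ciA <- f1_confidence_interval(cnt$tp, cnt$fn, cnt$fp, draws = 10000, seed = 4)
  ciB <- f1_confidence_interval(cnt$tp, cnt$fn, cnt$fp, draws = 20000, seed = 4)
  expect_lt(max(abs(ciA - ciB)), 0.002)

  expect_error(f1_confidence_interval(0, 0, 5), "positive")
})

test_that("counts_from_rates inverts printed three-decimal precision/recall", {
  cnt <- counts_from_rates(0.697, 0.783, 5165)
  expect_equal(cnt$tp, 4044)
  expect_equal(cnt$fn, 1121)
  expect_equal(cnt$fp, 1758)
  prf <- prf_metrics(cnt)
  expect_equal(round(prf[["precision"]], 3), 0.697)
  expect_equal(round(prf[["recall"]], 3), 0.783)
})
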
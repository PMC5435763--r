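test_that("overlap rate is intersection over union", {
  expect_equal(overlap_rate(c(10, 11), c(10, 11)), 1.0)
  expect_equal(overlap_rate(c(10, 11), c(12, 13)), 0.0)
  expect_equal(overlap_rate(c(0, 1), c(0.5, 1.5)), 1 / 3)
  expect_error(overlap_rate(c(1, 1), c(0, 1)), "positive duration")
  # symmetry, and 1 only for identical intervals
  set.seed(1)
  for (i in 1:50) {
    a <- sort(runif(2)); b <- sort(runif(2))
    if (diff(a) == 0 || diff(b) == 0) next
    expect_equal(overlap_rate(a, b), overlap_rate(b, a))
    if (!isTRUE(all.equal(a, b))) expect_lt(overlap_rate(a, b), 1)
  }
})

test_that("greedy one-to-one matching resolves the worked instances", {
  m <- match_events(event_list(c(0, 5), c(1, 1)), event_list(0.2, 1))
  expect_equal(c(m$tp, m$fn, m$fp), c(1L, 1L, 0L))

  m2 <- match_events(event_list(c(0, 5), c(1, 1)), event_list())
  expect_equal(c(m2$tp, m2$fn, m2$fp), c(0L, 2L, 0L))

  # one long detection over two gold events: one-to-one keeps a single TP
  m3 <- match_events(event_list(c(0, 2), c(1, 1)), event_list(0, 3))
  expect_equal(c(m3$tp, m3$fn, m3$fp), c(1L, 1L, 0L))
})

test_that("matching counts always partition gold and detections", {
  set.seed(7)
  for (i in 1:1000) {
    gold <- random_event_list(sample(0:8, 1))
    det <- random_event_list(sample(0:8, 1))
    m <- match_events(gold, det)
    expect_identical(m$tp + m$fn, nrow(gold))
    expect_identical(m$tp + m$fp, nrow(det))
    expect_true(m$tp >= 0 && m$fn >= 0 && m$fp >= 0)
    expect_true(!anyDuplicated(m$pairs$gold) && !anyDuplicated(m$pairs$det))
  }
})

test_that("greedy matching is near-optimal against the bipartite oracle", {
  # sparse, spindle-like instances: up to 8 events over 30 s
  set.seed(13)
  n_trials <- 10000
  agree <- 0L
  for (i in seq_len(n_trials)) {
    gold <- random_event_list(sample(1:8, 1), span = 30)
    det <- random_event_list(sample(1:8, 1), span = 30)
    m <- match_events(gold, det)
    g_on <- gold$onset; g_off <- gold$onset + gold$duration
    d_on <- det$onset; d_off <- det$onset + det$duration
    inter <- pmax(0, outer(g_off, d_off, pmin) - outer(g_on, d_on, pmax))
    uni <- outer(g_off, d_off, pmax) - outer(g_on, d_on, pmin)
    adj <- inter / uni > 0.2
    if (m$tp == max_matching_tp(adj)) agree <- agree + 1L
  }
  # greedy is the specified behavior; the oracle quantifies its gap
  expect_gte(agree / n_trials, 0.99)
})

test_that("precision/recall/F-beta follow the count definitions", {
  # published-style worked value: P=0.697, R=0.783 at beta 1
  expect_equal(round(f_beta(0.697, 0.783), 3), 0.738)
  m <- counts_from_rates(0.697, 0.783, 5165)
  prf <- prf_metrics(m)
  expect_equal(round(prf[["precision"]], 3), 0.697)
  expect_equal(round(prf[["recall"]], 3), 0.783)

  expect_equal(prf_metrics(list(tp = 1, fn = 1, fp = 1))[["f_score"]], 0.5)
  # F2 weighs recall: P=0.5, R=1 -> 5*0.5*1/(1+4*0.5)
  expect_equal(prf_metrics(list(tp = 2, fn = 0, fp = 2), beta = 2)[["f_score"]],
               5 * 0.5 / 3)
  # zero-denominator conventions
  expect_equal(unname(prf_metrics(list(tp = 0, fn = 0, fp = 0))), c(0, 0, 0))
  expect_error(prf_metrics(list(tp = 1, fn = 1, fp = 1), beta = 0), "positive")
})

test_that("F-beta lies between precision and recall when both are positive", {
  set.seed(5)
  for (i in 1:200) {
    cnt <- list(tp = sample(1:50, 1), fn = sample(0:50, 1), fp = sample(0:50, 1))
    beta <- runif(1, 0.2, 4)
    prf <- prf_metrics(cnt, beta)
    expect_gte(prf[["f_score"]], min(prf[["precision"]], prf[["recall"]]) - 1e-12)
    expect_lte(prf[["f_score"]], max(prf[["precision"]], prf[["recall"]]) + 1e-12)
  }
})

test_that("by-sample fusion obeys interval algebra", {
  a <- event_list(0, 2); b <- event_list(1, 2)
  u <- fuse_by_sample(a, b, rate = 256, mode = "union")
  expect_equal(u$onset, 0); expect_equal(u$duration, 3, tolerance = 1e-2)
  i <- fuse_by_sample(a, b, rate = 256, mode = "intersection")
  expect_equal(i$onset, 1, tolerance = 1e-2)
  expect_equal(i$duration, 1, tolerance = 1e-2)

  d1 <- event_list(0, 1); d2 <- event_list(5, 1)
  expect_equal(nrow(fuse_by_sample(d1, d2, mode = "intersection")), 0)
  u2 <- fuse_by_sample(d1, d2, mode = "union")
  expect_equal(u2$onset, c(0, 5), tolerance = 1e-2)

  same <- event_list(c(1, 4), c(0.5, 1))
  expect_equal(fuse_by_sample(same, same, mode = "union"),
               fuse_by_sample(same, same, mode = "intersection"))
})

test_that("fusion masks nest: intersection within inputs within union", {
  set.seed(21)
  for (i in 1:50) {
    a <- random_event_list(sample(0:6, 1), span = 20)
    b <- random_event_list(sample(0:6, 1), span = 20)
    n <- 23 * 64                       # covers span plus maximal duration
    ma <- events_to_mask(a, 64, n)$mask
    mb <- events_to_mask(b, 64, n)$mask
    mi <- events_to_mask(fuse_by_sample(a, b, 64, n, "intersection"), 64, n)$mask
    mu <- events_to_mask(fuse_by_sample(a, b, 64, n, "union"), 64, n)$mask
    expect_true(all(mi <= ma) && all(mi <= mb))
    expect_true(all(ma <= mu) && all(mb <= mu))
  }
})

test_that("scorer combination keeps expert 1's durations", {
  a <- event_list(0, 1.2); b <- event_list(0.5, 1.0)
  u <- dreams_combine_scorers(a, b, "union")
  expect_equal(u$onset, 0); expect_equal(u$duration, 1.2)
  i <- dreams_combine_scorers(a, b, "intersection")
  expect_equal(i$duration, 1.2)

  a2 <- event_list(0, 1); b2 <- event_list(5, 1)
  u2 <- dreams_combine_scorers(a2, b2, "union")
  expect_equal(u2$onset, c(0, 5))
  expect_equal(nrow(dreams_combine_scorers(a2, b2, "intersection")), 0)

  expect_equal(dreams_combine_scorers(event_list(), b2, "union")$onset, 5)
  expect_equal(nrow(dreams_combine_scorers(event_list(), b2, "intersection")), 0)
})
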
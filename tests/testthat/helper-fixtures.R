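# Shared fixtures: all built in code at test time.

# one Hann-windowed sigma burst planted in Gaussian noise
planted_burst <- function(fs = 200, total = 60, onset = 30, dur = 1,
                          freq = 13, amp = 40, noise_sd = 5, seed = 7) {
  set.seed(seed)
  n <- total * fs
  x <- rnorm(n, sd = noise_sd)
  i0 <- onset * fs + 1L
  len <- round(dur * fs)
  idx <- i0:(i0 + len - 1L)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
  x[idx] <- x[idx] + amp * sin(2 * pi * freq * (0:(len - 1)) / fs) * hann
  list(rec = recording(x, fs), gold = event_list(onset, dur),
       burst_interval = c(onset, onset + dur))
}

max_overlap_with <- function(ev, interval) {
  if (!nrow(ev)) return(0)
  max(vapply(seq_len(nrow(ev)), function(k)
    overlap_rate(interval, c(ev$onset[k], ev$onset[k] + ev$duration[k])), 0))
}

# synthetic subject in the dataset shape the protocol drivers expect
make_subject <- function(seed, duration = 360, ...) {
  sim <- simulate_psg(sim_config(duration = duration, seed = seed, ...))
  g <- sim$truth[, c("onset", "duration")]
  class(g) <- c("event_list", "data.frame")
  list(rec = sim$rec, stages = sim$stages, gold = g, sim = sim)
}

# maximum-bipartite-matching TP count via augmenting paths (oracle for the
# greedy matcher on small instances)
max_matching_tp <- function(adj) {
  ng <- nrow(adj); nd <- ncol(adj)
  match_d <- rep(0L, nd)
  try_aug <- function(g, seen) {
    for (d in which(adj[g, ])) {
      if (!seen[d]) {
        seen[d] <- TRUE
        if (match_d[d] == 0L || Recall(match_d[d], seen)) {
          match_d[d] <<- g
          return(TRUE)
        }
      }
    }
    FALSE
  }
  tp <- 0L
  for (g in seq_len(ng)) if (ng && nd && try_aug(g, rep(FALSE, nd))) tp <- tp + 1L
  tp
}

random_event_list <- function(n, span = 30, max_dur = 2) {
  if (n == 0) return(event_list())
  on <- sort(runif(n, 0, span))
  event_list(onset = on, duration = runif(n, 0.1, max_dur))
}
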
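# Pareto dominance over (FN, FP) and the SPEA2 optimizer used to trace
# each detector's false-negative / false-positive trade-off front.

#' Pareto dominance over (FN, FP)
#'
#' `a` dominates `b` iff `a` is no worse in both objectives and strictly
#' better in at least one.
#'
#' @param a,b numeric length-2 vectors `c(fn, fp)`.
#' @return logical.
#' @export
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

#' Nondominated filter
#'
#' Extracts the mutually nondominated subset of a set of (FN, FP) points.
#' Points duplicated in objective space are collapsed to their first
#' occurrence.
#'
#' @param fn,fp numeric vectors of objective values (false negatives /
#'   false positives), or `fn` may be a 2-column matrix.
#' @return list with `index` (positions of front members in the input) and
#'   `objectives` (2-column matrix).
#' @export
pareto_filter <- function(fn, fp = NULL) {
  if (is.null(fp)) { fp <- fn[, 2]; fn <- fn[, 1] }
  n <- length(fn)
  if (!n) return(list(index = integer(0),
                      objectives = cbind(fn = numeric(0), fp = numeric(0))))
  first <- !duplicated(cbind(fn, fp))
  idx <- which(first)
  f1 <- fn[idx]; f2 <- fp[idx]
  # among equal fn, only the lowest fp can survive
  o <- order(f1, f2)
  idx <- idx[o]; f1 <- f1[o]; f2 <- f2[o]
  keep_fn <- !duplicated(f1)
  idx <- idx[keep_fn]; f1 <- f1[keep_fn]; f2 <- f2[keep_fn]
  # fn strictly increasing; nondominated iff fp strictly decreasing so far
  best <- cummin(c(Inf, f2[-length(f2)]))
  nd <- f2 < best
  list(index = idx[nd], objectives = cbind(fn = f1[nd], fp = f2[nd]))
}

#' SPEA2 fitness assignment
#'
#' Strength `S(i)` is the number of pool members `i` dominates; raw fitness
#' `R(i)` sums the strengths of everything dominating `i` (nondominated
#' members get `R = 0`); density `D(i) = 1 / (sigma_k + 2)` where `sigma_k`
#' is the distance in (range-normalized) objective space to the k-th
#' nearest neighbor, `k = round(sqrt(pool size))`; fitness is `R + D`.
#'
#' @param obj numeric matrix (n x 2) of objective values.
#' @return data frame with columns `strength`, `raw`, `density`, `fitness`.
#' @export
spea2_fitness <- function(obj) {
  n <- nrow(obj)
  f1 <- obj[, 1]; f2 <- obj[, 2]
  le1 <- outer(f1, f1, `<=`); le2 <- outer(f2, f2, `<=`)
  lt <- outer(f1, f1, `<`) | outer(f2, f2, `<`)
  D <- le1 & le2 & lt                      # D[i,j]: i dominates j
  S <- rowSums(D)
  raw <- as.vector(crossprod(D, S))        # sum of strengths of dominators
  dens <- .spea2_density(obj)
  data.frame(strength = S, raw = raw, density = dens, fitness = raw + dens)
}

# normalize objectives by pool range (zero-range dimensions dropped) and
# return 1/(sigma_k + 2)
.spea2_density <- function(obj) {
  n <- nrow(obj)
  if (n == 1L) return(0.5)
  Z <- .normalize_objectives(obj)
  dm <- as.matrix(stats::dist(Z))
  k <- max(1L, min(n - 1L, round(sqrt(n))))
  sig <- apply(dm, 1, function(d) sort(d)[k + 1L])   # [1] is the self 0
  1 / (sig + 2)
}

.normalize_objectives <- function(obj) {
  rng <- apply(obj, 2, function(v) diff(range(v)))
  keep <- rng > 0
  if (!any(keep)) return(matrix(0, nrow(obj), 1))
  sweep(obj[, keep, drop = FALSE], 2, rng[keep], "/")
}

#' Control settings for the SPEA2 optimizer
#'
#' The per-detector defaults used for full training runs are population
#' sizes (100, 100, 100, 150, 120, 120, 170, 170, 270) and generation
#' counts (100, 100, 100, 250, 200, 200, 250, 250, 320) for d1..d9 (at
#' least ten times the parameter count, topped up to secure convergence);
#' see [spea2_defaults()]. Variation uses simulated-binary crossover and
#' polynomial mutation, standard real-coded settings.
#'
#' @param pop_size population size (>= 4).
#' @param max_gen number of generations (>= 1).
#' @param archive_size external archive size; defaults to `pop_size`.
#' @param seed RNG seed.
#' @param crossover_p,crossover_eta SBX probability and distribution index.
#' @param mutation_p per-gene mutation probability (`NA` = 1/n).
#' @param mutation_eta polynomial-mutation distribution index.
#' @return list of class `moea_config`.
#' @export
spea2_control <- function(pop_size = 40, max_gen = 40, archive_size = pop_size,
                          seed = 1L, crossover_p = 0.9, crossover_eta = 15,
                          mutation_p = NA, mutation_eta = 20) {
  stopifnot(pop_size >= 4, max_gen >= 1)
  structure(list(pop_size = pop_size, max_gen = max_gen,
                 archive_size = archive_size, seed = seed,
                 crossover_p = crossover_p, crossover_eta = crossover_eta,
                 mutation_p = mutation_p, mutation_eta = mutation_eta),
            class = "moea_config")
}

#' Published SPEA2 population/generation settings per detector
#'
#' @param id detector id `"d1"`..`"d9"`.
#' @param seed RNG seed passed through to [spea2_control()].
#' @return a [spea2_control()] list.
#' @export
spea2_defaults <- function(id, seed = 1L) {
  id <- match.arg(id, .DETECTOR_IDS)
  pops <- c(100, 100, 100, 150, 120, 120, 170, 170, 270)
  gens <- c(100, 100, 100, 250, 200, 200, 250, 250, 320)
  k <- match(id, .DETECTOR_IDS)
  spea2_control(pop_size = pops[k], max_gen = gens[k], seed = seed)
}

#' Optimize a two-objective evaluator with SPEA2
#'
#' Minimizes `F(x) = (FN(x), FP(x))` over a box: seeded uniform
#' initialization, per-generation fitness assignment on population plus
#' archive, environmental selection into the archive (nondominated first;
#' truncation by iterative nearest-neighbor removal with ties resolved by
#' the next-nearest distance; shortfall filled with the best dominated),
#' binary tournament mating selection, simulated-binary crossover and
#' polynomial mutation clamped to the bounds. Objective evaluations are
#' memoized on the parameter vector (12 significant digits). An evaluator
#' error yields sentinel objectives one above the largest finite count seen
#' and is logged via `warning()`.
#'
#' @param evaluate function mapping a parameter vector to `c(fn, fp)`.
#' @param lower,upper finite bound vectors.
#' @param control a [spea2_control()] list.
#' @return object of class `pareto_front`: nondominated archive with
#'   parameter matrix `X`, `objectives` (fn, fp), evaluation count, the
#'   control list, and the full memo table of evaluated points.
#' @export
spea2 <- function(evaluate, lower, upper, control = spea2_control()) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper >= lower))
  nvar <- length(lower)
  set.seed(control$seed)
  pm <- if (is.na(control$mutation_p)) 1 / nvar else control$mutation_p
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_x <- function(x) {
    key <- paste(signif(x, 12), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    obj <- tryCatch(as.numeric(evaluate(x)), error = function(e) {
      warning("evaluation failed (sentinel assigned): ", conditionMessage(e))
      c(NA_real_, NA_real_)
    })
    n_eval <<- n_eval + 1L
    memo[[key]] <- obj
    obj
  }
  X <- matrix(stats::runif(control$pop_size * nvar), ncol = nvar)
  X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
  arch_X <- matrix(numeric(0), ncol = nvar)
  arch_obj <- matrix(numeric(0), ncol = 2)
  for (gen in seq_len(control$max_gen)) {
    pop_obj <- t(apply(X, 1, eval_x))
    pool_X <- rbind(arch_X, X)
    pool_obj <- rbind(arch_obj, pop_obj)
    # replace failed evaluations by max finite count + 1 in each objective
    for (j in 1:2) {
      bad <- is.na(pool_obj[, j])
      if (any(bad))
        pool_obj[bad, j] <- max(c(pool_obj[!bad, j], 0)) + 1
    }
    fit <- spea2_fitness(pool_obj)
    nd <- which(fit$raw == 0)
    if (length(nd) > control$archive_size) {
      keep <- .spea2_truncate(pool_obj[nd, , drop = FALSE], control$archive_size)
      sel <- nd[keep]
    } else if (length(nd) < control$archive_size) {
      dom <- setdiff(order(fit$fitness), nd)
      sel <- c(nd, dom[seq_len(min(length(dom), control$archive_size - length(nd)))])
    } else sel <- nd
    arch_X <- pool_X[sel, , drop = FALSE]
    arch_obj <- pool_obj[sel, , drop = FALSE]
    arch_fit <- fit$fitness[sel]
    if (gen == control$max_gen) break
    # binary tournament on fitness (lower is better)
    na <- nrow(arch_X)
    pick <- function() {
      i <- sample.int(na, 1L); j <- sample.int(na, 1L)
      if (arch_fit[i] <= arch_fit[j]) i else j
    }
    child <- matrix(0, control$pop_size, nvar)
    for (i in seq(1, control$pop_size, by = 2)) {
      p1 <- arch_X[pick(), ]; p2 <- arch_X[pick(), ]
      cs <- .sbx(p1, p2, lower, upper, control$crossover_p, control$crossover_eta)
      child[i, ] <- .poly_mutate(cs[[1]], lower, upper, pm, control$mutation_eta)
      if (i + 1 <= control$pop_size)
        child[i + 1, ] <- .poly_mutate(cs[[2]], lower, upper, pm, control$mutation_eta)
    }
    X <- child
  }
  front <- pareto_filter(arch_obj)
  structure(list(X = arch_X[front$index, , drop = FALSE],
                 objectives = front$objectives,
                 archive_X = arch_X, archive_objectives = arch_obj,
                 evaluations = n_eval, control = control, memo = memo),
            class = "pareto_front")
}

# iterative SPEA2 archive truncation: repeatedly drop the member with the
# lexicographically smallest vector of sorted neighbor distances
.spea2_truncate <- function(obj, target) {
  alive <- seq_len(nrow(obj))
  Z <- .normalize_objectives(obj)
  dm <- as.matrix(stats::dist(Z))
  while (length(alive) > target) {
    sub <- dm[alive, alive, drop = FALSE]
    sorted <- apply(sub, 1, function(d) sort(d))  # includes self 0
    worst <- 1L
    for (i in seq_along(alive)[-1]) {
      cmp <- sorted[, i] - sorted[, worst]
      nz <- which(cmp != 0)
      if (length(nz) && cmp[nz[1]] < 0) worst <- i
    }
    alive <- alive[-worst]
  }
  alive
}

.sbx <- function(p1, p2, lower, upper, pc, eta) {
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < pc) {
    for (g in seq_along(p1)) {
      if (stats::runif(1) > 0.5 || abs(p1[g] - p2[g]) < 1e-14) next
      u <- stats::runif(1)
      bq <- if (u <= 0.5) (2 * u)^(1 / (eta + 1)) else (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[g] <- 0.5 * ((1 + bq) * p1[g] + (1 - bq) * p2[g])
      c2[g] <- 0.5 * ((1 - bq) * p1[g] + (1 + bq) * p2[g])
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

.poly_mutate <- function(x, lower, upper, pm, eta) {
  for (g in seq_along(x)) {
    if (stats::runif(1) >= pm) next
    rng <- upper[g] - lower[g]
    if (rng <= 0) next
    u <- stats::runif(1)
    if (u <= 0.5) {
      d1 <- (x[g] - lower[g]) / rng
      dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1
    } else {
      d2 <- (upper[g] - x[g]) / rng
      dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
    }
    x[g] <- x[g] + dq * rng
  }
  pmin(pmax(x, lower), upper)
}

#' PR- and F1-curves derived from a Pareto front
#'
#' For each front member with objectives (FN, FP) against `n_gold` gold
#' events, `TP = n_gold - FN` and precision/recall/F follow. Returns the
#' curves sorted by recall and the maximal-F operating point (ties by lower
#' FP).
#'
#' @param front a `pareto_front` object, or a list with an `objectives`
#'   matrix (and optionally `X`).
#' @param n_gold number of gold-standard events (>= every member's FN).
#' @param beta F-score weight.
#' @return list with `curve` (data frame fn, fp, precision, recall,
#'   f_score sorted by recall) and `best` (row index into the front,
#'   parameters if available, and its metrics).
#' @export
front_metrics <- function(front, n_gold, beta = 1) {
  obj <- front$objectives
  if (is.null(obj) || nrow(obj) == 0) stop("empty Pareto front")
  if (any(obj[, 1] > n_gold)) stop("n_gold smaller than a member's FN count")
  tp <- n_gold - obj[, 1]
  prf <- t(vapply(seq_len(nrow(obj)), function(i)
    prf_metrics(list(tp = tp[i], fn = obj[i, 1], fp = obj[i, 2]), beta),
    c(precision = 0, recall = 0, f_score = 0)))
  curve <- data.frame(fn = obj[, 1], fp = obj[, 2], prf)
  best_i <- order(-curve$f_score, curve$fp)[1]
  best <- list(index = best_i,
               x = if (!is.null(front$X)) front$X[best_i, ] else NULL,
               precision = curve$precision[best_i], recall = curve$recall[best_i],
               f_score = curve$f_score[best_i],
               fn = curve$fn[best_i], fp = curve$fp[best_i])
  list(curve = curve[order(curve$recall), ], best = best)
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d nondominated solutions (%d evaluations)\n",
              nrow(x$objectives), x$evaluations))
  cat(sprintf("  FN range %g-%g, FP range %g-%g\n",
              min(x$objectives[, 1]), max(x$objectives[, 1]),
              min(x$objectives[, 2]), max(x$objectives[, 2])))
  invisible(x)
}

#' @export
summary.pareto_front <- function(object, n_gold = NULL, ...) {
  cat(sprintf("SPEA2 Pareto front: %d members, %d parameter(s), %d evaluations\n",
              nrow(object$objectives), ncol(object$X), object$evaluations))
  if (!is.null(n_gold)) {
    fm <- front_metrics(object, n_gold)
    cat(sprintf("max-F1 operating point: P=%.3f R=%.3f F1=%.3f (FN=%g FP=%g)\n",
                fm$best$precision, fm$best$recall, fm$best$f_score,
                fm$best$fn, fm$best$fp))
    invisible(fm)
  } else invisible(object)
}

#' @export
coef.pareto_front <- function(object, ...) object$X

#' @export
plot.pareto_front <- function(x, ...) {
  graphics::plot(x$objectives[, 2], x$objectives[, 1], xlab = "FP", ylab = "FN",
                 pch = 19, col = "forestgreen",
                 main = "Pareto front: FN vs FP", ...)
  o <- order(x$objectives[, 2])
  graphics::lines(x$objectives[o, 2], x$objectives[o, 1], col = "grey60")
  invisible(x)
}
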
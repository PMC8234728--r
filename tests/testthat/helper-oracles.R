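# Independent oracles, deliberately implemented with different algorithms
# than the package uses.

dual_obj <- function(a, K) drop(crossprod(a, K %*% a)) - sum(a * diag(K))

# Euclidean projection onto {a : sum(a) = 1, 0 <= a_i <= C} by bisection on
# the shift of the clipped vector.
project_simplex_box <- function(v, C) {
  lo <- min(v) - 1; hi <- max(v)
  for (i in 1:40) {
    t <- (lo + hi) / 2
    s <- sum(pmin(pmax(v - t, 0), C))
    if (s > 1) lo <- t else hi <- t
  }
  pmin(pmax(v - (lo + hi) / 2, 0), C)
}

# Projected-gradient minimizer of the ball dual, restarted from random
# feasible points.  Convex objective, so this converges to the global
# minimum; it shares no code path with the package's pairwise solver.
oracle_dual_min <- function(K, C, restarts = 10, iters = 1500) {
  n <- nrow(K)
  obj <- function(a) drop(crossprod(a, K %*% a)) - sum(a * diag(K))
  step <- 1 / (2 * max(abs(eigen(K, symmetric = TRUE,
                                 only.values = TRUE)$values)) + 1e-12)
  best <- Inf
  for (r in seq_len(restarts)) {
    a <- project_simplex_box(stats::rgamma(n, 1), C)
    for (k in seq_len(iters)) {
      g <- 2 * drop(K %*% a) - diag(K)
      a <- project_simplex_box(a - step * g, C)
    }
    best <- min(best, obj(a))
  }
  best
}

# AUC as an explicit Mann-Whitney pairwise count: wins + half ties over all
# (DE, nonDE) pairs.
oracle_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  sp <- scores[truth]; sn <- scores[!truth]
  cmp <- outer(sp, sn, "-")
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(sp) * length(sn))
}

# small count-like training matrix for fixture fits
fixture_counts <- function(n, dim = 2, lambda = 50, seed = 1) {
  set.seed(seed)
  matrix(stats::rpois(n * dim, lambda), n, dim)
}
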
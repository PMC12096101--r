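# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: the belief and objective are recomputed
# from first principles.

# Build an agents data frame without going through init_agents().
agents_df <- function(x, y, mu) {
  data.frame(x = as.integer(x), y = as.numeric(y), mu = as.numeric(mu))
}

# Brute-force myopic best request: for every candidate x recompute the
# expected helper count by summing per-pair helping probabilities, then
# the expected own-clearing payoff, and enumerate.
oracle_best_request <- function(i, agents, history, forest_cells, h, c) {
  N <- nrow(agents)
  cap <- floor(forest_cells / N)
  if (cap <= 0) return(0L)
  best_x <- 0L
  best_g <- -Inf
  for (x in 0:cap) {
    ntilde <- 0
    for (j in seq_len(N)) {
      if (j == i) next
      ntilde <- ntilde +
        (1 - agents$mu[j]) * history[i, j] +
        agents$mu[j] * as.numeric(x <= agents$y[j])
    }
    party <- h * (1 + ntilde)
    m <- min(x, party)
    g <- m - c * m / party
    if (g > best_g + 1e-12) {
      best_g <- g
      best_x <- x
    }
  }
  best_x
}

# Bisection root of (1 - f) * p(f) = h * nu on the declining branch
# f in [F, 1]; independent of the closed form under test.
oracle_f_star_bisect <- function(p1, pmax, F, hnu, iters = 200) {
  pf <- function(f) (pmax - p1 * F - (pmax - p1) * f) / (1 - F)
  g <- function(f) (1 - f) * pf(f) - hnu
  lo <- F
  hi <- 1
  if (g(lo) < 0) return(NA_real_)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Verify the per-round cell-conservation identity on a recorded series.
conservation_ok <- function(run) {
  s <- run$series
  prev <- c(run$initial_forest_cells, s$forest_cells[-nrow(s)])
  all(s$forest_cells == prev - s$harvest_total + s$delta_f_plus - s$shock_loss)
}

# Small fast configuration for engine-level tests.
small_params <- function(...) {
  args <- utils::modifyList(list(N = 4L, L = 12L, T = 40L, seed = 1L),
                            list(...))
  do.call(swidden_params, args)
}
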
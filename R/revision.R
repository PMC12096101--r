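#' Expected number of helpers for a candidate request
#'
#' The belief an agent forms when revising its clearing request: the
#' expected helper count is the sum, over all other agents j, of
#' their helping probability
#' `(1 - mu_j) * history[i, j] + mu_j * [x <= y_j]`, using j's current
#' (previous-round) threshold and the history of help i previously
#' gave j (the reciprocity j owes i). As `x` grows the indicator terms
#' can only switch off, so the belief is a non-increasing step
#' function of `x`.
#'
#' @param i focal agent index.
#' @param x candidate request(s), integer >= 0; vectorized.
#' @param agents a `swidden_agents` data frame.
#' @param history the `N x N` helping-history matrix.
#' @return Expected helper count(s) in \[0, N-1\].
#' @examples
#' ag <- data.frame(x = c(1, 1, 1), y = c(0, 2, 5), mu = 0.75)
#' expected_helpers(1, c(2, 4, 6), ag, matrix(0, 3, 3))
#' @export
expected_helpers <- function(i, x, agents, history) {
  others <- setdiff(seq_len(nrow(agents)), i)
  mu_o <- agents$mu[others]
  y_o <- agents$y[others]
  recip <- sum((1 - mu_o) * history[i, others])
  vapply(x, function(xx) recip + sum(mu_o[y_o >= xx]), numeric(1))
}

# Expected own-clearing payoff for candidate request x given belief
# Ntilde: harvest min(x, h(1+Ntilde)) minus the agent's own variable
# clearing cost. Helping-others costs do not depend on own x.
#' @keywords internal
request_objective <- function(x, Ntilde, params) {
  mh <- params$h * (1 + Ntilde)
  m <- pmin(x, mh)
  m - params$c * m / mh
}

#' Myopic best clearing request
#'
#' Enumerates integer candidate requests `0..floor(forest_cells/N)`
#' (the per-agent clearing cap) and returns the one maximizing the
#' expected own-clearing payoff
#' `m(x) - c * m(x) / (h * (1 + Ntilde(x)))` with
#' `m(x) = min(x, h * (1 + Ntilde(x)))`, where `Ntilde(x)` is the
#' real-valued expected helper count from [expected_helpers()]. Ties
#' break towards the smallest maximizer.
#'
#' @inheritParams expected_helpers
#' @param forest_cells standing forest cell count.
#' @param params a [swidden_params()].
#' @return The optimal integer request.
#' @export
myopic_best_request <- function(i, agents, history, forest_cells, params) {
  cap <- as.integer(forest_cells) %/% params$N
  if (cap <= 0L) return(0L)
  xs <- 0:cap
  g <- request_objective(xs, expected_helpers(i, xs, agents, history), params)
  xs[which.max(g)]
}

#' Logit imitation distribution over role models
#'
#' Probability of copying agent j's sanctioning threshold is
#' proportional to `exp(lambda * payoff_j)`, normalized over all N
#' agents (self included; copying oneself leaves the threshold
#' unchanged). `lambda = 0` copies uniformly at random; large `lambda`
#' concentrates on the highest earner. Computed with a max-shift for
#' numerical stability.
#'
#' @param payoff_vec previous-round payoffs.
#' @param lambda imitation precision, >= 0.
#' @return Probability vector summing to 1.
#' @examples
#' imitation_distribution(c(1, 0), lambda = 10)
#' @export
imitation_distribution <- function(payoff_vec, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  w <- exp(lambda * (payoff_vec - max(payoff_vec)))
  w / sum(w)
}

#' Random threshold innovation
#'
#' Local mutation of the sanctioning threshold: a Gaussian step with
#' s.d. `innov_sd` (default half a clearing-request unit) is added to
#' the agent's current threshold, clamped to the admissible support
#' `[0, h*N]`. Local innovation supplies gradual variation for
#' payoff-based imitation to select on, letting the social
#' sanctioning norm drift (the cycling of the norm in the
#' high-intensity regime) without re-injecting extreme thresholds.
#' Consumes one normal deviate from the R RNG stream.
#'
#' @param params a [swidden_params()].
#' @param y the agent's current threshold.
#' @return Numeric threshold in `[0, h*N]`.
#' @export
innovate_threshold <- function(params, y) {
  ymax <- params$h * params$N
  min(max(y + stats::rnorm(1L, 0, params$innov_sd), 0), ymax)
}

# Draw a role-model index from the logit distribution using one
# uniform: inverse-CDF walk over the cumulative probabilities.
#' @keywords internal
draw_imitation_target <- function(payoff_vec, lambda) {
  p <- imitation_distribution(payoff_vec, lambda)
  u <- stats::runif(1L)
  j <- findInterval(u, cumsum(p)) + 1L
  min(j, length(p))
}

#' Simultaneous strategy revision
#'
#' Each agent independently gets the chance to revise: with
#' probability `nu0` the clearing request is replaced by
#' [myopic_best_request()]; with probability `nu1` the threshold is
#' replaced by an imitation draw over previous-round payoffs; with
#' probability `nu2` it is replaced by [innovate_threshold()]
#' (imitation and innovation are mutually exclusive). All revisions
#' evaluate against the previous round's thresholds, history and
#' payoffs (simultaneous revision). In round 1 there are no previous
#' payoffs, so threshold revision is skipped and no threshold-revision
#' draws are consumed.
#'
#' Draw order per agent: one uniform for the request-revision event,
#' then (from round 2) one uniform for the threshold event and, if
#' imitating or innovating, one more uniform.
#'
#' @param agents a `swidden_agents` data frame.
#' @param history the helping-history matrix.
#' @param payoffs_prev previous-round payoff vector.
#' @param forest_cells standing forest cell count at the round start.
#' @param params a [swidden_params()].
#' @param t round index (1-based).
#' @return The revised agents data frame.
#' @export
revise_agents <- function(agents, history, payoffs_prev, forest_cells,
                          params, t) {
  N <- nrow(agents)
  new_x <- agents$x
  new_y <- agents$y
  for (i in seq_len(N)) {
    if (stats::runif(1L) < params$nu0) {
      new_x[i] <- myopic_best_request(i, agents, history, forest_cells, params)
    }
    if (t > 1L) {
      u <- stats::runif(1L)
      if (u < params$nu1) {
        j <- draw_imitation_target(payoffs_prev, params$lambda)
        new_y[i] <- agents$y[j]
      } else if (u < params$nu1 + params$nu2) {
        new_y[i] <- innovate_threshold(params, agents$y[i])
      }
    }
  }
  agents$x <- as.integer(new_x)
  agents$y <- new_y
  agents
}
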
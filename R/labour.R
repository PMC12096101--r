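#' Probability that one agent helps another
#'
#' Mixes direct reciprocity with normative reasoning: agent `i` helps
#' requester `j` with probability
#' `(1 - mu_i) * h_ji + mu_i * [x_j <= y_i]`, where `h_ji` is the
#' exponentially weighted history of help `j` previously gave `i`
#' (the debt `i` owes `j`) and the indicator implements sanctioning:
#' requests above `i`'s acceptability threshold are refused on
#' normative grounds.
#'
#' @param x_j the requester's clearing request.
#' @param y_i the potential helper's sanctioning threshold.
#' @param h_ji helping history of `j` towards `i`, in \[0,1\].
#' @param mu_i the helper's normative-reasoning weight, in \[0,1\].
#' @return Helping probability in \[0,1\]; vectorized.
#' @examples
#' help_probability(x_j = 4, y_i = 2, h_ji = 0.4, mu_i = 0.75)  # 0.1
#' @export
help_probability <- function(x_j, y_i, h_ji, mu_i) {
  (1 - mu_i) * h_ji + mu_i * as.numeric(x_j <= y_i)
}

#' Sample one round's helping decisions
#'
#' Each ordered pair (i, j), i != j, yields an independent Bernoulli
#' draw with probability [help_probability()] evaluated at the
#' requester's current request `x_j`, the helper's threshold `y_i`,
#' the helper's weight `mu_i` and history entry `history[j, i]` (help
#' flowing from j to i in the past). Consumes `N^2` uniforms in
#' column-major order (diagonal draws discarded) from the current R
#' RNG stream.
#'
#' @param agents a `swidden_agents` data frame (columns `x`, `y`, `mu`).
#' @param history the `N x N` helping-history matrix; entry (i, j) is
#'   the history of help given by i to j.
#' @return An `N x N` binary integer matrix with zero diagonal; entry
#'   (i, j) = 1 iff i helps j this round. Helper counts are column
#'   sums.
#' @export
sample_help_matrix <- function(agents, history) {
  N <- nrow(agents)
  acc <- outer(agents$y, agents$x, ">=")          # [i,j]: x_j <= y_i
  q <- (1 - agents$mu) * t(history) + agents$mu * acc
  u <- matrix(stats::runif(N * N), N, N)
  d <- (u < q)
  diag(d) <- FALSE
  storage.mode(d) <- "integer"
  d
}

#' Realized per-agent harvests
#'
#' An agent clears `min(x_i, h * (1 + N_i+), floor(forest_cells / N))`
#' cells: the request, capped by the work party's clearing capacity
#' (the requester plus each helper clears `h` cells) and by the
#' per-agent share of the standing forest. The last cap guarantees
#' total demand never exceeds the forest
#' (`N * floor(forest_cells / N) <= forest_cells`).
#'
#' @param requests integer vector of clearing requests.
#' @param helper_counts integer vector of helpers received.
#' @param forest_cells standing forest cell count at the round start.
#' @param params a [swidden_params()].
#' @return Integer vector of realized harvests.
#' @export
harvests <- function(requests, helper_counts, forest_cells, params) {
  cap <- as.integer(forest_cells) %/% params$N
  as.integer(pmin(requests, params$h * (1L + helper_counts), cap))
}

#' Per-agent total helping and clearing costs
#'
#' Participating in the clearing of agent `j`'s field costs
#' `c0 * [i != j] + c * x_a_j / (h * (1 + N_j+))`: a fixed cost for
#' helping someone else plus a variable cost proportional to the work
#' actually done, which reaches its maximum `c` when the party clears
#' `h` cells per participant. The requester always participates in
#' their own clearing (variable cost, no fixed cost) whenever they
#' harvest anything.
#'
#' @param help_matrix binary matrix from [sample_help_matrix()].
#' @param harvest_vec realized harvests from [harvests()].
#' @param helper_counts helpers received per agent (column sums of
#'   `help_matrix`).
#' @param params a [swidden_params()].
#' @return Numeric vector of total costs `C_i`.
#' @export
helping_costs <- function(help_matrix, harvest_vec, helper_counts, params) {
  N <- length(harvest_vec)
  share <- params$c * harvest_vec / (params$h * (1 + helper_counts))
  per_pair <- help_matrix * matrix(params$c0 + share, N, N, byrow = TRUE)
  rowSums(per_pair) + share * (harvest_vec > 0)
}

#' Per-agent payoffs
#'
#' Material payoff: harvest minus total costs.
#'
#' @param harvest_vec realized harvests.
#' @param costs_vec total costs from [helping_costs()].
#' @return Numeric payoff vector.
#' @export
payoffs <- function(harvest_vec, costs_vec) {
  harvest_vec - costs_vec
}

#' Update the helping-history matrix
#'
#' Exponentially weighted update: entries move towards 1 where help
#' was given this round and towards 0 where it was not, with weight
#' `alpha` on the current round. Values stay in \[0,1\] and the
#' diagonal stays 0.
#'
#' @param history current `N x N` history matrix.
#' @param help_matrix this round's binary decisions.
#' @param alpha history-update weight in \[0,1\].
#' @return Updated history matrix.
#' @examples
#' update_history(matrix(0.5, 2, 2) - diag(0.5, 2), diag(0L, 2), 0.3)
#' @export
update_history <- function(history, help_matrix, alpha) {
  (1 - alpha) * history + alpha * help_matrix
}

#' Export a helping matrix or history as an edge list
#'
#' @param m an `N x N` matrix (binary decisions or history weights).
#' @param drop_zero drop zero-weight edges (default TRUE).
#' @return Data frame with columns `i`, `j`, `value`, diagonal
#'   excluded, suitable for network analysis or CSV export.
#' @export
matrix_to_edgelist <- function(m, drop_zero = TRUE) {
  N <- nrow(m)
  df <- data.frame(i = rep(seq_len(N), N),
                   j = rep(seq_len(N), each = N),
                   value = as.vector(m))
  df <- df[df$i != df$j, ]
  if (drop_zero) df <- df[df$value != 0, ]
  rownames(df) <- NULL
  df
}
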
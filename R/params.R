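#' Model parameters for the swidden labour-exchange simulation
#'
#' Constructs and validates the full parameter set of the coupled
#' social-ecological model. Called with no arguments it returns the
#' baseline configuration: `N = 40` households on a `120 x 120` forest
#' lattice simulated for `T = 1000` rounds, regeneration probabilities
#' `p0 = 0.01`, `p1 = 0.06`, `pmax = 0.12` peaking at local forest
#' fraction `F = 0.5`, clearing capacity `h = 3` cells per worker,
#' helping costs `c0 = 0.1` (fixed) and `c = 0.2` (maximum variable),
#' history weight `alpha = 0.3`, normative-reasoning weight
#' `mu = 0.75`, imitation precision `lambda = 10` and revision
#' probabilities `nu0 = nu1 = 0.2`, `nu2 = 0.1`, with a fully forested
#' initial grid (`f0 = 1`) and all extensions (shocks, revegetation
#' lag, heterogeneous `mu`) switched off.
#'
#' @param N number of agents (households), integer >= 1.
#' @param L side length of the square forest lattice (cells).
#' @param T number of simulated rounds.
#' @param p0 regeneration probability of an empty cell whose
#'   neighbourhood holds no forest.
#' @param p1 regeneration probability at full local forest density.
#' @param pmax peak regeneration probability, attained at local forest
#'   fraction `F`; must satisfy `pmax >= max(p0, p1)`.
#' @param F local forest fraction at which regeneration peaks, in (0,1).
#' @param h cells clearable per worker (the requester counts as one
#'   worker), integer >= 1.
#' @param c0 fixed cost incurred by helping another agent.
#' @param c maximum variable clearing cost per participant (paid in
#'   full when a work party clears `h` cells per participant).
#' @param alpha weight of the current round in the exponentially
#'   weighted helping history, in \[0,1\].
#' @param mu relative importance of normative reasoning (vs direct
#'   reciprocity) in helping decisions, in \[0,1\]. With
#'   `sigma_mu > 0` this is the population mean of the per-agent
#'   weights.
#' @param sigma_mu s.d. of per-agent normative-reasoning weights;
#'   draws from Normal(`mu`, `sigma_mu`) are clipped to \[0,1\].
#'   `sigma_mu = 0` gives every agent exactly `mu`.
#' @param lambda precision of logit payoff-based imitation; 0 is
#'   uniform copying, large values copy the best performer.
#' @param nu0 per-round probability an agent revises its clearing
#'   request by myopic optimization.
#' @param nu1 per-round probability an agent imitates another's
#'   sanctioning threshold.
#' @param nu2 per-round probability an agent innovates (locally
#'   perturbs) its sanctioning threshold; `nu1 + nu2 <= 1`.
#' @param innov_sd s.d. of the Gaussian innovation step applied to the
#'   sanctioning threshold (in threshold units, i.e. cells); half a
#'   clearing-request unit by default, so innovation supplies gradual
#'   variation for imitation to select on.
#' @param l revegetation time lag: a newly emptied cell is ineligible
#'   for regeneration for `l` regeneration steps, integer >= 0.
#' @param p_sh per-round probability of an external shock (0 disables
#'   shocks).
#' @param f_sh shock severity: fraction of the `L^2` cells destroyed
#'   when a shock fires, in \[0,1\].
#' @param shock_start first round at which shocks may occur; `NA`
#'   resolves to `floor(T/2) + 1` (shocks in the second half of the
#'   run) when shocks are enabled.
#' @param f0 initial forest fraction, default 1 (fully forested).
#' @param seed RNG seed used by [run_simulation()].
#' @param neighborhood neighbourhood convention for local forest
#'   density: `"moore"` (8 surrounding cells, the default) or
#'   `"von_neumann"` (4 orthogonal cells). The focal cell is excluded.
#' @param boundary boundary convention: `"torus"` (periodic, the
#'   default) or `"clip"` (edge cells use their truncated
#'   neighbourhood).
#'
#' @return An object of class `swidden_params`: a named list with the
#'   fields above (integer-valued fields stored as integers).
#' @seealso [update_params()], [init_state()], [run_simulation()]
#' @examples
#' p <- swidden_params()
#' p$N; p$L; p$mu
#' small <- swidden_params(N = 5, L = 20, T = 50, seed = 1)
#' @export
swidden_params <- function(N = 40L, L = 120L, T = 1000L,
                           p0 = 0.01, p1 = 0.06, pmax = 0.12, F = 0.5,
                           h = 3L, c0 = 0.1, c = 0.2, alpha = 0.3,
                           mu = 0.75, sigma_mu = 0, lambda = 10,
                           nu0 = 0.2, nu1 = 0.2, nu2 = 0.1,
                           innov_sd = 0.5,
                           l = 0L, p_sh = 0, f_sh = 0,
                           shock_start = NA_integer_,
                           f0 = 1, seed = 1L,
                           neighborhood = c("moore", "von_neumann"),
                           boundary = c("torus", "clip")) {
  neighborhood <- match.arg(neighborhood)
  boundary <- match.arg(boundary)
  p <- list(
    N = as.integer(N), L = as.integer(L), T = as.integer(T),
    p0 = as.numeric(p0), p1 = as.numeric(p1), pmax = as.numeric(pmax),
    F = as.numeric(F), h = as.integer(h),
    c0 = as.numeric(c0), c = as.numeric(c), alpha = as.numeric(alpha),
    mu = as.numeric(mu), sigma_mu = as.numeric(sigma_mu),
    lambda = as.numeric(lambda),
    nu0 = as.numeric(nu0), nu1 = as.numeric(nu1), nu2 = as.numeric(nu2),
    innov_sd = as.numeric(innov_sd),
    l = as.integer(l), p_sh = as.numeric(p_sh), f_sh = as.numeric(f_sh),
    shock_start = as.integer(shock_start),
    f0 = as.numeric(f0), seed = as.integer(seed),
    neighborhood = neighborhood, boundary = boundary
  )
  class(p) <- "swidden_params"
  validate_params(p)
  p
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced and the
#' result re-validated. Unknown field names are an error.
#'
#' @param params a [swidden_params()] object.
#' @param ... `name = value` replacements.
#' @return A validated `swidden_params` object.
#' @examples
#' update_params(swidden_params(), mu = 0.4, seed = 7)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "swidden_params"))
  repl <- list(...)
  if (length(repl)) {
    if (is.null(names(repl)) || any(!nzchar(names(repl))))
      stop("replacements must be named")
    unknown <- setdiff(names(repl), names(unclass(params)))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    int_fields <- c("N", "L", "T", "h", "l", "shock_start", "seed")
    for (nm in names(repl)) {
      v <- repl[[nm]]
      params[[nm]] <- if (nm %in% int_fields) as.integer(v)
                      else if (nm %in% c("neighborhood", "boundary")) as.character(v)
                      else as.numeric(v)
    }
  }
  validate_params(params)
  params
}

#' @keywords internal
validate_params <- function(p) {
  fail <- function(msg) stop("invalid parameters: ", msg, call. = FALSE)
  chk_prob <- function(nm) {
    v <- p[[nm]]
    if (!is.finite(v) || v < 0 || v > 1) fail(paste0(nm, " must lie in [0,1]"))
  }
  if (is.na(p$N) || p$N < 1L) fail("N must be an integer >= 1")
  if (is.na(p$L) || p$L < 1L) fail("L must be an integer >= 1")
  if (is.na(p$T) || p$T < 0L) fail("T must be an integer >= 0")
  if (is.na(p$h) || p$h < 1L) fail("h must be an integer >= 1")
  if (is.na(p$l) || p$l < 0L) fail("l must be an integer >= 0")
  for (nm in c("p0", "p1", "pmax", "alpha", "mu", "nu0", "nu1", "nu2",
               "p_sh", "f_sh", "f0")) chk_prob(nm)
  if (p$pmax < max(p$p0, p$p1))
    fail("pmax must be >= max(p0, p1) (regeneration peaks at F)")
  if (!is.finite(p$F) || p$F <= 0 || p$F >= 1) fail("F must lie in (0,1)")
  if (p$nu1 + p$nu2 > 1 + 1e-12) fail("nu1 + nu2 <= 1 violated")
  if (!is.finite(p$lambda) || p$lambda < 0) fail("lambda must be >= 0")
  if (!is.finite(p$innov_sd) || p$innov_sd < 0) fail("innov_sd must be >= 0")
  if (!is.finite(p$sigma_mu) || p$sigma_mu < 0) fail("sigma_mu must be >= 0")
  if (!is.na(p$shock_start) && p$shock_start < 1L)
    fail("shock_start must be >= 1")
  if (!p$neighborhood %in% c("moore", "von_neumann")) fail("unknown neighborhood")
  if (!p$boundary %in% c("torus", "clip")) fail("unknown boundary")
  invisible(p)
}

# First round in which shocks may fire (resolves the NA default).
#' @keywords internal
resolve_shock_start <- function(params) {
  if (!is.na(params$shock_start)) return(params$shock_start)
  as.integer(params$T %/% 2L + 1L)
}

#' @export
print.swidden_params <- function(x, ...) {
  cat("swidden model parameters\n")
  cat(sprintf("  agents N=%d, grid L=%d, rounds T=%d\n", x$N, x$L, x$T))
  cat(sprintf("  regeneration p0=%g p1=%g pmax=%g F=%g, lag l=%d\n",
              x$p0, x$p1, x$pmax, x$F, x$l))
  cat(sprintf("  labour h=%d, costs c0=%g c=%g, history alpha=%g\n",
              x$h, x$c0, x$c, x$alpha))
  cat(sprintf("  social mu=%g (sigma_mu=%g), lambda=%g, nu0=%g nu1=%g nu2=%g\n",
              x$mu, x$sigma_mu, x$lambda, x$nu0, x$nu1, x$nu2))
  if (x$p_sh > 0)
    cat(sprintf("  shocks p_sh=%g f_sh=%g from round %d\n",
                x$p_sh, x$f_sh, resolve_shock_start(x)))
  cat(sprintf("  init f0=%g, seed=%d, %s/%s\n",
              x$f0, x$seed, x$neighborhood, x$boundary))
  invisible(x)
}

#' Initialize the agent population
#'
#' Draws each agent's initial clearing request uniformly from the
#' integers 1..5 and its sanctioning (acceptability) threshold
#' uniformly from 0..`h*N`. With `sigma_mu > 0` each agent receives an
#' individual normative-reasoning weight drawn from
#' Normal(`mu`, `sigma_mu`) clipped to \[0,1\]; otherwise every agent
#' gets exactly `mu`. Uses the current R RNG stream.
#'
#' @param params a [swidden_params()] object.
#' @return A data frame of class `swidden_agents` with integer column
#'   `x` (clearing request) and numeric columns `y` (sanctioning
#'   threshold; initialized on integers, later perturbed continuously
#'   by innovation) and `mu`.
#' @examples
#' set.seed(1)
#' init_agents(swidden_params(N = 5))
#' @export
init_agents <- function(params) {
  validate_params(params)
  N <- params$N
  ymax <- params$h * N
  x <- sample.int(5L, N, replace = TRUE)
  y <- sample.int(ymax + 1L, N, replace = TRUE) - 1L
  mu <- if (params$sigma_mu > 0) {
    pmin(pmax(stats::rnorm(N, params$mu, params$sigma_mu), 0), 1)
  } else {
    rep(params$mu, N)
  }
  agents <- data.frame(x = as.integer(x), y = as.numeric(y), mu = mu)
  class(agents) <- c("swidden_agents", "data.frame")
  agents
}

#' Initialize the full simulation state
#'
#' Builds the forest grid (fraction `f0` of cells forested; all cells
#' for the default `f0 = 1`, otherwise a uniformly random subset of
#' exactly `round(f0 * L^2)` cells), the agent population via
#' [init_agents()], and an all-zero helping-history matrix. Uses the
#' current R RNG stream; [run_simulation()] seeds it from
#' `params$seed`.
#'
#' @param params a [swidden_params()] object.
#' @return A list with components `grid` (a [forest_grid()]), `agents`
#'   and `history` (an `N x N` numeric matrix with zero diagonal).
#' @export
init_state <- function(params) {
  validate_params(params)
  L <- params$L
  states <- matrix(1L, L, L)
  if (params$f0 < 1) {
    states[] <- 0L
    n_forest <- as.integer(round(params$f0 * L * L))
    if (n_forest > 0) states[sample.int(L * L, n_forest)] <- 1L
  }
  grid <- forest_grid(states)
  agents <- init_agents(params)
  history <- matrix(0, params$N, params$N)
  list(grid = grid, agents = agents, history = history)
}

#' Serialize parameters to a flat named list / JSON
#'
#' Every field keeps its canonical name, so configurations round-trip
#' through JSON config files unchanged.
#'
#' @param params a [swidden_params()] object.
#' @param path optional file path; when given, JSON is written there.
#' @return Invisibly (when writing) or visibly the flat named list.
#' @seealso [params_from_json()], [load_config()]
#' @export
params_to_json <- function(params, path = NULL) {
  validate_params(params)
  x <- unclass(params)
  if (is.null(path)) return(x)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(x)
}

#' Read parameters from a JSON config file or flat list
#'
#' Unknown keys are rejected with the offending name; values are
#' validated against the model constraints.
#'
#' @param x a file path to a JSON document or a named list.
#' @return A validated `swidden_params` object.
#' @export
params_from_json <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (!is.list(x)) stop("expected a named list or a JSON file path")
  x <- x[!vapply(x, is.null, logical(1))]
  defaults <- swidden_params()
  unknown <- setdiff(names(x), names(unclass(defaults)))
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  if (length(x)) do.call(update_params, c(list(defaults), x)) else defaults
}
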
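#' One full model round (reference implementation)
#'
#' Executes the canonical round order: (1) simultaneous strategy
#' revision against previous-round state; (2) helping decisions;
#' (3) helper counts and harvests, capped by the round-start forest
#' count; (4) clearing of harvested cells; (5) costs and payoffs;
#' (6) history update; (7) synchronous regeneration (new biomass
#' `delta_f_plus`); (8) external shock, if enabled and `t >=
#' shock_start`; (9) outcome recording with the end-of-round forest
#' fraction. This pure-R implementation defines the model semantics;
#' [run_simulation()] uses a compiled engine that reproduces it
#' draw-for-draw (verified in the test suite).
#'
#' @param state list with `grid`, `agents`, `history` (see
#'   [init_state()]).
#' @param payoffs_prev previous-round payoff vector (zeros in round 1).
#' @param params a [swidden_params()].
#' @param t round index, 1-based.
#' @return List with the updated `state`, the payoff vector `payoffs`
#'   (to feed the next round), and `outcome`: a one-row data frame
#'   with columns `t, x_mean, xa_mean, y_mean, nplus_mean,
#'   delta_f_plus, f, pi_mean, shock, harvest_total, shock_loss,
#'   forest_cells` plus per-agent vectors in attributes `xa` and
#'   `nplus`.
#' @export
run_round <- function(state, payoffs_prev, params, t) {
  grid <- state$grid
  agents <- state$agents
  history <- state$history
  fc0 <- sum(grid$states)

  agents <- revise_agents(agents, history, payoffs_prev, fc0, params, t)
  d <- sample_help_matrix(agents, history)
  nplus <- as.integer(colSums(d))
  xa <- harvests(agents$x, nplus, fc0, params)
  grid <- clear_cells(grid, xa, params)
  costs <- helping_costs(d, xa, nplus, params)
  pay <- payoffs(xa, costs)
  history <- update_history(history, d, params$alpha)
  reg <- regenerate(grid, params)
  grid <- reg$grid

  shock_occurred <- FALSE
  shock_loss <- 0L
  if (params$p_sh > 0 && t >= resolve_shock_start(params)) {
    sh <- apply_shock(grid, params)
    grid <- sh$grid
    shock_occurred <- sh$occurred
    shock_loss <- sh$loss
  }

  outcome <- data.frame(
    t = t,
    x_mean = mean(agents$x),
    xa_mean = mean(xa),
    y_mean = mean(agents$y),
    nplus_mean = mean(nplus),
    delta_f_plus = reg$delta_f_plus,
    f = forest_fraction(grid),
    pi_mean = mean(pay),
    shock = as.integer(shock_occurred),
    harvest_total = as.integer(sum(xa)),
    shock_loss = shock_loss,
    forest_cells = sum(grid$states)
  )
  attr(outcome, "xa") <- xa
  attr(outcome, "nplus") <- nplus
  list(state = list(grid = grid, agents = agents, history = history),
       payoffs = pay, outcome = outcome)
}

#' Run a full simulation
#'
#' Seeds the R RNG from `params$seed`, builds the initial state
#' ([init_state()]) and iterates [run_round()] for `T` rounds.
#' `engine = "cpp"` (default) uses the compiled round loop;
#' `engine = "r"` uses the pure-R reference implementation. Both
#' consume the RNG stream identically, so they produce the same run
#' for the same parameters.
#'
#' @param params a [swidden_params()] (its `seed` field seeds the run).
#' @param engine `"cpp"` or `"r"`.
#' @param record_agents also record per-agent requests and helper
#'   counts each round (needed by [gsi()]); stored as `N x T`
#'   matrices.
#' @return An object of class `swidden_run`: list with `params`,
#'   `series` (a `T`-row data frame with columns `t, x_mean, xa_mean,
#'   y_mean, nplus_mean, delta_f_plus, f, pi_mean, shock,
#'   harvest_total, shock_loss, forest_cells`), `seed`, optional
#'   `agents_x` / `agents_nplus` matrices, `initial_forest_cells` and
#'   `provenance`.
#' @examples
#' run <- run_simulation(swidden_params(N = 5, L = 20, T = 50, seed = 1))
#' tail(run$series$f, 3)
#' @export
run_simulation <- function(params, engine = c("cpp", "r"),
                           record_agents = FALSE) {
  engine <- match.arg(engine)
  validate_params(params)
  set.seed(params$seed)
  state <- init_state(params)
  init_fc <- sum(state$grid$states)
  Tn <- params$T

  if (Tn == 0L) {
    series <- empty_series()
  } else if (engine == "cpp") {
    res <- sim_engine_cpp(
      state$grid$states, state$grid$lag,
      state$agents$x, state$agents$y, state$agents$mu, state$history,
      params$N, params$L, Tn,
      params$p0, params$p1, params$pmax, params$F,
      params$h, params$c0, params$c, params$alpha, params$lambda,
      params$nu0, params$nu1, params$nu2, params$innov_sd,
      params$l, params$p_sh, params$f_sh, resolve_shock_start(params),
      if (params$neighborhood == "moore") 8L else 4L,
      params$boundary == "torus",
      record_agents
    )
    series <- data.frame(
      t = seq_len(Tn),
      x_mean = res$x_mean, xa_mean = res$xa_mean, y_mean = res$y_mean,
      nplus_mean = res$nplus_mean, delta_f_plus = res$delta_f_plus,
      f = res$forest_cells / (params$L^2), pi_mean = res$pi_mean,
      shock = res$shock, harvest_total = res$harvest_total,
      shock_loss = res$shock_loss, forest_cells = res$forest_cells
    )
    if (record_agents) {
      agents_x <- res$agents_x
      agents_nplus <- res$agents_nplus
    }
  } else {
    pay <- rep(0, params$N)
    rows <- vector("list", Tn)
    if (record_agents) {
      agents_x <- matrix(0L, params$N, Tn)
      agents_nplus <- matrix(0L, params$N, Tn)
    }
    for (t in seq_len(Tn)) {
      step <- run_round(state, pay, params, t)
      state <- step$state
      pay <- step$payoffs
      if (record_agents) {
        agents_x[, t] <- state$agents$x
        agents_nplus[, t] <- attr(step$outcome, "nplus")
      }
      attr(step$outcome, "xa") <- NULL
      attr(step$outcome, "nplus") <- NULL
      rows[[t]] <- step$outcome
    }
    series <- do.call(rbind, rows)
  }

  run <- list(
    params = params,
    series = series,
    seed = params$seed,
    initial_forest_cells = init_fc,
    provenance = list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      package_version = as.character(utils::packageVersion("swidden")),
      engine = engine
    )
  )
  if (record_agents && Tn > 0L) {
    run$agents_x <- agents_x
    run$agents_nplus <- agents_nplus
  }
  class(run) <- "swidden_run"
  run
}

#' @keywords internal
empty_series <- function() {
  data.frame(t = integer(0), x_mean = numeric(0), xa_mean = numeric(0),
             y_mean = numeric(0), nplus_mean = numeric(0),
             delta_f_plus = integer(0), f = numeric(0),
             pi_mean = numeric(0), shock = integer(0),
             harvest_total = integer(0), shock_loss = integer(0),
             forest_cells = integer(0))
}

#' @export
print.swidden_run <- function(x, ...) {
  Tn <- nrow(x$series)
  cat(sprintf("swidden_run: N=%d L=%d T=%d seed=%d (%s engine)\n",
              x$params$N, x$params$L, Tn, x$seed, x$provenance$engine))
  if (Tn > 0) {
    s <- summarize_run(x)
    cat(sprintf("  final-window f=%.4f xa=%.3f y=%.2f N+=%.3f -> %s\n",
                s$f_bar, s$xa_bar, s$y_bar, s$nplus_bar, s$regime))
  }
  invisible(x)
}

# Deterministic per-run seed derivation: a small LCG-style mix keeping
# everything inside 32-bit integer range (and double-exact).
#' @keywords internal
derive_seed <- function(base_seed, k, stream = 0L) {
  m <- 2147483647
  s <- (as.numeric(base_seed) %% m) * 48271 +
    as.numeric(k) * 1234567 + as.numeric(stream) * 7654321
  as.integer(s %% (m - 1)) + 1L
}

#' Run a seeded ensemble
#'
#' Executes `n_runs` independent simulations whose seeds derive
#' deterministically from `base_seed`, so the ensemble is reproducible
#' and independent of execution order. By default only per-run
#' final-window summaries are kept (memory-bounded); set
#' `summary_only = FALSE` to also keep the full runs.
#'
#' @param params a [swidden_params()] (its own `seed` is ignored here).
#' @param n_runs number of runs, >= 1.
#' @param base_seed master seed for the ensemble.
#' @param summary_only keep only [summarize_run()] rows (default).
#' @param window_frac final-window fraction for the summaries.
#' @param eps_help helper-count threshold for regime classification.
#' @param gsi also compute the graduated sanctioning index per run
#'   (forces per-agent recording during each run).
#' @param engine simulation engine, as in [run_simulation()].
#' @return A data frame with one row per run: `run`, `seed`, the
#'   [summarize_run()] columns, and `gsi` when requested. When
#'   `summary_only = FALSE` the full `swidden_run` objects are
#'   attached as attribute `"runs"`.
#' @export
run_ensemble <- function(params, n_runs, base_seed = params$seed,
                         summary_only = TRUE, window_frac = 0.25,
                         eps_help = 0.25, gsi = FALSE,
                         engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(n_runs >= 1)
  rows <- vector("list", n_runs)
  runs <- if (summary_only) NULL else vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    p <- update_params(params, seed = derive_seed(base_seed, r))
    run <- run_simulation(p, engine = engine, record_agents = gsi)
    s <- summarize_run(run, window_frac = window_frac, eps_help = eps_help)
    s <- cbind(data.frame(run = r, seed = p$seed), s)
    if (gsi) s$gsi <- gsi(run, window_frac = window_frac)
    rows[[r]] <- s
    if (!summary_only) runs[[r]] <- run
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "base_seed") <- base_seed
  if (!summary_only) attr(out, "runs") <- runs
  out
}
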
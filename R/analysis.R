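#' Final-window run summary and sustainability flag
#'
#' Averages the recorded round aggregates over the final
#' `ceil(window_frac * T)` rounds (the default window is the last 25%
#' of rounds, i.e. rounds 751-1000 of a 1000-round run). A run is
#' sustainable when the window-mean forest fraction exceeds 0.05; the
#' regime label comes from [classify_regime()].
#'
#' @param run a `swidden_run` from [run_simulation()].
#' @param window_frac fraction of rounds in the final window.
#' @param eps_help mean-helpers threshold separating low-intensity
#'   swidden from active labour exchange.
#' @return One-row data frame with columns `f_bar, x_bar, xa_bar,
#'   y_bar, nplus_bar, dfp_bar, pi_bar, sustainable, regime`.
#' @export
summarize_run <- function(run, window_frac = 0.25, eps_help = 0.25) {
  series <- run$series
  Tn <- nrow(series)
  if (Tn == 0L) stop("cannot summarize an empty run")
  w <- max(1L, as.integer(ceiling(window_frac * Tn)))
  win <- series[(Tn - w + 1L):Tn, , drop = FALSE]
  f_bar <- mean(win$f)
  nplus_bar <- mean(win$nplus_mean)
  data.frame(
    f_bar = f_bar,
    x_bar = mean(win$x_mean),
    xa_bar = mean(win$xa_mean),
    y_bar = mean(win$y_mean),
    nplus_bar = nplus_bar,
    dfp_bar = mean(win$delta_f_plus),
    pi_bar = mean(win$pi_mean),
    sustainable = f_bar > 0.05,
    regime = classify_regime(f_bar, nplus_bar, eps_help),
    stringsAsFactors = FALSE
  )
}

#' Classify the emergent swidden regime
#'
#' `deforestation` when the window-mean forest fraction is at or below
#' the 0.05 sustainability threshold; otherwise `low_intensity` when
#' labour exchange is essentially absent (mean helpers per agent below
#' `eps_help`, the severe-sanctions outcome where every household
#' clears alone) and `sustainable_high_intensity` when an active
#' helping network persists alongside a standing forest.
#'
#' @param f_bar window-mean forest fraction.
#' @param nplus_bar window-mean helpers per agent.
#' @param eps_help helper-count threshold (default 0.25).
#' @return One of `"deforestation"`, `"low_intensity"`,
#'   `"sustainable_high_intensity"`.
#' @export
classify_regime <- function(f_bar, nplus_bar, eps_help = 0.25) {
  if (f_bar <= 0.05) return("deforestation")
  if (nplus_bar < eps_help) return("low_intensity")
  "sustainable_high_intensity"
}

#' Mean-field forest equilibrium under solitary clearing
#'
#' In the low-intensity regime every household clears `h` cells alone,
#' so roughly `h * N` cells leave the forest each round. Ignoring
#' spatial correlations, the forest fraction settles where per-cell
#' regeneration balances the per-cell harvest rate:
#' `(1 - f) * p(f) = h * nu` with population density `nu = N / L^2`,
#' on the declining branch of the recruitment curve (`f > F`), where
#' `p(f) = (pmax - p1*F - (pmax - p1)*f) / (1 - F)`. Writing
#' `A = (pmax - p1*F)/(1 - F)` and `B = (pmax - p1)/(1 - F)` (note
#' `A - B = p1`), the stable root is
#' `f* = ((A + B) - sqrt(p1^2 + 4*B*h*nu)) / (2*B)`.
#'
#' @param params a [swidden_params()].
#' @return A list with `f_star`, `nu`, and `branch_valid` (`FALSE`
#'   when `h * nu` exceeds the maximum regeneration flux
#'   `(1 - F) * pmax` attainable on this branch, in which case
#'   `f_star` is `NA`).
#' @examples
#' mean_field_f_star(swidden_params())$f_star  # about 0.887
#' @export
mean_field_f_star <- function(params) {
  nu <- params$N / params$L^2
  hnu <- params$h * nu
  A <- (params$pmax - params$p1 * params$F) / (1 - params$F)
  B <- (params$pmax - params$p1) / (1 - params$F)
  max_flux <- (1 - params$F) * params$pmax
  if (hnu > max_flux) {
    return(list(f_star = NA_real_, nu = nu, branch_valid = FALSE))
  }
  disc <- (A - B)^2 + 4 * B * hnu
  f_star <- ((A + B) - sqrt(disc)) / (2 * B)
  list(f_star = f_star, nu = nu,
       branch_valid = f_star >= params$F && f_star <= 1)
}

#' Cross a parameter grid with seeded ensembles
#'
#' For every combination of the supplied parameter values, runs a
#' seeded ensemble and collects per-run final-window summaries. Each
#' combination gets a deterministically derived base seed, so results
#' do not depend on execution order and single combinations can be
#' reproduced in isolation.
#'
#' @param params base [swidden_params()].
#' @param grid named list of parameter value vectors, crossed as a
#'   full factorial (e.g. `list(mu = seq(0, 1, 0.25))`).
#' @param n_runs runs per combination.
#' @param base_seed master seed.
#' @param ... passed to [run_ensemble()] (e.g. `gsi = TRUE`,
#'   `window_frac`).
#' @return Data frame with the combination columns followed by the
#'   [run_ensemble()] columns, one row per run.
#' @seealso [sweep_aggregates()], [bistability_fraction()]
#' @export
param_sweep <- function(params, grid, n_runs, base_seed, ...) {
  stopifnot(is.list(grid), length(grid) >= 1, !is.null(names(grid)))
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  for (k in seq_len(nrow(combos))) {
    vals <- as.list(combos[k, , drop = FALSE])
    p <- do.call(update_params, c(list(params), vals))
    ens <- run_ensemble(p, n_runs,
                        base_seed = derive_seed(base_seed, 0L,
                                                stream = combo_stream(vals)),
                        ...)
    out[[k]] <- cbind(combos[rep(k, nrow(ens)), , drop = FALSE], ens,
                      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "base_seed") <- base_seed
  attr(res, "n_runs") <- n_runs
  res
}

# Combination seeds derive from the combination's values (not its
# position in the grid), so sweep results are invariant to the order
# in which combinations are listed or executed.
#' @keywords internal
combo_stream <- function(vals) {
  s <- 0
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    num <- if (is.numeric(v)) v else sum(utf8ToInt(as.character(v)))
    s <- (s * 131 + j * 31 + abs(round(num * 1000))) %% 1000000
  }
  as.integer(s)
}

#' Per-combination aggregates of a sweep table
#'
#' @param sweep_df output of [param_sweep()].
#' @param by combination column names (defaults to everything before
#'   the `run` column).
#' @return Data frame with the mean of each outcome and the fraction
#'   of sustainable runs per combination.
#' @export
sweep_aggregates <- function(sweep_df, by = NULL) {
  if (is.null(by)) {
    by <- names(sweep_df)[seq_len(match("run", names(sweep_df)) - 1L)]
  }
  num_cols <- c("f_bar", "x_bar", "xa_bar", "y_bar", "nplus_bar",
                "dfp_bar", "pi_bar")
  num_cols <- intersect(num_cols, names(sweep_df))
  if ("gsi" %in% names(sweep_df)) num_cols <- c(num_cols, "gsi")
  key <- interaction(sweep_df[by], drop = TRUE, lex.order = TRUE)
  agg <- lapply(split(sweep_df, key), function(d) {
    row <- d[1L, by, drop = FALSE]
    for (col in num_cols) row[[col]] <- mean(d[[col]])
    row$frac_sustainable <- bistability_fraction(d)
    row$n_runs <- nrow(d)
    row
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res
}

#' Fraction of sustainable runs at one parameter combination
#'
#' Values strictly between 0 and 1 indicate ensemble-level
#' bistability: sustainable high-intensity swidden and complete
#' deforestation coexist as attractors and the realized outcome
#' depends on the run's initial conditions and noise.
#'
#' @param summaries data frame with a logical `sustainable` column
#'   (one row per run).
#' @return Fraction in \[0, 1\].
#' @export
bistability_fraction <- function(summaries) {
  stopifnot(nrow(summaries) >= 1, "sustainable" %in% names(summaries))
  mean(summaries$sustainable)
}

#' Graduated sanctioning index of a run
#'
#' Standardized mismatch between clearing decisions and help received.
#' Each round, requests and helper counts are z-scored across agents
#' (population s.d.; a zero-variance round contributes zero scores)
#' and each agent's per-round index is `z(x_i) - z(N+_i)`. The default
#' run-level aggregate weights these differences by the standardized
#' request, `mean_i z(x_i) * (z(x_i) - z(N+_i))`, averaged over the
#' final window; per round this equals `1 - cor(x, N+)`, so it is 0
#' when help tracks requests (no graduation) and positive when large
#' requests are systematically refused help (graduated sanctioning).
#' The unweighted per-agent mean of `z(x) - z(N+)` is identically zero
#' across agents by construction, which is why the weighted form is
#' the default; `aggregate` is pluggable for other conventions.
#'
#' @param run a `swidden_run` created with `record_agents = TRUE`.
#' @param window_frac final-window fraction.
#' @param aggregate function mapping the two z-score matrices
#'   (agents x rounds) to a scalar; the default implements the
#'   request-weighted mean described above.
#' @return The run-level GSI (scalar).
#' @export
gsi <- function(run, window_frac = 0.25, aggregate = NULL) {
  if (is.null(run$agents_x) || is.null(run$agents_nplus))
    stop("run was not recorded with record_agents = TRUE")
  Tn <- ncol(run$agents_x)
  w <- max(1L, as.integer(ceiling(window_frac * Tn)))
  cols <- (Tn - w + 1L):Tn
  zx <- apply(run$agents_x[, cols, drop = FALSE], 2L, zscore_pop)
  zn <- apply(run$agents_nplus[, cols, drop = FALSE], 2L, zscore_pop)
  if (is.null(aggregate)) aggregate <- function(zx, zn) mean(zx * (zx - zn))
  aggregate(zx, zn)
}

# Population z-score; zero vector when the variance vanishes.
#' @keywords internal
zscore_pop <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}
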
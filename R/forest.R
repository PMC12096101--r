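#' Forest lattice
#'
#' A binary `L x L` lattice (1 = forest, 0 = empty) plus per-cell lag
#' counters holding the number of regeneration steps an empty cell
#' must still wait before it becomes eligible to regenerate (all zero
#' unless the revegetation lag `l > 0`).
#'
#' @param states integer matrix of 0/1 cell states (square).
#' @param lag optional integer matrix of non-negative lag counters,
#'   zero wherever `states == 1`.
#' @return An object of class `forest_grid`: list with `states`,
#'   `lag` and side length `L`.
#' @examples
#' g <- forest_grid(matrix(1L, 10, 10))
#' forest_fraction(g)
#' @export
forest_grid <- function(states, lag = NULL) {
  states <- as.matrix(states)
  if (nrow(states) != ncol(states)) stop("grid must be square")
  storage.mode(states) <- "integer"
  if (!all(states %in% c(0L, 1L))) stop("states must be 0/1")
  if (is.null(lag)) lag <- matrix(0L, nrow(states), ncol(states))
  lag <- as.matrix(lag)
  storage.mode(lag) <- "integer"
  if (!identical(dim(lag), dim(states))) stop("lag dimensions must match states")
  if (any(lag < 0L)) stop("lag counters must be >= 0")
  if (any(lag > 0L & states == 1L)) stop("forest cells cannot carry a lag")
  structure(list(states = states, lag = lag, L = nrow(states)),
            class = "forest_grid")
}

#' @export
print.forest_grid <- function(x, ...) {
  cat(sprintf("forest_grid %dx%d: %d forest cells (f = %.4f)\n",
              x$L, x$L, sum(x$states), forest_fraction(x)))
  invisible(x)
}

#' Fraction of cells occupied by trees
#'
#' @param grid a [forest_grid()].
#' @return Forest cell count divided by `L^2`.
#' @export
forest_fraction <- function(grid) {
  sum(grid$states) / (grid$L^2)
}

# Shift a matrix by (dr, dc); torus wraps, clip pads with `fill`.
#' @keywords internal
shift_matrix <- function(m, dr, dc, torus = TRUE, fill = 0L) {
  L <- nrow(m)
  if (torus) {
    ri <- ((seq_len(L) - 1L - dr) %% L) + 1L
    ci <- ((seq_len(L) - 1L - dc) %% L) + 1L
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(fill, L, L)
  rs <- seq_len(L) + dr
  cs <- seq_len(L) + dc
  ok_r <- rs >= 1L & rs <= L
  ok_c <- cs >= 1L & cs <= L
  out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c], drop = FALSE]
  out
}

#' @keywords internal
neighborhood_offsets <- function(neighborhood) {
  if (neighborhood == "moore") {
    expand.grid(dr = -1:1, dc = -1:1)[-5, , drop = FALSE]
  } else {
    data.frame(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  }
}

# Per-cell forested-neighbour counts and neighbourhood sizes.
#' @keywords internal
neighbor_forest_counts <- function(states, neighborhood, boundary) {
  off <- neighborhood_offsets(neighborhood)
  torus <- boundary == "torus"
  L <- nrow(states)
  counts <- matrix(0L, L, L)
  sizes <- matrix(0L, L, L)
  ones <- matrix(1L, L, L)
  for (k in seq_len(nrow(off))) {
    counts <- counts + shift_matrix(states, off$dr[k], off$dc[k], torus)
    sizes <- sizes + if (torus) ones else
      shift_matrix(ones, off$dr[k], off$dc[k], FALSE)
  }
  list(counts = counts, sizes = sizes)
}

#' Local forest fraction around a cell
#'
#' Fraction of the cell's neighbours (Moore-8 or von-Neumann-4, focal
#' cell excluded) occupied by trees, under the configured boundary
#' convention.
#'
#' @param grid a [forest_grid()].
#' @param cell integer vector `c(row, col)`, 1-based.
#' @param params a [swidden_params()] supplying the neighbourhood and
#'   boundary conventions.
#' @return A fraction in \[0, 1\].
#' @export
local_forest_fraction <- function(grid, cell, params) {
  r <- as.integer(cell[1]); cc <- as.integer(cell[2])
  if (is.na(r) || is.na(cc) || r < 1L || cc < 1L || r > grid$L || cc > grid$L)
    stop("cell coordinate out of range")
  nb <- neighbor_forest_counts(grid$states, params$neighborhood, params$boundary)
  nb$counts[r, cc] / nb$sizes[r, cc]
}

#' Density-dependent regeneration probability
#'
#' Piecewise-linear recruitment curve: the probability that an empty
#' cell regenerates grows linearly from `p0` at local forest fraction
#' 0 to its peak `pmax` at fraction `F`, then declines linearly to
#' `p1` at fraction 1. `F` near 0.5 makes recruitment best at
#' intermediate local density (competition for light/resources); `F`
#' near 1 approximates logistic-type growth.
#'
#' @param f_k local forest fraction(s) in \[0, 1\]; vectorized.
#' @param params a [swidden_params()].
#' @return Regeneration probability/ies.
#' @examples
#' regen_probability(c(0, 0.5, 1), swidden_params())
#' @export
regen_probability <- function(f_k, params) {
  if (any(!is.finite(f_k)) || any(f_k < 0) || any(f_k > 1))
    stop("f_k must lie in [0,1]")
  p0 <- params$p0; p1 <- params$p1; pmax_ <- params$pmax; Fp <- params$F
  ifelse(f_k <= Fp,
         (pmax_ - p0) * f_k / Fp + p0,
         (pmax_ - p1 * Fp - (pmax_ - p1) * f_k) / (1 - Fp))
}

#' One synchronous regeneration step
#'
#' Every empty cell whose lag counter is zero regenerates
#' independently with probability [regen_probability()] of its local
#' forest fraction, all evaluated against the pre-update grid
#' (synchronous update). Lag counters of the remaining empty cells
#' decrement by one. Uses the current R RNG stream; draws are consumed
#' for eligible cells in column-major cell order.
#'
#' @param grid a [forest_grid()].
#' @param params a [swidden_params()].
#' @return List with the updated `grid` and `delta_f_plus`, the count
#'   of cells that regenerated (the round's new biomass).
#' @export
regenerate <- function(grid, params) {
  states <- grid$states
  lag <- grid$lag
  eligible <- which(states == 0L & lag == 0L)
  delta <- 0L
  if (length(eligible)) {
    nb <- neighbor_forest_counts(states, params$neighborhood, params$boundary)
    f_k <- nb$counts[eligible] / nb$sizes[eligible]
    p <- regen_probability(f_k, params)
    u <- stats::runif(length(eligible))
    flip <- eligible[u < p]
    delta <- length(flip)
    if (delta) states[flip] <- 1L
  }
  lagged <- lag > 0L
  if (any(lagged)) lag[lagged] <- lag[lagged] - 1L
  list(grid = forest_grid(states, lag), delta_f_plus = as.integer(delta))
}

# Select k forest cells uniformly at random without replacement:
# one uniform key per forested cell (ascending cell index), the k
# smallest keys win. The key scheme makes the R and compiled engines
# consume the RNG stream identically.
#' @keywords internal
draw_forest_cells <- function(states, k) {
  idx <- which(states == 1L)
  if (k > length(idx)) stop("internal error: clearing demand exceeds forest")
  if (k == 0L) return(integer(0))
  keys <- stats::runif(length(idx))
  idx[order(keys)[seq_len(k)]]
}

#' Clear harvested cells
#'
#' Removes `sum(harvests)` forest cells, chosen uniformly at random
#' without replacement (the model's agents have no spatial identity).
#' With a revegetation lag `l > 0` the emptied cells receive lag
#' counter `l`.
#'
#' @param grid a [forest_grid()].
#' @param harvests per-agent realized harvests (cells); their sum must
#'   not exceed the standing forest (guaranteed upstream by the
#'   per-agent clearing cap).
#' @param params a [swidden_params()].
#' @return The updated `forest_grid`.
#' @export
clear_cells <- function(grid, harvests, params) {
  k <- as.integer(sum(harvests))
  if (k == 0L) return(grid)
  sel <- draw_forest_cells(grid$states, k)
  states <- grid$states
  lag <- grid$lag
  states[sel] <- 0L
  if (params$l > 0L) lag[sel] <- params$l
  forest_grid(states, lag)
}

#' Apply an external shock
#'
#' With probability `p_sh` a shock destroys `round(f_sh * L^2)`
#' uniformly chosen forest cells; if fewer forest cells remain, the
#' whole grid becomes empty. Newly emptied cells receive lag counter
#' `l`. The caller gates this on the round index (shocks only from
#' `shock_start` onwards). No RNG draw is consumed when `p_sh = 0`.
#'
#' @param grid a [forest_grid()].
#' @param params a [swidden_params()].
#' @return List with `grid`, logical `occurred`, and `loss` (forest
#'   cells destroyed).
#' @export
apply_shock <- function(grid, params) {
  if (params$p_sh <= 0)
    return(list(grid = grid, occurred = FALSE, loss = 0L))
  u <- stats::runif(1L)
  if (u >= params$p_sh)
    return(list(grid = grid, occurred = FALSE, loss = 0L))
  L2 <- grid$L^2
  k_sh <- as.integer(round(params$f_sh * L2))
  n_forest <- sum(grid$states)
  states <- grid$states
  lag <- grid$lag
  if (n_forest < k_sh) {
    hit <- which(states == 1L)
  } else {
    hit <- draw_forest_cells(states, k_sh)
  }
  loss <- length(hit)
  if (loss) {
    states[hit] <- 0L
    if (params$l > 0L) lag[hit] <- params$l
  }
  list(grid = forest_grid(states, lag), occurred = TRUE,
       loss = as.integer(loss))
}

#' Export a grid snapshot as plain text
#'
#' Writes the 0/1 cell states either as a headerless CSV (one lattice
#' row per line) or as a portable graymap (PGM, P2) for quick viewing.
#'
#' @param grid a [forest_grid()].
#' @param path output file path.
#' @param format `"csv"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(grid$states, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(grid$L, grid$L), "1"), con)
    apply(grid$states, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  }
  invisible(path)
}
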
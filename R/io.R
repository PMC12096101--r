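#' Resolve a run configuration from file, overrides and defaults
#'
#' Reads a flat JSON key-value document holding model parameters plus
#' optional execution keys (`n_runs`, `base_seed`, `out_dir`,
#' `summary_only`, `window_frac`) and an optional `sweep` object
#' mapping parameter names to value lists. Precedence is
#' overrides > file > package defaults; unknown keys are rejected
#' with their names, and the merged parameter set is validated.
#'
#' @param path optional path to a JSON config file.
#' @param overrides named list of values that win over the file
#'   (e.g. parsed command-line flags).
#' @return A list of class `swidden_config` with elements `params`
#'   (a [swidden_params()]), `execution` (n_runs, base_seed, out_dir,
#'   summary_only, window_frac), `sweep` (named list or NULL) and
#'   `provenance` (which source set each key).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  exec_defaults <- list(n_runs = 1L, base_seed = 1L, out_dir = ".",
                        summary_only = TRUE, window_frac = 0.25)
  param_names <- names(unclass(swidden_params()))
  known <- c(param_names, names(exec_defaults), "sweep")

  from_file <- list()
  if (!is.null(path)) {
    from_file <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(from_file)) stop("config file must hold a JSON object")
    from_file <- from_file[!vapply(from_file, function(v)
      is.null(v) || (length(v) == 1L && is.na(v) && !is.character(v)),
      logical(1))]
  }
  for (src in list(from_file, overrides)) {
    unknown <- setdiff(names(src), known)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }

  merged <- utils::modifyList(from_file, overrides)
  provenance <- c(
    stats::setNames(rep("file", length(from_file)), names(from_file)),
    stats::setNames(rep("override", length(overrides)), names(overrides))
  )
  provenance <- provenance[!duplicated(names(provenance), fromLast = TRUE)]

  sweep <- merged[["sweep"]]
  if (!is.null(sweep)) {
    sweep <- lapply(as.list(sweep), unlist)
    unknown <- setdiff(names(sweep), param_names)
    if (length(unknown))
      stop("unknown sweep parameter(s): ", paste(unknown, collapse = ", "))
  }
  exec <- utils::modifyList(exec_defaults,
                            merged[intersect(names(merged), names(exec_defaults))])
  exec$n_runs <- as.integer(exec$n_runs)
  exec$base_seed <- as.integer(exec$base_seed)
  exec$summary_only <- as.logical(exec$summary_only)
  exec$window_frac <- as.numeric(exec$window_frac)
  pvals <- merged[intersect(names(merged), param_names)]
  params <- if (length(pvals))
    do.call(update_params, c(list(swidden_params()), pvals))
  else swidden_params()

  structure(list(params = params, execution = exec, sweep = sweep,
                 provenance = provenance),
            class = "swidden_config")
}

# Frozen column set of the per-round CSV.
run_csv_columns <- c("t", "x_mean", "xa_mean", "y_mean", "nplus_mean",
                     "delta_f_plus", "f", "pi_mean", "shock")

#' Write a run's time series as CSV with a JSON sidecar
#'
#' The CSV holds one row per round with the frozen columns
#' `t, x_mean, xa_mean, y_mean, nplus_mean, delta_f_plus, f, pi_mean,
#' shock` (floating-point values at 10 significant digits); the
#' sidecar `<path>.json` holds the full parameter set, seed and code
#' version, which alone suffice to reconstruct the run.
#'
#' @param run a `swidden_run`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @seealso [read_run_csv()]
#' @export
write_run_csv <- function(run, path) {
  df <- run$series[, run_csv_columns, drop = FALSE]
  for (col in c("x_mean", "xa_mean", "y_mean", "nplus_mean", "f", "pi_mean"))
    df[[col]] <- sprintf("%.10g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(params = unclass(run$params), seed = run$seed,
                  provenance = run$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a run CSV
#'
#' @param path CSV path written by [write_run_csv()].
#' @return Data frame with the frozen run columns.
#' @export
read_run_csv <- function(path) {
  utils::read.csv(path)
}

#' Write ensemble/sweep summaries as CSV with a JSON sidecar
#'
#' @param summaries data frame from [run_ensemble()] or
#'   [param_sweep()].
#' @param path CSV output path.
#' @param meta extra metadata for the sidecar (merged with the stored
#'   base seed and run count when present as attributes).
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path, meta = list()) {
  df <- summaries
  num <- vapply(df, is.double, logical(1))
  for (col in names(df)[num]) df[[col]] <- sprintf("%.10g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- utils::modifyList(
    list(base_seed = attr(summaries, "base_seed"),
         n_runs = attr(summaries, "n_runs")),
    meta)
  sidecar <- sidecar[!vapply(sidecar, is.null, logical(1))]
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
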
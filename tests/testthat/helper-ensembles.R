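# Shared, lazily computed ensembles for the acceptance suite. Base
# seeds are a fixed function of the experimental condition so every
# test that asks for the first n runs of a condition sees the same
# runs, and nothing depends on test execution order.

.acc_cache <- new.env(parent = emptyenv())

acc_ensemble <- function(mu, n_runs, gsi = FALSE) {
  key <- sprintf("mu%03d_g%d", round(100 * mu), as.integer(gsi))
  cur <- get0(key, envir = .acc_cache)
  if (is.null(cur) || nrow(cur) < n_runs) {
    cur <- run_ensemble(swidden_params(mu = mu), n_runs,
                        base_seed = 1000L + round(100 * mu), gsi = gsi)
    assign(key, cur, envir = .acc_cache)
  }
  cur[seq_len(n_runs), , drop = FALSE]
}

# Full normative-weight sweep: mu in {0, 0.05, ..., 1}, 10 runs each,
# with the graduated sanctioning index recorded per run.
acc_mu_sweep <- function() {
  cur <- get0("mu_sweep", envir = .acc_cache)
  if (is.null(cur)) {
    cur <- param_sweep(swidden_params(), list(mu = seq(0, 1, by = 0.05)),
                       n_runs = 10, base_seed = 424L, gsi = TRUE)
    assign("mu_sweep", cur, envir = .acc_cache)
  }
  cur
}
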
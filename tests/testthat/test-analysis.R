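# Fabricate a run object with a prescribed f trajectory (other columns
# held constant) for window arithmetic tests.
fake_run <- function(f, nplus = 0, xa = 3) {
  Tn <- length(f)
  series <- data.frame(
    t = seq_len(Tn), x_mean = 3, xa_mean = xa, y_mean = 1,
    nplus_mean = nplus, delta_f_plus = 0L, f = f, pi_mean = 2.8,
    shock = 0L, harvest_total = 0L, shock_loss = 0L,
    forest_cells = as.integer(round(f * 100))
  )
  structure(list(params = swidden_params(), series = series, seed = 1L,
                 initial_forest_cells = 100L,
                 provenance = list(engine = "fake")),
            class = "swidden_run")
}

test_that("run summaries average exactly the final window", {
  s1 <- summarize_run(fake_run(rep(1, 100)))
  expect_equal(s1$f_bar, 1)
  expect_true(s1$sustainable)
  s0 <- summarize_run(fake_run(rep(0, 100)))
  expect_false(s0$sustainable)
  expect_identical(s0$regime, "deforestation")
  # T = 1000 with a 25% window averages rounds 751..1000
  sr <- summarize_run(fake_run((1:1000) / 1000))
  expect_equal(sr$f_bar, mean(751:1000) / 1000)
  # window length is ceil(window_frac * T)
  s3 <- summarize_run(fake_run(c(0, 0, 1)), window_frac = 0.5)
  expect_equal(s3$f_bar, 0.5)
})

test_that("regimes classify by forest retention then helping intensity", {
  expect_identical(classify_regime(0.01, 5), "deforestation")
  expect_identical(classify_regime(0.05, 5), "deforestation")   # boundary
  expect_identical(classify_regime(0.88, 0.02), "low_intensity")
  expect_identical(classify_regime(0.4, 2.0), "sustainable_high_intensity")
  expect_identical(classify_regime(0.4, 0.3, eps_help = 0.5), "low_intensity")
  s <- summarize_run(fake_run(rep(0.9, 40), nplus = 3))
  expect_identical(s$regime, "sustainable_high_intensity")
})

test_that("mean-field equilibrium solves the regeneration-harvest balance", {
  p <- swidden_params()
  mf <- mean_field_f_star(p)
  expect_true(mf$branch_valid)
  expect_equal(mf$nu, 40 / 120^2)
  # frozen value computed with the independent bisection oracle
  expect_equal(mf$f_star, 0.8867584, tolerance = 1e-6)
  expect_equal(mf$f_star,
               oracle_f_star_bisect(p$p1, p$pmax, p$F, p$h * mf$nu),
               tolerance = 1e-10)
  # no harvest: the full forest is the fixed point
  p0 <- update_params(p, h = 1L, N = 1L, L = 1000L)
  expect_equal(mean_field_f_star(p0)$f_star, 1, tolerance = 1e-3)
  # harvest pressure beyond the maximum regeneration flux: no root
  bad <- swidden_params(N = 300, L = 20)
  expect_false(mean_field_f_star(bad)$branch_valid)
  expect_true(is.na(mean_field_f_star(bad)$f_star))
})

test_that("closed-form equilibrium matches bisection on random parameters", {
  set.seed(16)
  for (k in 1:100) {
    pm <- runif(1, 0.1, 1)
    p1v <- runif(1, 0.01, pm)
    Fv <- runif(1, 0.1, 0.9)
    hnu <- runif(1, 0, (1 - Fv) * pm * 0.98)
    # choose grid side and population so that h * N / L^2 = hnu
    L <- 100L
    N <- max(1L, as.integer(round(hnu * L^2)))
    p <- swidden_params(p1 = p1v, pmax = pm, p0 = runif(1, 0, p1v),
                        F = Fv, h = 1L, N = N, L = L)
    mf <- mean_field_f_star(p)
    expect_equal(mf$f_star,
                 oracle_f_star_bisect(p1v, pm, Fv, p$h * N / L^2),
                 tolerance = 1e-10)
  }
})

test_that("parameter sweeps cross grids reproducibly and order-free", {
  p <- small_params(T = 30)
  sw <- param_sweep(p, list(mu = c(0.2, 0.8)), n_runs = 2, base_seed = 50)
  expect_identical(nrow(sw), 4L)
  expect_true(all(c("mu", "run", "seed", "f_bar", "sustainable") %in% names(sw)))
  # reversing the grid order leaves each combination's runs unchanged
  sw_rev <- param_sweep(p, list(mu = c(0.8, 0.2)), n_runs = 2, base_seed = 50)
  a <- sw[sw$mu == 0.2, ]; b <- sw_rev[sw_rev$mu == 0.2, ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  # a single-point grid with one run equals the plain simulation summary
  sw1 <- param_sweep(p, list(mu = 0.6), n_runs = 1, base_seed = 50)
  one <- run_simulation(update_params(p, mu = 0.6, seed = sw1$seed[1]))
  expect_equal(sw1$f_bar, summarize_run(one)$f_bar)
  # aggregates: one row per combination with the sustainable fraction
  ag <- sweep_aggregates(sw)
  expect_identical(nrow(ag), 2L)
  expect_true(all(ag$frac_sustainable >= 0 & ag$frac_sustainable <= 1))
  expect_identical(ag$n_runs, c(2L, 2L))
})

test_that("the bistability fraction is the share of sustainable runs", {
  expect_equal(bistability_fraction(data.frame(sustainable = c(TRUE, TRUE))), 1)
  expect_equal(bistability_fraction(data.frame(sustainable = FALSE)), 0)
  expect_equal(bistability_fraction(data.frame(sustainable = c(TRUE, FALSE,
                                                               FALSE, TRUE))),
               0.5)
})

test_that("the graduated sanctioning index separates sanctioned requests", {
  base <- fake_run(rep(0.5, 40))
  # identical agents every round: zero z-scores, zero index
  r1 <- base
  r1$agents_x <- matrix(3L, 4, 40)
  r1$agents_nplus <- matrix(2L, 4, 40)
  expect_equal(gsi(r1), 0)
  # help perfectly rank-aligned with requests (equal variances): ~0
  r2 <- base
  r2$agents_x <- matrix(rep(c(1L, 2L, 3L, 4L), 40), 4)
  r2$agents_nplus <- r2$agents_x
  expect_equal(gsi(r2), 0)
  # large requests systematically refused help: positive index
  r3 <- base
  r3$agents_x <- matrix(rep(c(5L, 1L), 40), 2)
  r3$agents_nplus <- matrix(rep(c(0L, 3L), 40), 2)
  expect_gt(gsi(r3), 0)
  # per-round value equals 1 - cor(x, N+) under population z-scoring
  expect_equal(gsi(r3), 1 - stats::cor(c(5, 1), c(0, 3)))
  expect_error(gsi(base), "record_agents")
})
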
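test_that("regeneration probability is the piecewise-linear recruitment curve", {
  p <- swidden_params()
  expect_equal(regen_probability(0, p), 0.01)
  expect_equal(regen_probability(1, p), 0.06)
  expect_equal(regen_probability(p$F, p), 0.12)
  # interior point, checked against an independent two-point line:
  # p0 + (pmax - p0) * f / F at f = 0.25
  line <- 0.01 + (0.12 - 0.01) * 0.25 / 0.5
  expect_equal(regen_probability(0.25, p), line)
  expect_equal(line, 0.065)
  expect_error(regen_probability(1.2, p), "f_k")
  expect_error(regen_probability(-0.1, p), "f_k")
})

test_that("recruitment curve is continuous, piecewise linear and peaks at F", {
  set.seed(42)
  for (k in 1:50) {
    pm <- runif(1, 0.2, 1)
    p <- swidden_params(p0 = runif(1, 0, pm), p1 = runif(1, 0, pm),
                        pmax = pm, F = runif(1, 0.1, 0.9))
    f <- sort(c(seq(0, 1, length.out = 201), p$F))
    v <- regen_probability(f, p)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(max(v), regen_probability(p$F, p))
    # continuity at the peak
    expect_equal(regen_probability(p$F - 1e-9, p),
                 regen_probability(p$F + 1e-9, p), tolerance = 1e-6)
    # linear on each branch: the midpoint lies on the chord
    expect_equal(regen_probability(p$F / 2, p),
                 (regen_probability(0, p) + regen_probability(p$F, p)) / 2)
    expect_equal(regen_probability((p$F + 1) / 2, p),
                 (regen_probability(p$F, p) + regen_probability(1, p)) / 2)
  }
})

test_that("local forest fraction respects neighbourhood and boundary", {
  p <- swidden_params()
  full <- forest_grid(matrix(1L, 8, 8))
  empty <- forest_grid(matrix(0L, 8, 8))
  expect_equal(local_forest_fraction(full, c(3, 3), p), 1)
  expect_equal(local_forest_fraction(empty, c(3, 3), p), 0)
  # single empty cell: its own state does not enter its neighbourhood
  m <- matrix(1L, 8, 8); m[4, 4] <- 0L
  g <- forest_grid(m)
  expect_equal(local_forest_fraction(g, c(4, 4), p), 1)
  # the empty cell removes 1 of 8 neighbours for an adjacent cell
  expect_equal(local_forest_fraction(g, c(4, 5), p), 7 / 8)
  pv <- swidden_params(neighborhood = "von_neumann")
  expect_equal(local_forest_fraction(g, c(4, 5), pv), 3 / 4)
  # clipped boundary: a corner has 3 Moore neighbours
  pc <- swidden_params(boundary = "clip")
  expect_equal(local_forest_fraction(full, c(1, 1), pc), 1)
  m2 <- matrix(1L, 8, 8); m2[1, 2] <- 0L
  expect_equal(local_forest_fraction(forest_grid(m2), c(1, 1), pc), 2 / 3)
  expect_error(local_forest_fraction(full, c(0, 1), p), "out of range")
  expect_error(local_forest_fraction(full, c(9, 1), p), "out of range")
})

test_that("regeneration updates synchronously against the pre-update grid", {
  # one forest cell; recruitment certain at any positive local density,
  # impossible at zero density. A synchronous step converts exactly the
  # 8 Moore neighbours; any sequential cascade would convert more.
  p <- swidden_params(p0 = 0, p1 = 1, pmax = 1, F = 0.1)
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  set.seed(1)
  out <- regenerate(forest_grid(m), p)
  expect_identical(out$delta_f_plus, 8L)
  expect_identical(sum(out$grid$states), 9L)
  got <- which(out$grid$states == 1L, arr.ind = TRUE)
  expect_true(all(abs(got[, 1] - 5) <= 1 & abs(got[, 2] - 5) <= 1))
})

test_that("regeneration on degenerate grids and its sampling distribution", {
  p <- swidden_params()
  full <- forest_grid(matrix(1L, 20, 20))
  set.seed(2)
  expect_identical(regenerate(full, p)$delta_f_plus, 0L)

  # all-empty default-size grid: Delta f+ ~ Binomial(L^2, p0)
  set.seed(4)
  out <- regenerate(forest_grid(matrix(0L, 120, 120)), p)
  mu <- 120^2 * 0.01
  sdv <- sqrt(120^2 * 0.01 * 0.99)
  expect_lt(abs(out$delta_f_plus - mu), 4 * sdv)

  # flat recruitment curve: goodness of fit against Binomial(100, 0.3)
  pf <- swidden_params(p0 = 0.3, p1 = 0.3, pmax = 0.3)
  g0 <- forest_grid(matrix(0L, 10, 10))
  set.seed(5)
  draws <- replicate(10000, regenerate(g0, pf)$delta_f_plus)
  expect_equal(mean(draws), 30, tolerance = 0.02)
  br <- c(-Inf, 24:36, Inf)
  obs <- table(cut(draws, br))
  pr <- diff(pbinom(c(-Inf, 24:36, Inf), 100, 0.3))
  expect_gt(chisq.test(as.vector(obs), p = pr)$p.value, 0.001)
})

test_that("revegetation lag blocks regeneration for exactly l steps", {
  p <- swidden_params(p0 = 1, p1 = 1, pmax = 1, l = 2L, N = 1)
  g <- forest_grid(matrix(1L, 6, 6))
  set.seed(6)
  g <- clear_cells(g, 5, p)
  expect_identical(sum(g$states), 31L)
  expect_identical(sum(g$lag == 2L), 5L)
  r1 <- regenerate(g, p)          # cleared cells ineligible (lag 2 -> 1)
  expect_identical(r1$delta_f_plus, 0L)
  r2 <- regenerate(r1$grid, p)    # still ineligible (lag 1 -> 0)
  expect_identical(r2$delta_f_plus, 0L)
  r3 <- regenerate(r2$grid, p)    # eligible, certain recruitment
  expect_identical(r3$delta_f_plus, 5L)
  expect_equal(forest_fraction(r3$grid), 1)
  # with l = 0 the lag counters never leave zero
  p0 <- swidden_params(N = 1)
  g0 <- clear_cells(forest_grid(matrix(1L, 6, 6)), 10, p0)
  expect_true(all(g0$lag == 0L))
})

test_that("clearing removes the requested number of uniformly chosen cells", {
  p <- swidden_params(N = 5)
  g <- forest_grid(matrix(1L, 10, 10))
  set.seed(7)
  expect_identical(clear_cells(g, c(0, 0, 0, 0, 0), p)$states, g$states)
  g2 <- clear_cells(g, c(10, 5, 5, 5, 5), p)
  expect_identical(sum(g2$states), 70L)
  g3 <- clear_cells(g, rep(20, 5), p)
  expect_identical(sum(g3$states), 0L)
  expect_error(clear_cells(g2, rep(20, 5), p), "exceeds")
})

test_that("external shocks destroy round(f_sh * L^2) cells or the whole forest", {
  set.seed(8)
  p_off <- swidden_params(p_sh = 0)
  g <- forest_grid(matrix(1L, 10, 10))
  expect_false(apply_shock(g, p_off)$occurred)

  p_all <- swidden_params(p_sh = 1, f_sh = 1)
  sh <- apply_shock(g, p_all)
  expect_true(sh$occurred)
  expect_identical(sum(sh$grid$states), 0L)
  expect_identical(sh$loss, 100L)

  p_part <- swidden_params(p_sh = 1, f_sh = 0.1)
  sh2 <- apply_shock(g, p_part)
  expect_identical(sh2$loss, 10L)
  expect_identical(sum(sh2$grid$states), 90L)

  # fewer forest cells than the shock demands: everything goes
  m <- matrix(0L, 10, 10); m[1:10] <- 1L
  sh3 <- apply_shock(forest_grid(m), swidden_params(p_sh = 1, f_sh = 0.2))
  expect_identical(sum(sh3$grid$states), 0L)
  expect_identical(sh3$loss, 10L)
})

test_that("forest fraction is the forest count over L^2", {
  expect_equal(forest_fraction(forest_grid(matrix(1L, 12, 12))), 1)
  expect_equal(forest_fraction(forest_grid(matrix(0L, 12, 12))), 0)
  m <- matrix(0L, 120, 120); m[seq_len(7200)] <- 1L
  expect_equal(forest_fraction(forest_grid(m)), 0.5)
})

test_that("grid snapshots export as CSV and PGM text", {
  g <- forest_grid(matrix(c(1L, 0L, 0L, 1L), 2, 2))
  f1 <- tempfile(fileext = ".csv")
  write_grid(g, f1)
  back <- as.matrix(utils::read.csv(f1, header = FALSE))
  dimnames(back) <- NULL
  expect_equal(back, g$states)
  f2 <- tempfile(fileext = ".pgm")
  write_grid(g, f2, format = "pgm")
  expect_identical(readLines(f2)[1], "P2")
})
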
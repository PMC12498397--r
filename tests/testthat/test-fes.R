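test_that("reweighting is uniform for zero bias and exponential in dV", {
  p <- double_well_1d(3, 4.4, 3)
  s <- simulate_langevin(
    archetype_potential("inactive"),
    sim_params(n_steps = 2000L, seed = 4))
  wr <- list(window = NULL, series = s, bias = NULL)
  w <- reweight_samples(wr)[[1]]
  expect_true(all(abs(w - 1) < 1e-12))
  # single window + one hill: two-point weight ratio equals exp(beta dV)
  win <- make_window_schedule(2.50, 0.15, 1, 350)[1, ]
  bs <- bias_state(window = win, w0 = 2, sigma = 0.1)
  bs <- deposit_hill(bs, 4.0, t = 1)
  s2 <- s[1:2, ]; s2$s1 <- c(2.50, 2.60); s2$s2 <- c(4.0, 4.1)
  attr(s2, "params") <- attr(s, "params")
  w2 <- reweight_samples(list(window = win, series = s2, bias = bs))[[1]]
  dv <- bias_energy(bs, c(2.60, 4.1)) - bias_energy(bs, c(2.50, 4.0))
  expect_equal(w2[2] / w2[1], exp(dv / kT300), tolerance = 1e-10)
})

test_that("reweighted biased sampling recovers the unbiased density", {
  # sample a harmonic well under a displaced umbrella; over the region the
  # biased run actually covers, the reweighted histogram must reproduce the
  # unbiased Boltzmann density (checked as a density ratio between two
  # points, which is insensitive to the heavy importance-weight tails)
  p <- harmonic_potential(60, 3.4)
  win <- list(center = 3.55, k = 120)
  bs <- bias_state(window = win, w0 = 0, sigma = 0.1, window_cv = 1, meta_cv = 1)
  s <- simulate_langevin(p, sim_params(friction = 5, n_steps = 2e5L, seed = 6),
                         bias = bs, start = 3.6, n_equil = 5000L)
  wr <- list(window = win, series = s, bias = attr(s, "bias"))
  w <- reweight_samples(wr)[[1]]
  at <- function(x0) sum(w[abs(s$s1 - x0) < 0.02])
  ratio <- at(3.45) / at(3.60)
  ratio_true <- exp(-(p$energy(3.45) - p$energy(3.60)) / kT300)
  expect_equal(ratio, ratio_true, tolerance = 0.1)
})

test_that("single-window WHAM degenerates to Boltzmann inversion", {
  p <- archetype_potential("inactive")
  s <- simulate_langevin(p, sim_params(n_steps = 2e5L, seed = 13),
                         n_equil = 5000L)
  spec <- fes_grid_spec(c(2.0, 3.2), c(3.8, 5.2), 24, 28)
  g <- boltzmann_invert(s, spec, min_count = 20)
  ctr <- as.matrix(expand.grid(spec$xcenters, spec$ycenters))
  Ftrue <- matrix(p$energy(ctr), spec$nx, spec$ny)
  d <- (g$F - Ftrue)[g$sampled_mask]
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), kT300)
})

test_that("two overlapping windows on a linear potential recover the slope", {
  # the ramp is steep (15 kJ/mol/A) so the 5% check probes the window
  # matching itself rather than sub-noise free-energy differences
  slope_true <- 15
  p <- model_potential("ramp",
                       energy = function(s) {
                         if (is.matrix(s)) return(slope_true * s[, 1] + 0.5 * 30 * (s[, 2] - 4)^2)
                         slope_true * s[1] + 0.5 * 30 * (s[2] - 4)^2
                       },
                       gradient = function(s) c(slope_true, 30 * (s[2] - 4)),
                       dim = 2L, check = FALSE)
  sch <- make_window_schedule(3.0, 0.15, 2, 100, equilibration_time = 2,
                              production_time = 1500)
  runs <- run_window_schedule(p, sch, sim_params(n_steps = 1L, seed = 14),
                              w0 = 0, start = c(3.0, 4.0),
                              wall_lo = NULL, wall_hi = NULL)
  spec <- fes_grid_spec(c(2.4, 3.6), c(3.4, 4.6), 30, 12)
  g <- wham_2d(runs, spec, min_count = 200, restrict_to_windows = FALSE)$grid
  # regress out the analytic transverse bowl and fit the slope over all
  # well-sampled bins
  pts <- which(g$sampled_mask, arr.ind = TRUE)
  x <- spec$xcenters[pts[, 1]]; y2 <- spec$ycenters[pts[, 2]]
  keep <- abs(y2 - 4) < 0.3
  z <- g$F[pts][keep] - 0.5 * 30 * (y2[keep] - 4)^2
  fit <- coef(lm(z ~ x[keep]))
  expect_equal(unname(fit[2]), slope_true, tolerance = 0.05 * slope_true)
})

test_that("gauge invariance: a constant added to every window bias cancels", {
  run <- archetype_run("dissociative")
  g1 <- run$grid
  # add a constant-in-space bias (one enormous-width hill of height 5 kJ/mol,
  # stamped before all real hills) to every window
  runs2 <- lapply(run$runs, function(wr) {
    wr$bias$hills <- rbind(
      data.frame(time = -1, center = 4, sigma = 1e6, height = 5),
      wr$bias$hills)
    wr
  })
  g2 <- wham_2d(runs2, fes_grid_spec())$grid
  expect_equal(g2$F, g1$F, tolerance = 1e-6)
})

test_that("restarting WHAM from its converged state stops within 2 iterations", {
  run <- archetype_run("dissociative")
  expect_true(run$wham$converged)
  wh2 <- wham_2d(run$runs, fes_grid_spec(), f_init = run$wham$f)
  expect_lte(wh2$wham$iterations, 2)
})

test_that("attack split partitions samples with the 90-degree tie to cis", {
  df <- data.frame(alpha = c(60, 135, 90, 10, 120), x = 1:5)
  sp <- split_by_attack(df)
  expect_equal(nrow(sp$cis) + nrow(sp$trans), 5)
  expect_true(all(c(60, 90, 10) %in% sp$cis$alpha))
  expect_true(all(c(135, 120) %in% sp$trans$alpha))
})

test_that("find_features sees exactly the constructed minima and saddles", {
  # single (slightly off-centre, so bins do not tie) paraboloid
  xs <- seq(-1, 1, length.out = 30)
  F1 <- outer(xs, xs, function(a, b) 10 * ((a - 0.03)^2 + (b + 0.07)^2))
  g1 <- grid_from_matrix(F1)
  f1 <- find_features(g1, 0.5)
  expect_equal(sum(f1$kind == "minimum"), 1)
  expect_equal(sum(f1$kind == "saddle"), 0)
  # double well with a 5 kJ/mol barrier (off-centre to avoid bin ties)
  F2 <- outer(xs, xs, function(a, b)
    5 * (a^2 - 0.49)^2 / 0.49^2 + 5 * (b + 0.04)^2 + 0.01 * a)
  g2 <- grid_from_matrix(F2)
  f2 <- find_features(g2, 2.5)
  expect_equal(sum(f2$kind == "minimum"), 2)
  expect_equal(sum(f2$kind == "saddle"), 1)
  sad <- f2[f2$kind == "saddle", ]
  expect_lt(abs(sad$F - 5), 0.6)  # within a bin's energy span
  # flat grid: no features
  g3 <- grid_from_matrix(matrix(1, 20, 20))
  expect_equal(nrow(find_features(g3, 0.1)), 0)
})

test_that("minimum-energy path follows ramps and the lower saddle", {
  # monotone ramp (with a faint transverse bowl so the optimum is unique)
  F <- outer(1:20, 1:20, function(i, j) i + 0.001 * (j - 10)^2)
  g <- grid_from_matrix(F)
  pth <- minimum_energy_path(g, c(1, 10), c(20, 10))
  expect_equal(attr(pth, "max_F"), max(g$F[, 10]))
  expect_equal(nrow(pth), 20)
  expect_true(all(pth$iy == 10))
  # a ridge row pierced by two gaps of different heights: the path must use
  # the lower gap
  Fs <- outer(1:21, 1:21, function(i, j) 0.001 * (i + j))
  Fs[11, ] <- Fs[11, ] + 10   # ridge
  Fs[11, 5] <- 2              # low saddle
  Fs[11, 17] <- 5             # high saddle
  gs <- grid_from_matrix(Fs)
  pth2 <- minimum_energy_path(gs, c(3, 11), c(19, 11))
  expect_lt(attr(pth2, "max_F"), 2.5)
  expect_true(any(pth2$ix == 11 & pth2$iy == 5))
  expect_false(any(pth2$ix == 11 & pth2$iy == 17))
})

test_that("minimax value agrees with exhaustive enumeration on tiny grids", {
  set.seed(31)
  for (i in 1:25) {
    F <- matrix(runif(12, 0, 10), 3, 4)
    g <- grid_from_matrix(F)
    pth <- minimum_energy_path(g, c(1, 1), c(3, 4))
    expect_equal(attr(pth, "max_F"), oracle_minimax_dfs(g$F, c(1, 1), c(3, 4)))
  }
})

test_that("disconnected masks raise a no-path error naming the level", {
  F <- matrix(0, 9, 9)
  counts <- matrix(1e6, 9, 9); counts[5, ] <- 0  # severing column
  spec <- fes_grid_spec(c(0, 1), c(0, 1), 9, 9)
  g <- fes_grid(spec, F, counts, min_count = 1)
  expect_error(minimum_energy_path(g, c(1, 1), c(9, 9)), "no sampled path")
})

test_that("smoothing removes bin noise without moving a deep minimum", {
  xs <- seq(-1, 1, length.out = 40)
  F <- outer(xs, xs, function(a, b) 8 * (a^2 + b^2))
  set.seed(17)
  g <- grid_from_matrix(F + matrix(rnorm(1600, sd = 1.0), 40, 40))
  raw <- find_features(g, 1.0)
  sm <- find_features(smooth_fes(g, 1.5), 1.0)
  expect_lt(sum(sm$kind == "minimum"), sum(raw$kind == "minimum"))
  m <- sm[sm$kind == "minimum", ][1, ]
  expect_lt(abs(m$s1 - 0.5) + abs(m$s2 - 0.5), 0.25)  # center is (0.5, 0.5) in grid units
})
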
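test_that("attack statistics report percentages among qualifying samples", {
  all_cis <- data.frame(alpha = rep(60, 50), d_RuOmin = rep(3, 50))
  st <- attack_statistics(all_cis, 4.0)
  expect_equal(st$cis_pct, 100.0)
  expect_equal(st$trans_pct, 0.0)
  # cutoff excludes everything: explicit empty result, not 0/0
  far <- data.frame(alpha = rep(60, 50), d_RuOmin = rep(5, 50))
  st2 <- attack_statistics(far, 4.0)
  expect_true(st2$empty)
  expect_true(is.na(st2$cis_pct))
  expect_error(attack_statistics(all_cis, -1))
})

test_that("generated attack fractions are recovered within the binomial CI", {
  p_true <- 0.627
  n <- 10000L
  g <- generate_attack_series(n, p_true, cutoff = 4.0, seed = 42)
  st <- attack_statistics(g, 4.0)
  expect_equal(st$n_qualifying, n)
  half <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / n) * 100
  expect_lt(abs(st$cis_pct - 62.7), half)
  expect_equal(st$cis_pct + st$trans_pct, 100)
})

test_that("electronic-state labels follow the spin/geometry anchors", {
  thr <- state_thresholds()
  lab <- function(spin, ds, do)
    label_state(data.frame(spin_Ru = spin, d_RuS = ds, d_RuOmin = do), thr)
  expect_equal(lab(0.7, 2.3, 5.0), "MLCT")
  expect_equal(lab(1.3, 3.0, 5.0), "MC")
  expect_equal(lab(0.8, 4.5, 2.2), "P")
  expect_equal(lab(0.95, 4.5, 4.5), "pentacoordinate")
  expect_equal(lab(0.95, 3.5, 3.5), "unassigned")
  expect_error(lab(NA, 2.3, 5.0), "spin")
  expect_error(state_thresholds(mc_spin = 0.5), "mc_spin")
})

test_that("absorption region uses per-axis 1.96 sigma and scales linearly", {
  set.seed(40)
  xy <- data.frame(s1 = rnorm(50000, 2.4, 0.05), s2 = rnorm(50000, 4.4, 0.12))
  class(xy) <- c("cv_series", "data.frame")
  r <- absorption_region(xy)
  expect_equal(unname(r$center), c(2.4, 4.4), tolerance = 0.01)
  expect_equal(unname(r$semi_axes), 1.96 * c(0.05, 0.12), tolerance = 0.02)
  # empirical coverage equals the convention's own analytic value for
  # independent normals: P(chi2_2 <= ...) of the ellipse, about 0.853
  inside <- in_region(r, xy$s1, xy$s2)
  cover_analytic <- mean(in_region(
    list(center = c(0, 0), semi_axes = c(1.96, 1.96)),
    rnorm(2e5), rnorm(2e5)))
  expect_equal(mean(inside), cover_analytic, tolerance = 0.01)
  # doubling the spread doubles the semi-axes
  xy2 <- xy; xy2$s1 <- 2.4 + 2 * (xy$s1 - 2.4); xy2$s2 <- 4.4 + 2 * (xy$s2 - 4.4)
  r2 <- absorption_region(xy2)
  expect_equal(unname(r2$semi_axes), 2 * unname(r$semi_axes), tolerance = 1e-9)
  # constant series: degenerate flagged region
  cst <- data.frame(s1 = rep(2.4, 200), s2 = rep(4.4, 200))
  expect_warning(r3 <- absorption_region(cst), "degenerate")
  expect_true(r3$degenerate)
})

# build a clean analytic grid from a potential for classifier rule checks
clean_grid <- function(pot, nx = 80, ny = 80) {
  spec <- fes_grid_spec(c(2.0, 6.0), c(2.0, 6.0), nx, ny)
  ctr <- as.matrix(expand.grid(spec$xcenters, spec$ycenters))
  F <- matrix(pot$energy(ctr), nx, ny)
  fes_grid(spec, F, counts = matrix(1e6, nx, ny), min_count = 1)
}

fixed_region <- function() {
  structure(list(center = c(2.55, 4.5), semi_axes = c(0.26, 0.26), z = 1.96,
                 degenerate = FALSE), class = "absorption_region")
}

test_that("an intermediate at Ru-Omin 3.75 A classifies as associative", {
  # heptacoordinate station exactly margin-deep inside the cutoff
  f <- function(x, y, A, wx, wy) data.frame(x = x, y = y, A = A, wx = wx, wy = wy)
  pot <- channel_potential(
    "boundary hepta",
    waypoints = rbind(c(2.55, 4.5), c(3.0, 3.75), c(4.3, 3.4), c(5.0, 2.3)),
    wells = rbind(f(2.55, 4.5, -6, 0.30, 0.40),
                  f(2.78, 4.12, 3, 0.20, 0.20),  # TS pinch
                  f(3.0, 3.75, -5, 0.28, 0.28),
                  f(5.0, 2.3, -7, 0.40, 0.35)))
  # y-bin width 0.1 puts a bin center exactly at 3.75 Angstrom
  g <- clean_grid(pot, nx = 80, ny = 40)
  rep <- classify_mechanism(g, g, fixed_region(), smooth_sigma = 0)
  expect_equal(rep$mechanism, "associative")
  expect_true(rep$borderline)
})

test_that("raising the cutoff walks verdicts toward the associative side", {
  run <- archetype_run("interchange_associative")
  region <- mlct_region()
  verdict <- function(cutoff) {
    classify_mechanism(run$grid, run$grid, region,
                       state_thresholds(interaction_cutoff = cutoff),
                       spin_field = spin_surrogate)$mechanism
  }
  order_rank <- c(dissociative = 1, interchange_dissociative = 2,
                  interchange = 3, interchange_associative = 4,
                  associative = 5)
  ranks <- order_rank[vapply(c(3.6, 4.0, 4.4), verdict, character(1))]
  expect_true(all(diff(ranks) >= 0))
})
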
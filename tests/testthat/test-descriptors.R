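test_that("dihedral folding treats both bending directions equally", {
  expect_equal(fold_theta(-30), 30)
  expect_equal(fold_theta(150), 30)   # planes are unordered; 180 is coplanar
  expect_equal(fold_theta(90), 90)
  expect_equal(fold_theta(0), 0)
  expect_equal(fold_theta(180), 0)
  # idempotent and even over a sweep
  th <- seq(-360, 360, by = 7.3)
  expect_equal(fold_theta(fold_theta(th)), fold_theta(th))
  expect_equal(fold_theta(-th), fold_theta(th))
  expect_true(all(fold_theta(th) >= 0 & fold_theta(th) <= 90))
})

test_that("planarity and rigidity are the folded mean and sd", {
  p <- planarity_rigidity(rep(12.1, 100))
  expect_equal(p$mu_theta, 12.1)
  expect_equal(p$sigma_theta, 0)
  p2 <- planarity_rigidity(c(0, 90))
  expect_equal(p2$mu_theta, 45)
  expect_equal(p2$sigma_theta, 45)  # population convention
  p3 <- planarity_rigidity(c(0, 90), population = FALSE)
  expect_equal(p3$sigma_theta, sd(c(0, 90)))
  expect_error(planarity_rigidity(numeric(0)), "2 frames")
})

test_that("planarity recovers the dihedral generator's parameters", {
  for (m in c(15, 47.1, 58.7, 69)) {
    th <- generate_theta_series(m, 6, n = 20000L, seed = round(m * 10))
    p <- planarity_rigidity(th)
    expect_lt(abs(p$mu_theta - m) / m, 0.02)
    expect_lt(abs(p$sigma_theta - 6) / 6, 0.10)
  }
})

test_that("spearman rho matches the printed table analysis and the oracle", {
  tabs <- compound_tables()
  r_mc <- spearman_rank(tabs$photophysics$phi_515, tabs$barriers$dE_MLCT_MC)
  r_ts <- spearman_rank(tabs$photophysics$phi_515, tabs$barriers$dE_MLCT_TS)
  expect_equal(round(r_mc$rho, 2), -0.40)
  expect_equal(round(r_ts$rho, 2), -0.43)
  expect_gt(r_mc$p_value, 0.05)  # not significant, as reported
  expect_equal(r_mc$method, "exact permutation")
  # perfect monotone association
  r1 <- spearman_rank(1:8, (1:8)^3)
  expect_equal(r1$rho, 1)
  expect_lt(r1$p_value, 0.001)
  # ties: rho equals the longhand midrank Pearson oracle
  set.seed(44)
  for (i in 1:10) {
    x <- sample(1:4, 6, replace = TRUE)
    y <- rnorm(6)
    expect_equal(spearman_rank(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
  expect_error(spearman_rank(rep(1, 5), 1:5), "constant")
})

test_that("spearman is invariant under monotone transforms", {
  set.seed(45)
  x <- rnorm(9); y <- rnorm(9)
  r0 <- spearman_rank(x, y)
  expect_equal(spearman_rank(exp(x), y)$rho, r0$rho)
  expect_equal(spearman_rank(x, y^3 + 5 * y)$rho, r0$rho)
  expect_equal(spearman_rank(exp(x), y)$p_value, r0$p_value)
})

test_that("exact permutation p agrees with cor.test on untied small samples", {
  set.seed(46)
  x <- rnorm(7); y <- rnorm(7)
  mine <- spearman_rank(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("linear fits reproduce the printed R2 and the normal equations", {
  tabs <- compound_tables()
  f_mc <- linear_fit_ci(tabs$barriers$dE_MLCT_MC, tabs$photophysics$phi_515)
  f_ts <- linear_fit_ci(tabs$barriers$dE_MLCT_TS, tabs$photophysics$phi_515)
  expect_equal(round(f_mc$R2, 2), 0.01)
  expect_equal(round(f_ts$R2, 2), 0.01)
  # exactly linear data: perfect fit, zero-width band
  xx <- 1:6; yy <- 2 + 3 * xx
  fl <- linear_fit_ci(xx, yy)
  expect_equal(fl$R2, 1)
  expect_equal(fl$residual_se, 0, tolerance = 1e-12)
  expect_equal(max(fl$band$half_width), 0, tolerance = 1e-10)
  # 5-point set vs brute-force normal equations
  set.seed(47)
  x5 <- rnorm(5); y5 <- rnorm(5)
  f5 <- linear_fit_ci(x5, y5)
  o5 <- oracle_ols(x5, y5)
  expect_equal(f5$slope, o5$slope, tolerance = 1e-10)
  expect_equal(f5$intercept, o5$intercept, tolerance = 1e-10)
  expect_equal(f5$R2, o5$R2, tolerance = 1e-10)
  expect_error(linear_fit_ci(rep(2, 5), rnorm(5)), "constant")
})

test_that("the 95% band covers the true mean response at its nominal rate", {
  # pointwise coverage of the t-scaled band (the band is pointwise by
  # construction; simultaneous whole-line coverage is necessarily lower)
  set.seed(48)
  n <- 10; x <- seq(0, 1, length.out = n)
  hits <- replicate(1000, {
    y <- 1 + 2 * x + rnorm(n, sd = 0.5)
    f <- linear_fit_ci(x, y)
    truth <- 1 + 2 * x
    mean(abs(truth - f$band$fit) <= f$band$half_width + 1e-12)
  })
  expect_gte(mean(hits), 0.93)
})

test_that("fixture tables carry the full nine-complex series", {
  tabs <- compound_tables(zero_inactive = FALSE)
  expect_equal(nrow(tabs$photophysics), 9)
  expect_equal(nrow(tabs$barriers), 9)
  expect_equal(nrow(tabs$attack), 9)
  expect_true(is.na(tabs$photophysics$phi_515[1]))  # inactive complex
  expect_false(tabs$photophysics$photoactive[1])
  expect_true(all(tabs$attack$cis_pct + tabs$attack$trans_pct == 100))
  tz <- compound_tables()
  expect_equal(tz$photophysics$phi_515[1], 0)  # zero-assignment rule
})
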
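test_that("window schedules form the documented arithmetic progression", {
  sch <- make_window_schedule(2.50, 0.15, 20, 350)
  expect_equal(nrow(sch), 20)
  expect_equal(sch$center[1], 2.50)
  expect_equal(sch$center[20], 5.35)
  one <- make_window_schedule(2.50, 0.15, 1, 350)
  expect_equal(one$center, 2.50)
  # arbitrary progressions against a loop oracle
  set.seed(8)
  for (i in 1:5) {
    a <- runif(1, 1, 3); d <- runif(1, 0.05, 0.4); n <- sample(2:30, 1)
    sch <- make_window_schedule(a, d, n, 100)
    loop <- numeric(n); loop[1] <- a
    for (k in 2:n) loop[k] <- loop[k - 1] + d
    expect_equal(sch$center, loop)
    expect_equal(sch$center[n], a + (n - 1) * d)
  }
})

test_that("umbrella energy is the harmonic restraint with exact gradient", {
  w <- make_window_schedule(2.50, 0.15, 1, 350)[1, ]
  expect_equal(umbrella_energy(w, 2.50), 0)
  expect_equal(umbrella_energy(w, 2.60), 0.5 * 350 * 0.01)
  set.seed(2)
  for (i in 1:10) {
    w2 <- list(center = runif(1, 2, 5), k = runif(1, 50, 500))
    s <- runif(1, 2, 5)
    fd <- (umbrella_energy(w2, s + 1e-6) - umbrella_energy(w2, s - 1e-6)) / 2e-6
    expect_equal(-umbrella_force(w2, s), fd, tolerance = 1e-5)
  }
})

test_that("well-tempered deposition follows the tempering rule", {
  st <- bias_state(w0 = 2.0, sigma = 0.1, bias_factor = 15, temperature = 300)
  st <- deposit_hill(st, 3.0, t = 1)
  expect_equal(st$hills$height[1], 2.0)  # first deposit is always w0
  # repeated deposits at one point: k-th height = w0 exp(-V_{k-1}/(kB dT))
  dT <- 14 * 300
  for (k in 2:8) {
    v_prev <- oracle_hill_sum(st$hills, 3.0)
    st <- deposit_hill(st, 3.0, t = k)
    expect_equal(st$hills$height[k],
                 2.0 * exp(-v_prev / (photosub::KB_KJMOL * dT)),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(st$hills$height) < 0))
  # standard metadynamics limit: gamma -> Inf keeps heights at w0
  stI <- bias_state(w0 = 2.0, sigma = 0.1, bias_factor = Inf)
  for (k in 1:5) stI <- deposit_hill(stI, 3.0, t = k)
  expect_true(all(stI$hills$height == 2.0))
  expect_error(bias_state(bias_factor = 1), "bias_factor")
})

test_that("bias energy equals brute-force summation and respects time", {
  st <- bias_state(w0 = 2.0, sigma = 0.1)
  expect_equal(bias_energy(st, 3.3), 0)
  st <- deposit_hill(st, 3.0, t = 1)
  expect_equal(bias_energy(st, 3.0), 2.0)
  expect_equal(bias_energy(st, 3.1), 2.0 * exp(-0.5))
  expect_equal(bias_energy(st, 3.0, t = 0.5), 0)  # hill not yet deposited
  # 500 random hills vs the oracle
  set.seed(11)
  st$hills <- data.frame(time = seq_len(500),
                         center = runif(500, 2, 6),
                         sigma = runif(500, 0.05, 0.3),
                         height = runif(500, 0.1, 2))
  q <- runif(50, 2, 6)
  expect_equal(unname(vapply(q, function(x) bias_energy(st, x), numeric(1))),
               unname(oracle_hill_sum(st$hills, q)), tolerance = 1e-10)
})

test_that("total bias force matches finite differences of the energy", {
  sch <- make_window_schedule(2.50, 0.15, 3, 350)
  st <- bias_state(window = sch[2, ], w0 = 2.0, sigma = 0.1,
                   wall_lo = 2.1, wall_hi = 5.9)
  set.seed(3)
  for (k in 1:6) st <- deposit_hill(st, runif(1, 2.2, 5.8), t = k)
  for (i in 1:8) {
    s <- runif(2, 2.2, 5.8)
    fd <- vapply(1:2, function(kk) {
      e <- c(0, 0); e[kk] <- 1e-6
      (bias_energy(st, s + e) - bias_energy(st, s - e)) / 2e-6
    }, numeric(1))
    expect_equal(bias_force(st, s), -fd, tolerance = 1e-5)
  }
})

test_that("HILLS files round-trip through the PLUMED dialect", {
  st <- bias_state(w0 = 2.0, sigma = 0.1, bias_factor = 15)
  set.seed(5)
  for (k in 1:20) st <- deposit_hill(st, runif(1, 2.5, 5.5), t = k * 0.1)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hills(st, path)
  expect_match(readLines(path, n = 1), "^#! FIELDS time center sigma height")
  back <- read_hills(path)
  expect_equal(back$hills, st$hills, tolerance = 1e-15)
  expect_equal(back$bias_factor, 15)
  bad <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("nonsense", "1 2 3"), bad)
  expect_error(read_hills(bad), "FIELDS")
})
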
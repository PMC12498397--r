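# geometry measurements on constructed frames

simple_frame <- function() {
  # Ru at origin, S on +z, chelate in canonical pose, two oxygens
  rbind(c(0, 0, 0),            # Ru
        c(0, 0, 2.3),          # S
        c(2.1, 0, 0),          # N_C
        c(2.8, 0, 1.2),        # C_C
        c(0, 0, -2.1),         # N_T
        c(1.3, 0, -2.1),       # C_T  (coplanar with the cis plane)
        c(3.0, 0, 0),          # O at 3.0
        c(0, 3.5, 0))          # O at 3.5
}

test_that("measure_cv picks the nearest oxygen and its angle", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  cv <- measure_cv(simple_frame(), roles)
  expect_equal(cv$d_RuS, 2.3)
  expect_equal(cv$d_RuOmin, 3.0)
  expect_equal(cv$alpha, 90)  # O on +x, S on +z
  expect_false(cv$monodentate)
  # swap which oxygen is closest
  fr <- simple_frame(); fr[8, ] <- c(0, 2.8, 0)
  cv2 <- measure_cv(fr, roles)
  expect_equal(cv2$d_RuOmin, 2.8)
  expect_equal(cv2$alpha, 90)
})

test_that("measured minimum distance equals exhaustive search on random frames", {
  set.seed(6)
  for (i in 1:100) {
    n_o <- sample(3:20, 1)
    fr <- rbind(simple_frame()[1:6, ], matrix(rnorm(3 * n_o, sd = 3), n_o, 3))
    roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 6 + seq_len(n_o))
    cv <- measure_cv(fr, roles)
    dd <- apply(fr[6 + seq_len(n_o), , drop = FALSE], 1,
                function(o) sqrt(sum(o^2)))
    expect_equal(cv$d_RuOmin, min(dd))
  }
})

test_that("missing role atoms are rejected by name", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  expect_error(measure_cv(simple_frame()[1:5, ], roles), "solvent_O")
  roles2 <- role_map(1, 2, 3, 4, 5, 20, solvent_O = 7:8)
  expect_error(measure_cv(simple_frame(), roles2), "C_T")
})

test_that("chelate dihedral matches an independent normal/atan2 oracle", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  # coplanar chelate: theta = 0
  expect_equal(chelate_dihedral(simple_frame(), roles), 0, tolerance = 1e-10)
  # rotate the trans half-plane by 90 degrees about z
  fr <- simple_frame(); fr[6, ] <- c(0, 1.3, -2.1)
  expect_equal(fold_theta(chelate_dihedral(fr, roles)), 90, tolerance = 1e-10)
  # random configurations vs oracle
  set.seed(9)
  for (i in 1:50) {
    fr <- simple_frame()
    fr[3:6, ] <- fr[3:6, ] + matrix(rnorm(12, sd = 0.4), 4, 3)
    th <- chelate_dihedral(fr, roles)
    n1 <- oracle_cross(fr[3, ], fr[4, ])
    n2 <- oracle_cross(fr[5, ], fr[6, ])
    ang <- atan2(sqrt(sum(oracle_cross(n1, n2)^2)), sum(n1 * n2)) * 180 / pi
    expect_equal(abs(th), ang, tolerance = 1e-6)
  }
})

test_that("collinear plane atoms raise an undefined-plane error", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  fr <- simple_frame(); fr[4, ] <- 2 * fr[3, ]  # C_C on the Ru-N_C line
  expect_error(chelate_dihedral(fr, roles), "degenerate")
})

test_that("CVs are invariant under rigid rotation and translation", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  fr <- simple_frame()
  cv0 <- measure_cv(fr, roles)
  set.seed(10)
  for (i in 1:10) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    tr <- matrix(rnorm(3, sd = 5), nrow(fr), 3, byrow = TRUE)
    fr2 <- fr %*% t(Rx %*% Rz) + tr
    cv <- measure_cv(fr2, roles)
    expect_equal(cv$d_RuS, cv0$d_RuS, tolerance = 1e-9)
    expect_equal(cv$d_RuOmin, cv0$d_RuOmin, tolerance = 1e-9)
    expect_equal(cv$alpha, cv0$alpha, tolerance = 1e-9)
    expect_equal(cv$theta, cv0$theta, tolerance = 1e-9)
  }
})

test_that("monodentate-like frames are flagged, not dropped", {
  roles <- role_map(1, 2, 3, 4, 5, 6, solvent_O = 7:8)
  fr <- simple_frame(); fr[3, ] <- c(4.5, 0, 0)  # Ru-N_C broken
  cv <- measure_cv(fr, roles)
  expect_true(cv$monodentate)
  expect_true(is.finite(cv$theta))
})

test_that("quasi-uniform subsampling is greedy farthest-point", {
  # identity when asked for everything
  df <- data.frame(s1 = runif(20, 2, 6), s2 = runif(20, 2, 6))
  out <- quasi_uniform_subsample(df, 20)
  expect_equal(nrow(out), 20)
  expect_equal(attr(out, "indices"), 1:20)
  # points on a line: the two extremes
  line <- data.frame(s1 = seq(2, 5, length.out = 11), s2 = seq(2, 5, length.out = 11))
  two <- quasi_uniform_subsample(line, 2)
  expect_setequal(attr(two, "indices"), c(1, 11))
  # the greedy set's min pairwise distance beats random subsets
  set.seed(12)
  cloud <- data.frame(s1 = runif(200, 2, 6), s2 = runif(200, 2, 6))
  sel <- quasi_uniform_subsample(cloud, 10)
  mindist <- function(idx) min(dist(cbind(cloud$s1[idx], cloud$s2[idx])))
  d_greedy <- mindist(attr(sel, "indices"))
  d_rand <- replicate(1000, mindist(sample(200, 10)))
  expect_true(all(d_greedy >= d_rand))
  expect_error(quasi_uniform_subsample(cloud[0, ], 1), "empty")
})
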
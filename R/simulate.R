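# Langevin sampler on model potentials, plus the auxiliary stochastic
# generators (chelate dihedral OU process, attack-angle mixture, Mulliken-spin
# surrogate). The engine evolves the collective variables directly with a
# fictitious mass: only the sampling statistics matter, not the microscopic
# dynamics of the underlying QM/MM system.

#' Simulation parameters
#'
#' @param temperature Kelvin, > 0.
#' @param friction Langevin friction, 1/ps; scalar or one value per CV.
#'   The default damps a harmonically restrained first coordinate near
#'   critically (fast decorrelation under the umbrella restraint) while
#'   keeping the second diffusive enough to traverse its range many times per
#'   window.
#' @param timestep integration step, ps.
#' @param mass fictitious CV mass, amu.
#' @param n_steps number of production steps.
#' @param seed RNG seed; a fixed seed gives a bit-identical trajectory.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(temperature = 300, friction = c(20, 1.5), timestep = 0.002,
                       mass = 1, n_steps = 10000L, seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  stopifnot(all(friction > 0), timestep > 0, mass > 0, n_steps >= 1)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "sim_params")
}

#' Langevin dynamics on a model potential
#'
#' BAOAB-splitting Langevin integrator. The total force is
#' `-grad(energy + bias)` plus friction and Gaussian noise obeying
#' fluctuation-dissipation at `params$temperature`. If the attached
#' [bias_state()] has `w0 > 0`, a well-tempered hill is deposited every
#' `pace` steps during production (PLUMED-style, counting frames).
#'
#' @param potential a [model_potential()].
#' @param params a [sim_params()].
#' @param bias optional [bias_state()]; `NULL` for unbiased sampling.
#' @param start starting CV vector; defaults to the potential's first known
#'   minimum.
#' @param n_equil equilibration steps discarded before recording (no hills are
#'   deposited during equilibration).
#' @param record_every record every k-th production step.
#' @param t0 time origin (ps) for the recorded series and hill stamps.
#' @return data.frame of class `cv_series` with columns `time`, `s1` (and `s2`
#'   in 2D), with attributes `bias` (final bias state incl. deposited hills)
#'   and `params`.
#' @export
simulate_langevin <- function(potential, params, bias = NULL, start = NULL,
                              n_equil = 0L, record_every = 1L, t0 = 0) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(params, "sim_params"))
  d <- potential$dim
  if (is.null(start)) {
    if (is.null(potential$known_minima))
      stop("no start given and potential has no known minima")
    start <- as.numeric(potential$known_minima[1, ])
  }
  stopifnot(length(start) == d)

  kT <- KB_KJMOL * params$temperature
  dt <- params$timestep
  m <- params$mass
  c1 <- exp(-rep_len(params$friction, d) * dt)
  c2 <- sqrt(kT / m * (1 - c1^2))

  deposit <- !is.null(bias) && bias$w0 > 0
  has_bias <- !is.null(bias)
  if (has_bias && !is.null(bias$temperature)) bias$temperature <- params$temperature

  # mutable hill storage (preallocated) plus a fine grid cache of the
  # metadynamics bias: per-step force is linear interpolation on the cache,
  # each deposit updates only the grid points within 6 sigma of the hill
  if (has_bias) {
    n_max <- if (deposit) params$n_steps %/% bias$pace + 1L else 0L
    h_time <- numeric(n_max); h_center <- numeric(n_max); h_height <- numeric(n_max)
    nh <- nrow(bias$hills)
    if (nh > 0) {  # carry over pre-existing hills
      h_time <- c(bias$hills$time, h_time)
      h_center <- c(bias$hills$center, h_center)
      h_height <- c(bias$hills$height, h_height)
    }
    sig2 <- 2 * bias$sigma^2
    mcv <- min(bias$meta_cv, d)
    wcv <- if (!is.null(bias$window)) min(bias$window_cv, d) else 0L
    dT <- (bias$bias_factor - 1) * params$temperature
    w_center <- if (wcv > 0) bias$window$center else 0
    w_k <- if (wcv > 0) bias$window$k else 0
    # bias cache over a generous CV range
    g_lo <- 0; g_h <- 0.01
    g_x <- seq(g_lo, 10, by = g_h)
    g_V <- numeric(length(g_x)); g_F <- numeric(length(g_x))
    add_to_cache <- function(center, w) {
      r <- range(max(1L, floor((center - 6 * bias$sigma - g_lo) / g_h) + 1L),
                 min(length(g_x), ceiling((center + 6 * bias$sigma - g_lo) / g_h) + 1L))
      idx <- r[1]:r[2]
      dd <- g_x[idx] - center
      e <- w * exp(-dd^2 / sig2)
      g_V[idx] <<- g_V[idx] + e
      g_F[idx] <<- g_F[idx] + e * dd / bias$sigma^2
    }
    if (nh > 0) for (i in seq_len(nh)) add_to_cache(h_center[i], h_height[i])
    cache_at <- function(x, vals) {
      if (x <= g_lo || x >= 10) return(0)
      i <- floor((x - g_lo) / g_h) + 1L
      w1 <- (x - g_x[i]) / g_h
      (1 - w1) * vals[i] + w1 * vals[i + 1L]
    }
  }

  bias_f <- function(x) {
    f <- numeric(d)
    if (!has_bias) return(f)
    if (nh > 0) f[mcv] <- cache_at(x[mcv], g_F)
    f[mcv] <- f[mcv] + wall_force(bias, x[mcv])
    if (wcv > 0) f[wcv] <- f[wcv] - w_k * (x[wcv] - w_center)
    f
  }

  n_tot <- n_equil + params$n_steps
  set.seed(params$seed)
  noise <- matrix(stats::rnorm(n_tot * d), n_tot, d)

  n_rec <- params$n_steps %/% record_every
  rec <- matrix(NA_real_, n_rec, d)
  rec_t <- numeric(n_rec)

  x <- as.numeric(start)
  v <- numeric(d)  # start at rest; equilibration thermalises
  f <- -potential$gradient(x) + bias_f(x)
  if (any(!is.finite(f)) || !is.finite(potential$energy(x)))
    stop("non-finite energy/force at the starting point")

  irec <- 0L
  for (step in seq_len(n_tot)) {
    v <- v + (dt / 2) * f / m
    x <- x + (dt / 2) * v
    v <- c1 * v + c2 * noise[step, ]
    x <- x + (dt / 2) * v
    f <- -potential$gradient(x) + bias_f(x)
    if (any(!is.finite(f)))
      stop("non-finite force at step ", step, " (position ",
           paste(signif(x, 6), collapse = ", "), ")")
    v <- v + (dt / 2) * f / m

    if (step > n_equil) {
      pstep <- step - n_equil
      t_now <- t0 + pstep * dt
      if (deposit && pstep %% bias$pace == 0L) {
        s_now <- x[mcv]
        v_here <- if (nh > 0) cache_at(s_now, g_V) else 0
        w <- if (is.infinite(bias$bias_factor)) bias$w0
             else bias$w0 * exp(-v_here / (KB_KJMOL * dT))
        nh <- nh + 1L
        if (nh > length(h_time)) {  # carried-over hills shifted capacity
          h_time <- c(h_time, numeric(64)); h_center <- c(h_center, numeric(64))
          h_height <- c(h_height, numeric(64))
        }
        h_time[nh] <- t_now; h_center[nh] <- s_now; h_height[nh] <- w
        add_to_cache(s_now, w)
        f <- -potential$gradient(x) + bias_f(x)
      }
      if (pstep %% record_every == 0L) {
        irec <- irec + 1L
        rec[irec, ] <- x
        rec_t[irec] <- t_now
      }
    }
  }

  out <- data.frame(time = rec_t[seq_len(irec)])
  for (k in seq_len(d)) out[[paste0("s", k)]] <- rec[seq_len(irec), k]
  class(out) <- c("cv_series", "data.frame")
  if (has_bias) {
    bias$hills <- data.frame(time = h_time[seq_len(nh)],
                             center = h_center[seq_len(nh)],
                             sigma = rep(bias$sigma, nh),
                             height = h_height[seq_len(nh)])
    attr(out, "bias") <- bias
  }
  attr(out, "params") <- params
  out
}

#' Run an umbrella-window schedule with per-window metadynamics
#'
#' Sequentially simulates each window of a schedule: the umbrella restraint is
#' recentred window by window (mimicking pulling the Ru-S bond outward in 0.15
#' Angstrom increments) while a well-tempered metadynamics bias acts along the
#' second coordinate. The starting configuration of each window is the final
#' configuration of the previous one; by default the hill list is reset per
#' window (`persist_hills = FALSE` mirrors the per-window production runs).
#'
#' @param potential a 2D [model_potential()].
#' @param schedule a [make_window_schedule()].
#' @param params a [sim_params()]; `n_steps` is ignored (window times rule).
#' @param w0,sigma,bias_factor,pace metadynamics settings (see [bias_state()]).
#' @param start starting CV vector for the first window.
#' @param record_every record every k-th step.
#' @param persist_hills carry hills across windows instead of resetting
#'   (default: carry; the converged bias makes late windows sample close to
#'   equilibrium, which the reweighting estimators rely on).
#' @param wall_lo,wall_hi,wall_k restraining walls on the metadynamics CV
#'   (see [bias_state()]); `NULL` disables them.
#' @param n_walkers number of independent replicas of the whole schedule
#'   (seeds offset per walker); all windows of all walkers are returned and
#'   pooled by [wham_2d()].
#' @return flat list of per-window results, each `list(window, series, bias)`.
#' @export
run_window_schedule <- function(potential, schedule, params,
                                w0 = 2.0, sigma = 0.1, bias_factor = 15,
                                pace = 50L, start = NULL, record_every = 1L,
                                persist_hills = TRUE,
                                wall_lo = 2.05, wall_hi = 5.95, wall_k = 1000,
                                n_walkers = 1L) {
  stopifnot(potential$dim == 2L, inherits(schedule, "umbrella_schedule"))
  dt <- params$timestep
  res <- list()
  for (wk in seq_len(n_walkers)) {
    x0 <- if (is.null(start)) c(schedule$center[1],
                                potential$known_minima[1, 2]) else start
    carry <- NULL
    for (j in seq_len(nrow(schedule))) {
      win <- schedule[j, ]
      bs <- bias_state(window = win, w0 = w0, sigma = sigma,
                       bias_factor = bias_factor, pace = pace,
                       temperature = params$temperature,
                       wall_lo = wall_lo, wall_hi = wall_hi, wall_k = wall_k)
      if (persist_hills && !is.null(carry)) bs$hills <- carry
      pj <- sim_params(temperature = params$temperature,
                       friction = params$friction, timestep = dt,
                       mass = params$mass,
                       n_steps = round(win$production_time / dt),
                       seed = params$seed + j + 7919L * (wk - 1L))
      series <- simulate_langevin(potential, pj, bias = bs, start = x0,
                                  n_equil = round(win$equilibration_time / dt),
                                  record_every = record_every,
                                  t0 = ((wk - 1L) * nrow(schedule) + j - 1) *
                                    (win$equilibration_time + win$production_time))
      bfinal <- attr(series, "bias")
      if (persist_hills) carry <- bfinal$hills
      x0 <- c(series$s1[nrow(series)], series$s2[nrow(series)])
      res[[length(res) + 1L]] <- list(window = win, series = series,
                                      bias = bfinal, walker = wk)
    }
  }
  class(res) <- "window_run"
  res
}

#' Ornstein-Uhlenbeck chelate dihedral series
#'
#' Generates a signed dihedral trajectory theta(t) by exact OU discretisation:
#' `theta[i+1] = mean + phi * (theta[i] - mean) + sd * sqrt(1 - phi^2) * xi`
#' with `phi = exp(-dt / relaxation_time)`. The stationary distribution is
#' N(mean_deg, sd_deg^2); after folding onto [0, 90] (see [fold_theta()]) the
#' recovered planarity converges to `mean_deg` for means away from the fold
#' boundaries.
#'
#' @param mean_deg stationary mean, degrees in [0, 90].
#' @param sd_deg stationary standard deviation, degrees >= 0.
#' @param relaxation_time OU relaxation time, ps.
#' @param n number of frames, >= 1.
#' @param dt sampling interval, ps.
#' @param seed RNG seed.
#' @return numeric vector of signed dihedrals (degrees).
#' @export
generate_theta_series <- function(mean_deg, sd_deg, n, relaxation_time = 1,
                                  dt = 0.2, seed = 1L) {
  if (sd_deg < 0) stop("sd_deg must be >= 0")
  stopifnot(n >= 1, mean_deg >= 0, mean_deg <= 90)
  if (sd_deg == 0) return(rep(mean_deg, n))
  set.seed(seed)
  phi <- exp(-dt / relaxation_time)
  innov <- sd_deg * sqrt(1 - phi^2)
  th <- numeric(n)
  th[1] <- stats::rnorm(1, mean_deg, sd_deg)
  z <- stats::rnorm(n - 1)
  for (i in seq_len(n - 1))
    th[i + 1] <- mean_deg + phi * (th[i] - mean_deg) + innov * z[i]
  th
}

#' Ruthenium Mulliken-spin surrogate
#'
#' Smooth monotone map from the two reaction coordinates to a Ru spin value:
#' about 0.7 while the thioether is bound (Ru-S <= 2.5 A; MLCT character),
#' rising past 1.2 once Ru-S > 4 A with no aqua ligand bound (MC character),
#' and relaxing toward about 0.8 when a water oxygen coordinates
#' (Ru-Omin <= 2.5 A; triplet-product character). Total function; no error
#' states.
#'
#' @param d_RuS Ru-S distance, Angstrom (vectorised).
#' @param d_RuOmin minimum Ru-O(water) distance, Angstrom (vectorised).
#' @return spin value(s), unitless.
#' @export
spin_surrogate <- function(d_RuS, d_RuOmin) {
  g1 <- stats::plogis((d_RuS - 3.25) / 0.25)    # S departure
  g2 <- stats::plogis((2.8 - d_RuOmin) / 0.20)  # aqua coordination
  0.7 + 0.7 * g1 - 0.6 * g1 * g2
}

#' Attack-angle generator
#'
#' Draws per-frame S-Ru-Omin angles from a two-component mixture: with
#' probability `cis_fraction` the approach is cis (angle < 90 deg), otherwise
#' trans (angle > 90 deg). Angles are uniform within (45, 90) and (90, 135);
#' qualifying Ru-Omin distances are uniform below the interaction cutoff.
#' Used to emulate the per-compound attack statistics.
#'
#' @param n number of frames.
#' @param cis_fraction true cis probability.
#' @param cutoff interaction cutoff (Angstrom); generated distances lie in
#'   (2.0, cutoff).
#' @param seed RNG seed.
#' @return data.frame with columns `alpha` (deg) and `d_RuOmin` (Angstrom).
#' @export
generate_attack_series <- function(n, cis_fraction, cutoff = 4.0, seed = 1L) {
  stopifnot(n >= 1, cis_fraction >= 0, cis_fraction <= 1)
  set.seed(seed)
  is_cis <- stats::runif(n) < cis_fraction
  alpha <- ifelse(is_cis, stats::runif(n, 45, 90 - 1e-9),
                  stats::runif(n, 90 + 1e-9, 135))
  data.frame(alpha = alpha, d_RuOmin = stats::runif(n, 2.0, cutoff - 1e-9))
}
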
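# Enhanced-sampling bias objects: harmonic umbrella restraints along Ru-S and
# well-tempered metadynamics hills along Ru-Omin. Both are plain energy/force
# objects shared by the Langevin sampler and the reweighting estimators.

#' Boltzmann constant in kJ/mol/K
#' @export
KB_KJMOL <- 0.0083144626

#' Umbrella window schedule
#'
#' Centers form the arithmetic progression `start, start + step, ...`. The
#' default protocol is 20 windows from 2.50 Angstrom in steps of 0.15 (final
#' center 5.35) with a 350 kJ/mol/A^2 restraint, 5 ps equilibration and 40 ps
#' production per window.
#'
#' @param start first center (Angstrom).
#' @param step center spacing (Angstrom), > 0.
#' @param n_windows number of windows, >= 1.
#' @param k harmonic force constant (kJ/mol/A^2), > 0.
#' @param equilibration_time,production_time per-window times (ps).
#' @return data.frame of class `umbrella_schedule` with one row per window.
#' @export
make_window_schedule <- function(start = 2.50, step = 0.15, n_windows = 20L,
                                 k = 350, equilibration_time = 5,
                                 production_time = 40) {
  stopifnot(n_windows >= 1, step > 0, k > 0)
  out <- data.frame(index = seq_len(n_windows),
                    center = start + (seq_len(n_windows) - 1) * step,
                    k = k,
                    equilibration_time = equilibration_time,
                    production_time = production_time)
  class(out) <- c("umbrella_schedule", "data.frame")
  out
}

#' Harmonic umbrella energy
#'
#' `0.5 * k * (s - s0)^2` for a window (one row of a schedule, or any list with
#' `center` and `k`).
#'
#' @param window list/row with `center` and `k`.
#' @param s position(s) along the restrained CV (Angstrom).
#' @return energy in kJ/mol (vectorised over `s`).
#' @export
umbrella_energy <- function(window, s) 0.5 * window$k * (s - window$center)^2

#' @rdname umbrella_energy
#' @export
umbrella_force <- function(window, s) -window$k * (s - window$center)

#' Create a bias state
#'
#' Bundles an optional umbrella window with a (possibly empty) well-tempered
#' hill series. During simulation, hills are deposited every `pace` integrator
#' steps along coordinate `meta_cv` with the tempered height
#' `w0 * exp(-V(s,t) / (kB * (bias_factor - 1) * temperature))`.
#'
#' @param window optional umbrella window (row of [make_window_schedule()]);
#'   its restraint acts on coordinate `window_cv`.
#' @param w0 initial hill height (kJ/mol). Set to 0 to disable deposition.
#' @param sigma hill width (Angstrom).
#' @param bias_factor well-tempered bias factor (gamma), > 1 (may be `Inf` for
#'   standard non-tempered metadynamics).
#' @param pace steps between deposits.
#' @param temperature system temperature (K) used for tempering.
#' @param meta_cv index of the coordinate carrying the metadynamics bias.
#' @param window_cv index of the coordinate carrying the umbrella restraint.
#' @param wall_lo,wall_hi optional half-harmonic restraining walls on the
#'   metadynamics CV (Angstrom); they confine sampling to the analysis range
#'   so hills are not spent outside it. Like the hills, wall energy is part of
#'   the bias and is removed during reweighting.
#' @param wall_k wall stiffness, kJ/mol/A^2.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(window = NULL, w0 = 2.0, sigma = 0.1, bias_factor = 15,
                       pace = 50L, temperature = 300, meta_cv = 2L,
                       window_cv = 1L, wall_lo = NULL, wall_hi = NULL,
                       wall_k = 1000) {
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  stopifnot(sigma > 0, w0 >= 0, pace >= 1)
  structure(
    list(window = window, w0 = w0, sigma = sigma, bias_factor = bias_factor,
         pace = as.integer(pace), temperature = temperature,
         meta_cv = as.integer(meta_cv), window_cv = as.integer(window_cv),
         wall_lo = wall_lo, wall_hi = wall_hi, wall_k = wall_k,
         hills = data.frame(time = numeric(0), center = numeric(0),
                            sigma = numeric(0), height = numeric(0))),
    class = "bias_state")
}

# Half-harmonic wall energy/force on the metadynamics CV (vectorised).
wall_energy <- function(state, x) {
  e <- numeric(length(x))
  if (!is.null(state$wall_lo)) e <- e + 0.5 * state$wall_k * pmax(state$wall_lo - x, 0)^2
  if (!is.null(state$wall_hi)) e <- e + 0.5 * state$wall_k * pmax(x - state$wall_hi, 0)^2
  e
}
wall_force <- function(state, x) {
  f <- numeric(length(x))
  if (!is.null(state$wall_lo)) f <- f + state$wall_k * pmax(state$wall_lo - x, 0)
  if (!is.null(state$wall_hi)) f <- f - state$wall_k * pmax(x - state$wall_hi, 0)
  f
}

#' @export
print.bias_state <- function(x, ...) {
  cat("<bias_state>", nrow(x$hills), "hills; w0 =", x$w0, "kJ/mol; sigma =",
      x$sigma, "A; gamma =", x$bias_factor, "\n")
  if (!is.null(x$window))
    cat("  umbrella: center", x$window$center, "A, k =", x$window$k, "kJ/mol/A^2\n")
  invisible(x)
}

# Metadynamics bias (hills only) at positions x along the biased CV, using
# hills deposited up to time t. Vectorised over x.
meta_bias <- function(state, x, t = Inf) {
  h <- state$hills
  if (nrow(h) == 0) return(numeric(length(x)) + 0)
  keep <- h$time <= t
  if (!any(keep)) return(numeric(length(x)) + 0)
  c_ <- h$center[keep]; w_ <- h$height[keep]; s_ <- h$sigma[keep]
  vapply(x, function(xi) sum(w_ * exp(-(xi - c_)^2 / (2 * s_^2))), numeric(1))
}

meta_bias_force <- function(state, x, t = Inf) {
  h <- state$hills
  if (nrow(h) == 0) return(0)
  keep <- h$time <= t
  if (!any(keep)) return(0)
  c_ <- h$center[keep]; w_ <- h$height[keep]; s_ <- h$sigma[keep]
  d <- x - c_
  sum(w_ * exp(-d^2 / (2 * s_^2)) * d / s_^2)  # -dV/dx
}

#' Deposit a well-tempered hill
#'
#' Appends one Gaussian hill at the current position of the biased CV. The
#' height follows the well-tempered rule
#' `w = w0 * exp(-V(s,t) / (kB * dT))` with `dT = (bias_factor - 1) *
#' temperature`; the first deposit anywhere therefore has height `w0`, and
#' heights at any revisited point are non-increasing.
#'
#' @param state a [bias_state()].
#' @param s_now current value of the biased CV (Angstrom).
#' @param t current time (ps).
#' @return the updated `bias_state`.
#' @export
deposit_hill <- function(state, s_now, t) {
  v_here <- meta_bias(state, s_now, t)
  w <- if (is.infinite(state$bias_factor)) state$w0 else {
    dT <- (state$bias_factor - 1) * state$temperature
    state$w0 * exp(-v_here / (KB_KJMOL * dT))
  }
  state$hills <- rbind(state$hills,
                       data.frame(time = t, center = s_now,
                                  sigma = state$sigma, height = w))
  state
}

#' Total bias energy at a point
#'
#' Sum of all hills with `deposit_time <= t` evaluated at the biased CV, plus
#' the umbrella term if a window is attached. `s` is the full CV vector (or an
#' n x dim matrix); for a bare 1D metadynamics state a scalar/vector of CV
#' values is accepted.
#'
#' @param state a [bias_state()].
#' @param s CV position(s).
#' @param t evaluation time (ps); only hills deposited at or before `t` count.
#' @return bias energy in kJ/mol.
#' @export
bias_energy <- function(state, s, t = Inf) {
  if (is.matrix(s)) {
    sm <- if (ncol(s) >= state$meta_cv) s[, state$meta_cv] else s[, 1]
    e <- meta_bias(state, sm, t) + wall_energy(state, sm)
    if (!is.null(state$window)) {
      sw <- s[, state$window_cv]
      e <- e + umbrella_energy(state$window, sw)
    }
    return(e)
  }
  if (length(s) == 1) {
    e <- meta_bias(state, s, t) + wall_energy(state, s)
    if (!is.null(state$window)) e <- e + umbrella_energy(state$window, s)
    return(e)
  }
  e <- meta_bias(state, s[state$meta_cv], t) + wall_energy(state, s[state$meta_cv])
  if (!is.null(state$window))
    e <- e + umbrella_energy(state$window, s[state$window_cv])
  e
}

#' Bias force (negative gradient) at a CV vector
#'
#' @param state a [bias_state()].
#' @param s CV vector (length = dim of the sampled space).
#' @param t evaluation time (ps).
#' @return force vector, kJ/mol/A.
#' @export
bias_force <- function(state, s, t = Inf) {
  f <- numeric(length(s))
  mcv <- min(state$meta_cv, length(s))
  f[mcv] <- f[mcv] + meta_bias_force(state, s[mcv], t) + wall_force(state, s[mcv])
  if (!is.null(state$window)) {
    wcv <- min(state$window_cv, length(s))
    f[wcv] <- f[wcv] + umbrella_force(state$window, s[wcv])
  }
  f
}

#' Write / read a PLUMED-dialect HILLS file
#'
#' Header `#! FIELDS time center sigma height biasf`, whitespace-separated
#' columns, full double precision.
#'
#' @param state a [bias_state()] (its hills are written).
#' @param path file path.
#' @return `read_hills` returns a `bias_state` carrying the hills read.
#' @export
write_hills <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  h <- state$hills
  if (nrow(h) > 0) {
    rows <- sprintf("%.17g %.17g %.17g %.17g %.17g",
                    h$time, h$center, h$sigma, h$height,
                    rep(state$bias_factor, nrow(h)))
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#! FIELDS"))
    stop("not a HILLS file (missing '#! FIELDS' header): ", path)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", header), "\\s+")[[1]]
  need <- c("time", "center", "sigma", "height")
  if (!all(need %in% fields))
    stop("HILLS file missing column(s): ",
         paste(setdiff(need, fields), collapse = ", "))
  tab <- utils::read.table(path, skip = 1, col.names = fields,
                           colClasses = "numeric")
  bf <- if ("biasf" %in% fields && nrow(tab) > 0) tab$biasf[1] else 15
  st <- bias_state(w0 = if (nrow(tab) > 0) tab$height[1] else 2.0,
                   sigma = if (nrow(tab) > 0) tab$sigma[1] else 0.1,
                   bias_factor = bf)
  st$hills <- tab[, need]
  st
}
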
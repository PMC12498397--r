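# Analytic model potentials over the (Ru-S, Ru-Omin) collective-variable plane.
# These stand in for the QM/MM triplet hypersurface: each archetype realises one
# ligand-exchange scenario (dissociative, interchange variants, associative,
# photoinactive) as a smooth sum of Gaussian wells/ridges plus confining walls,
# so that the exact free energy is known and the sampling + reconstruction
# machinery can be validated against it.

#' Construct a model potential
#'
#' Wraps an analytic energy/gradient pair into the container used by the
#' Langevin sampler, the WHAM reconstruction and the mechanism classifier.
#'
#' @param name label for the potential.
#' @param energy function; takes a numeric vector of length `dim` (or an
#'   n x dim matrix) and returns energy in kJ/mol (or a vector of energies).
#' @param gradient function; takes a numeric vector of length `dim` and returns
#'   the gradient vector in kJ/mol/Angstrom.
#' @param dim dimensionality of the CV space (1 or 2).
#' @param known_minima optional matrix (m x dim) of local-minimum locations.
#' @param archetype optional mechanism label, one of
#'   `"dissociative"`, `"interchange_dissociative"`, `"interchange"`,
#'   `"interchange_associative"`, `"associative"`, `"inactive"`.
#' @param check if `TRUE` (default), the gradient is verified against central
#'   finite differences at a few probe points (1e-6 relative tolerance) and
#'   each known minimum is verified to be a stationary local minimum.
#'
#' @return an object of class `model_potential`.
#' @export
model_potential <- function(name, energy, gradient, dim = 2L,
                            known_minima = NULL, archetype = NULL,
                            check = TRUE) {
  stopifnot(is.function(energy), is.function(gradient), dim %in% c(1L, 2L))
  pot <- structure(
    list(name = name, energy = energy, gradient = gradient, dim = as.integer(dim),
         known_minima = known_minima, archetype = archetype),
    class = "model_potential")
  if (check) {
    probes <- if (dim == 2L) rbind(c(2.6, 4.2), c(3.5, 3.5), c(5.0, 2.6))
              else matrix(c(2.6, 3.5, 5.0), ncol = 1)
    for (i in seq_len(nrow(probes))) {
      p <- probes[i, ]
      g <- gradient(p)
      gfd <- .fd_gradient(energy, p)
      scale <- max(abs(gfd), 1)
      if (any(abs(g - gfd) / scale > 1e-5))
        stop("analytic gradient of '", name, "' disagrees with finite differences")
    }
    if (!is.null(known_minima)) {
      for (i in seq_len(nrow(known_minima))) {
        m <- known_minima[i, ]
        e0 <- energy(m)
        for (dlt in list(c(1e-3, 0), c(-1e-3, 0), c(0, 1e-3), c(0, -1e-3))[seq_len(2 * dim)]) {
          if (energy(m + dlt[seq_len(dim)]) < e0 - 1e-9)
            stop("known minimum ", i, " of '", name, "' is not a local minimum")
        }
      }
    }
  }
  pot
}

.fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.model_potential <- function(x, ...) {
  cat("<model_potential>", x$name,
      if (!is.null(x$archetype)) paste0("[", x$archetype, "]"), "\n")
  cat("  dim:", x$dim, "\n")
  if (!is.null(x$known_minima)) {
    cat("  known minima:\n")
    print(round(x$known_minima, 3))
  }
  invisible(x)
}

# Quartic confining walls outside [lo, hi] per coordinate.
.wall_energy <- function(x, lo, hi, k) {
  below <- pmax(lo - x, 0); above <- pmax(x - hi, 0)
  k * sum(below^4 + above^4)
}
.wall_grad <- function(x, lo, hi, k) {
  below <- pmax(lo - x, 0); above <- pmax(x - hi, 0)
  k * (-4 * below^3 + 4 * above^3)
}

#' Build a 2D potential from Gaussian wells and ridges
#'
#' Energy is `sum_i A_i exp(-0.5 ((s1-x_i)^2/wx_i^2 + (s2-y_i)^2/wy_i^2))`
#' (negative `A` = well, positive `A` = ridge) plus an optional linear tilt and
#' quartic confining walls outside `box`. Minima supplied via `refine_from` are
#' polished with BFGS on the analytic gradient and stored as `known_minima`.
#'
#' @param name label.
#' @param features data.frame with columns `x`, `y`, `A` (kJ/mol; negative for
#'   wells), `wx`, `wy` (Angstrom).
#' @param tilt length-2 numeric; linear term `tilt[1]*s1 + tilt[2]*s2`.
#' @param box length-2 numeric; confining box per coordinate.
#' @param k_wall wall stiffness (kJ/mol/A^4).
#' @param refine_from optional matrix of starting points for minimum refinement.
#' @param archetype optional mechanism label carried along.
#' @return `model_potential` of dim 2.
#' @export
gaussian_potential_2d <- function(name, features, tilt = c(0, 0),
                                  box = c(2.0, 6.0), k_wall = 300,
                                  refine_from = NULL, archetype = NULL) {
  stopifnot(all(c("x", "y", "A", "wx", "wy") %in% names(features)))
  cx <- features$x; cy <- features$y; A <- features$A
  ivx <- 1 / features$wx^2; ivy <- 1 / features$wy^2

  energy <- function(s) {
    if (is.matrix(s)) return(apply(s, 1, energy))
    dx <- s[1] - cx; dy <- s[2] - cy
    sum(A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy))) +
      tilt[1] * s[1] + tilt[2] * s[2] +
      .wall_energy(s, box[1], box[2], k_wall)
  }
  gradient <- function(s) {
    dx <- s[1] - cx; dy <- s[2] - cy
    g <- A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy))
    c(-sum(g * dx * ivx), -sum(g * dy * ivy)) +
      tilt + .wall_grad(s, box[1], box[2], k_wall)
  }

  known <- NULL
  if (!is.null(refine_from)) {
    known <- t(apply(refine_from, 1, function(p) {
      stats::optim(p, fn = energy, gr = gradient, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500))$par
    }))
    colnames(known) <- c("s1", "s2")
  }
  model_potential(name, energy, gradient, dim = 2L,
                  known_minima = known, archetype = archetype)
}

# Squared distance from point s to the polyline, and the vector s - proj
# (gradient of d^2/2). Smooth except on the medial axis (measure zero).
.polyline_proj <- function(s, waypoints) {
  best <- Inf; vec <- c(0, 0)
  for (i in seq_len(nrow(waypoints) - 1)) {
    a <- waypoints[i, ]; b <- waypoints[i + 1, ]
    ab <- b - a
    t <- sum((s - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    p <- a + t * ab
    d2 <- sum((s - p)^2)
    if (d2 < best) { best <- d2; vec <- s - p }
  }
  list(d2 = best, vec = vec)
}

#' Valley-channel potential with station wells
#'
#' A Gaussian channel of depth `channel_depth` and width `channel_width`
#' along a waypoint polyline (energy `channel_depth *
#' exp(-d^2 / (2 width^2))` with `d` the distance to the polyline), plus
#' Gaussian station wells and confining walls. This is the shape of a
#' reaction valley connecting reactant, intermediates and product basins.
#'
#' @param name label.
#' @param waypoints matrix (k x 2) of polyline vertices (Angstrom).
#' @param wells data.frame as in [gaussian_potential_2d()].
#' @param channel_depth channel floor energy, kJ/mol (negative).
#' @param channel_width channel Gaussian width, Angstrom.
#' @param box,k_wall confining walls.
#' @param refine_from starting points for minimum refinement.
#' @param archetype optional mechanism label.
#' @return `model_potential` of dim 2.
#' @export
channel_potential <- function(name, waypoints, wells,
                              channel_depth = -8, channel_width = 0.35,
                              box = c(2.0, 6.0), k_wall = 300,
                              refine_from = NULL, archetype = NULL) {
  cx <- wells$x; cy <- wells$y; A <- wells$A
  ivx <- 1 / wells$wx^2; ivy <- 1 / wells$wy^2
  iw2 <- 1 / channel_width^2
  energy <- function(s) {
    if (is.matrix(s)) return(apply(s, 1, energy))
    dx <- s[1] - cx; dy <- s[2] - cy
    pr <- .polyline_proj(s, waypoints)
    sum(A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy))) +
      channel_depth * exp(-0.5 * pr$d2 * iw2) +
      .wall_energy(s, box[1], box[2], k_wall)
  }
  gradient <- function(s) {
    dx <- s[1] - cx; dy <- s[2] - cy
    g <- A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy))
    pr <- .polyline_proj(s, waypoints)
    ch <- channel_depth * exp(-0.5 * pr$d2 * iw2)
    c(-sum(g * dx * ivx), -sum(g * dy * ivy)) +
      ch * (-iw2) * pr$vec +
      .wall_grad(s, box[1], box[2], k_wall)
  }
  known <- NULL
  if (!is.null(refine_from)) {
    known <- t(apply(refine_from, 1, function(p) {
      stats::optim(p, fn = energy, gr = gradient, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500))$par
    }))
    colnames(known) <- c("s1", "s2")
  }
  model_potential(name, energy, gradient, dim = 2L,
                  known_minima = known, archetype = archetype)
}

#' Archetype triplet-surface potentials
#'
#' Six constructed 2D surfaces over (Ru-S, Ru-Omin), one per photosubstitution
#' scenario. All share an MLCT basin near (2.3, 4.5) Angstrom where photon
#' absorption deposits the system; they differ in which intermediates exist on
#' the way to the aqua photoproduct:
#' \describe{
#'   \item{dissociative}{MC basin, then a pentacoordinate intermediate (both
#'     distances > 4 A) before the product.}
#'   \item{interchange_dissociative}{no intermediate; Ru-S elongates past the
#'     4 A cutoff before Ru-Omin descends, over a real barrier.}
#'   \item{interchange}{nearly flat, concerted landscape; no intermediate and
#'     no barrier above thermal energy.}
#'   \item{interchange_associative}{a transient seven-coordinate feature with
#'     Ru-Omin hovering just inside the 4 A cutoff.}
#'   \item{associative}{a true heptacoordinate intermediate well inside the
#'     cutoff before Ru-S dissociates.}
#'   \item{inactive}{a single MLCT basin; energy rises monotonically beyond it,
#'     no reactive minima anywhere.}
#' }
#' Well depths are on the scale of the computed triplet barriers for this
#' family of complexes (a few to ~15 kJ/mol).
#'
#' @param archetype one of the six labels above.
#' @return `model_potential` of dim 2 with `known_minima` filled in.
#' @export
archetype_potential <- function(archetype = c("dissociative",
                                              "interchange_dissociative",
                                              "interchange",
                                              "interchange_associative",
                                              "associative",
                                              "inactive")) {
  archetype <- match.arg(archetype)
  mlct <- c(2.55, 4.5)
  f <- function(x, y, A, wx, wy) data.frame(x = x, y = y, A = A, wx = wx, wy = wy)
  switch(archetype,
    dissociative = channel_potential(
      "dissociative archetype",
      waypoints = rbind(c(2.55, 4.5), c(3.3, 4.1), c(4.6, 4.4),
                        c(5.1, 3.5), c(5.1, 2.45)),
      wells = rbind(f(2.55, 4.5, -6, 0.30, 0.40),  # MLCT
                    f(3.3, 4.1, -4, 0.25, 0.30),   # MC
                    f(4.6, 4.4, -5, 0.30, 0.35),   # pentacoordinate intermediate
                    f(5.1, 2.45, -7, 0.40, 0.35)), # product 3P
      refine_from = rbind(mlct, c(3.3, 4.1), c(4.6, 4.4), c(5.1, 2.45)),
      archetype = "dissociative"),
    interchange_dissociative = channel_potential(
      "interchange-dissociative archetype",
      waypoints = rbind(c(2.55, 4.5), c(4.6, 4.5), c(5.0, 2.4)),
      wells = rbind(f(2.55, 4.5, -7, 0.30, 0.45),  # MLCT (broad, merges MC)
                    f(5.0, 2.4, -7, 0.40, 0.40)),  # product 3P; no intermediate
      refine_from = rbind(mlct, c(5.0, 2.4)),
      archetype = "interchange_dissociative"),
    interchange = gaussian_potential_2d(
      "interchange archetype",
      rbind(f(5.0, 2.45, -6, 0.45, 0.40)),  # terminal 3P pocket
      tilt = c(-1.0, 1.0),                  # gentle concerted downhill
      refine_from = rbind(c(5.0, 2.45)),
      archetype = "interchange"),
    interchange_associative = channel_potential(
      "interchange-associative archetype",
      waypoints = rbind(c(2.55, 4.5), c(3.25, 3.9), c(4.5, 3.8), c(5.0, 2.4)),
      wells = rbind(f(2.55, 4.5, -6, 0.30, 0.40),  # MLCT
                    f(3.25, 3.90, -4, 0.28, 0.25), # transient 7-coordinate
                    f(5.0, 2.4, -7, 0.40, 0.40)),  # product 3P
      refine_from = rbind(mlct, c(3.25, 3.90), c(5.0, 2.4)),
      archetype = "interchange_associative"),
    associative = channel_potential(
      "associative archetype",
      waypoints = rbind(c(2.55, 4.5), c(3.3, 3.5), c(4.4, 3.3), c(5.0, 2.3)),
      wells = rbind(f(2.55, 4.5, -6, 0.30, 0.40),  # MLCT
                    f(2.92, 4.0, 3, 0.22, 0.22),   # TS pinch before the intermediate
                    f(3.3, 3.5, -6, 0.28, 0.28),   # heptacoordinate intermediate
                    f(5.0, 2.3, -7, 0.40, 0.35)),  # product 3P
      refine_from = rbind(mlct, c(3.3, 3.5), c(5.0, 2.3)),
      archetype = "associative"),
    inactive = {
      # single MLCT basin on a landscape rising with Ru-S and curving in Ru-Omin;
      # built directly so the quadratic s2 bowl has an analytic gradient
      cx <- 2.55; cy <- 4.5; A <- -12; ivx <- 1 / 0.35^2; ivy <- 1 / 0.55^2
      box <- c(2.0, 6.0); k_wall <- 300
      energy <- function(s) {
        if (is.matrix(s)) return(apply(s, 1, energy))
        dx <- s[1] - cx; dy <- s[2] - cy
        A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy)) +
          1.5 * s[1] + 0.4 * (s[2] - 4.5)^2 +
          .wall_energy(s, box[1], box[2], k_wall)
      }
      gradient <- function(s) {
        dx <- s[1] - cx; dy <- s[2] - cy
        g <- A * exp(-0.5 * (dx^2 * ivx + dy^2 * ivy))
        c(g * (-dx * ivx), g * (-dy * ivy)) +
          c(1.5, 0.8 * (s[2] - 4.5)) +
          .wall_grad(s, box[1], box[2], k_wall)
      }
      start <- c(2.57, 4.5)
      m <- stats::optim(start, energy, gradient, method = "BFGS",
                        control = list(reltol = 1e-14))$par
      model_potential("photoinactive archetype", energy, gradient, dim = 2L,
                      known_minima = matrix(m, 1, dimnames = list(NULL, c("s1", "s2"))),
                      archetype = "inactive")
    })
}

#' Harmonic well potential
#'
#' `U(s) = 0.5 * k * |s - center|^2`, the basic oracle for equipartition and
#' zero-temperature fixed-point checks.
#'
#' @param k force constant, kJ/mol/A^2 (scalar or per-coordinate).
#' @param center well position.
#' @param dim dimensionality (defaults to `length(center)`).
#' @return `model_potential`.
#' @export
harmonic_potential <- function(k, center = 0, dim = length(center)) {
  center <- rep_len(center, dim); k <- rep_len(k, dim)
  model_potential(
    paste0("harmonic(k=", paste(k, collapse = ","), ")"),
    energy = function(s) {
      if (is.matrix(s)) return(apply(s, 1, function(r) sum(0.5 * k * (r - center)^2)))
      sum(0.5 * k * (s - center)^2)
    },
    gradient = function(s) k * (s - center),
    dim = as.integer(dim),
    known_minima = matrix(center, 1),
    check = FALSE)
}

#' Flat (zero) potential
#'
#' Free diffusion; used to check the integrator's analytic diffusion constant.
#'
#' @param dim dimensionality.
#' @return `model_potential`.
#' @export
flat_potential <- function(dim = 1L) {
  model_potential("flat",
                  energy = function(s) if (is.matrix(s)) numeric(nrow(s)) else 0,
                  gradient = function(s) numeric(length(s)),
                  dim = as.integer(dim), check = FALSE)
}

#' Symmetric/asymmetric 1D double well
#'
#' Quartic double well with minima at `a` and `b` and barrier height `height`
#' at the midpoint, plus an optional linear `bias_slope` that tilts the two
#' wells relative to each other. Used as the analytic oracle for Boltzmann
#' well-population and well-tempered convergence checks.
#'
#' @param a,b well positions (Angstrom).
#' @param height barrier height at the midpoint (kJ/mol).
#' @param bias_slope linear tilt (kJ/mol/A), default 0.
#' @return `model_potential` of dim 1.
#' @export
double_well_1d <- function(a = 3.0, b = 4.4, height = 6, bias_slope = 0) {
  m <- (a + b) / 2; h4 <- ((b - a) / 2)^4
  scale <- height / h4
  model_potential(
    sprintf("double well [%g, %g] h=%g", a, b, height),
    energy = function(s) {
      s <- drop(s)
      scale * (s - a)^2 * (s - b)^2 + bias_slope * (s - m)
    },
    gradient = function(s) {
      s <- drop(s)
      scale * (2 * (s - a) * (s - b)^2 + 2 * (s - a)^2 * (s - b)) + bias_slope
    },
    dim = 1L, check = FALSE)
}
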
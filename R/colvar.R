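# Collective-variable extraction from Cartesian frames: Ru-S distance, minimum
# Ru-O(water) distance, S-Ru-Omin attack angle and the signed chelate dihedral
# between the Ru-N_C-C_C and Ru-N_T-C_T half-planes.

#' Atom role map
#'
#' Indices (1-based) of the atoms every CV needs: the metal, the thioether
#' sulfur, the four chelate atoms (N/C cis and trans to S) and the set of
#' solvent oxygens. Roles are explicit indices because XYZ frames carry no
#' residue information.
#'
#' @param Ru,S,N_C,C_C,N_T,C_T atom indices.
#' @param solvent_O integer vector of solvent oxygen indices (non-empty for
#'   Ru-Omin measurements).
#' @return list of class `role_map`.
#' @export
role_map <- function(Ru, S, N_C, C_C, N_T, C_T, solvent_O = integer(0)) {
  core <- c(Ru = Ru, S = S, N_C = N_C, C_C = C_C, N_T = N_T, C_T = C_T)
  if (anyDuplicated(c(core, solvent_O)))
    stop("role indices must be distinct")
  structure(list(Ru = Ru, S = S, N_C = N_C, C_C = C_C, N_T = N_T, C_T = C_T,
                 solvent_O = as.integer(solvent_O)),
            class = "role_map")
}

.get_atom <- function(frame, idx, role) {
  if (idx > nrow(frame) || idx < 1)
    stop("role '", role, "' index ", idx, " outside frame (", nrow(frame), " atoms)")
  frame[idx, ]
}

#' Measure collective variables on one frame
#'
#' Returns the Ru-S distance, the minimum Ru-O distance over all solvent
#' oxygens, the S-Ru-Omin angle (at Ru, between the Ru->S and Ru->Omin
#' vectors, taken to the oxygen realising the minimum), and the signed chelate
#' dihedral theta.
#'
#' @param frame numeric matrix (n_atoms x 3), Angstrom.
#' @param roles a [role_map()].
#' @param flag_monodentate_at Ru-N distance (Angstrom) beyond which the chelate
#'   is flagged as monodentate-like (the frame is flagged, never dropped).
#' @return one-row data.frame: `d_RuS`, `d_RuOmin`, `alpha`, `theta`,
#'   `monodentate`.
#' @export
measure_cv <- function(frame, roles, flag_monodentate_at = 4.0) {
  stopifnot(inherits(roles, "role_map"))
  ru <- .get_atom(frame, roles$Ru, "Ru")
  s  <- .get_atom(frame, roles$S, "S")
  d_RuS <- sqrt(sum((s - ru)^2))
  d_RuOmin <- NA_real_; alpha <- NA_real_
  if (length(roles$solvent_O) > 0) {
    if (any(roles$solvent_O > nrow(frame) | roles$solvent_O < 1))
      stop("role 'solvent_O' contains indices outside the frame")
    om <- frame[roles$solvent_O, , drop = FALSE]
    dd <- sqrt(rowSums(sweep(om, 2, ru)^2))
    i <- which.min(dd)
    d_RuOmin <- dd[i]
    v1 <- s - ru; v2 <- om[i, ] - ru
    cosa <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    alpha <- acos(pmin(1, pmax(-1, cosa))) * 180 / pi
  }
  th <- chelate_dihedral(frame, roles)
  dn_c <- sqrt(sum((.get_atom(frame, roles$N_C, "N_C") - ru)^2))
  dn_t <- sqrt(sum((.get_atom(frame, roles$N_T, "N_T") - ru)^2))
  data.frame(d_RuS = d_RuS, d_RuOmin = d_RuOmin, alpha = alpha, theta = th,
             monodentate = max(dn_c, dn_t) > flag_monodentate_at)
}

#' Measure a whole trajectory
#'
#' @param traj list with `frames` (list of n x 3 matrices) and optional `times`.
#' @param roles a [role_map()].
#' @inheritParams measure_cv
#' @return data.frame of class `cv_series`: `time`, `d_RuS`, `d_RuOmin`,
#'   `alpha`, `theta`, `monodentate`.
#' @export
measure_trajectory <- function(traj, roles, flag_monodentate_at = 4.0) {
  frames <- if (!is.null(traj$frames)) traj$frames else traj
  rows <- lapply(frames, measure_cv, roles = roles,
                 flag_monodentate_at = flag_monodentate_at)
  out <- do.call(rbind, rows)
  out <- cbind(time = if (!is.null(traj$times)) traj$times
               else seq_along(frames) - 1, out)
  class(out) <- c("cv_series", "data.frame")
  out
}

#' Signed chelate dihedral
#'
#' The angle between the plane through (Ru, N_C, C_C) and the plane through
#' (Ru, N_T, C_T), measured between the plane normals
#' `n_C = (N_C - Ru) x (C_C - Ru)` and `n_T = (N_T - Ru) x (C_T - Ru)`.
#' The sign is the sign of `(n_C x n_T) . (midpoint(N_C, N_T) - Ru)`; any
#' fixed convention suffices because downstream folding onto [0, 90] erases
#' the bending direction.
#'
#' @param frame numeric matrix (n_atoms x 3).
#' @param roles a [role_map()].
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
chelate_dihedral <- function(frame, roles) {
  ru <- .get_atom(frame, roles$Ru, "Ru")
  n_c <- .cross(.get_atom(frame, roles$N_C, "N_C") - ru,
                .get_atom(frame, roles$C_C, "C_C") - ru)
  n_t <- .cross(.get_atom(frame, roles$N_T, "N_T") - ru,
                .get_atom(frame, roles$C_T, "C_T") - ru)
  if (sqrt(sum(n_c^2)) < 1e-10) stop("plane Ru-N_C-C_C is degenerate (collinear atoms)")
  if (sqrt(sum(n_t^2)) < 1e-10) stop("plane Ru-N_T-C_T is degenerate (collinear atoms)")
  cr <- .cross(n_c, n_t)
  ang <- atan2(sqrt(sum(cr^2)), sum(n_c * n_t)) * 180 / pi
  mid <- (.get_atom(frame, roles$N_C, "N_C") + .get_atom(frame, roles$N_T, "N_T")) / 2
  sgn <- sum(cr * (mid - ru))
  if (sgn < 0) -ang else ang
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Quasi-uniform subsampling of a CV series
#'
#' Greedy farthest-point (maximin) selection in the (d_RuS, d_RuOmin) plane:
#' the first point is the one farthest from the cloud centroid (an extreme
#' point), and each subsequent point maximises its minimum distance to the
#' points already selected. Emulates delta-net configuration picking for
#' follow-up single-point calculations.
#'
#' @param series data.frame with the two CV columns (`s1`/`s2` or
#'   `d_RuS`/`d_RuOmin`).
#' @param n_out number of points to keep, `<= nrow(series)`.
#' @return the selected rows of `series` (original order preserved), with the
#'   selection indices in attribute `indices`.
#' @export
quasi_uniform_subsample <- function(series, n_out) {
  if (nrow(series) == 0) stop("empty series")
  stopifnot(n_out >= 1, n_out <= nrow(series))
  xy <- .cv2(series)
  n <- nrow(xy)
  ctr <- colMeans(xy)
  d2ctr <- (xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2
  sel <- integer(n_out)
  sel[1] <- which.max(d2ctr)
  mind2 <- (xy[, 1] - xy[sel[1], 1])^2 + (xy[, 2] - xy[sel[1], 2])^2
  if (n_out > 1) {
    for (k in 2:n_out) {
      sel[k] <- which.max(mind2)
      d2 <- (xy[, 1] - xy[sel[k], 1])^2 + (xy[, 2] - xy[sel[k], 2])^2
      mind2 <- pmin(mind2, d2)
    }
  }
  sel <- sort(sel)
  out <- series[sel, , drop = FALSE]
  attr(out, "indices") <- sel
  out
}

# Extract the (s1, s2) matrix from either simulator or measured naming.
.cv2 <- function(x) {
  if (all(c("s1", "s2") %in% names(x))) return(cbind(x$s1, x$s2))
  if (all(c("d_RuS", "d_RuOmin") %in% names(x))) return(cbind(x$d_RuS, x$d_RuOmin))
  stop("series lacks (s1, s2) or (d_RuS, d_RuOmin) columns")
}
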
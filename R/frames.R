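# Synthetic Cartesian frames for a toy octahedral complex: given target CV
# values (Ru-S, Ru-Omin, attack angle, chelate dihedral) the builder places the
# role atoms so that re-measuring the frame returns the inputs exactly, and
# surrounds the complex with decoy water oxygens farther out than Omin. This
# exercises the whole geometry stack (nearest-oxygen search, angle, dihedral)
# with a known ground truth.

#' Toy complex template
#'
#' Reference geometry rules: Ru at the origin; S along +z at the requested
#' Ru-S distance; the incoming water oxygen in the xz-plane at the requested
#' attack angle from Ru->S; N_C on +x and N_T on -z (cis and trans to S); C_C
#' fixed in the xz-plane so the cis half-plane is the reference plane; C_T
#' placed so the trans half-plane makes the requested signed dihedral with it.
#'
#' @param d_RuN Ru-N bond length (Angstrom).
#' @param d_NC chelate N-C bond length (Angstrom).
#' @param n_decoys number of decoy solvent oxygens (placed at least
#'   `decoy_margin` beyond d_RuOmin so the nearest-oxygen search is exercised).
#' @param decoy_margin minimum extra distance for decoys (Angstrom).
#' @return list of class `toy_template`.
#' @export
toy_complex_template <- function(d_RuN = 2.1, d_NC = 1.4, n_decoys = 25L,
                                 decoy_margin = 0.5) {
  structure(list(d_RuN = d_RuN, d_NC = d_NC, n_decoys = as.integer(n_decoys),
                 decoy_margin = decoy_margin),
            class = "toy_template")
}

#' Build Cartesian frames realising CV values
#'
#' For each row of `cv` (columns `d_RuS`, `d_RuOmin`, `alpha`) and each value
#' of `theta`, constructs a frame whose re-measured CVs equal the inputs to
#' machine precision. Atom order: Ru, S, N_C, C_C, N_T, C_T, then the target
#' oxygen followed by the decoys.
#'
#' @param template a [toy_complex_template()].
#' @param cv data.frame with `d_RuS`, `d_RuOmin` (both >= 0) and `alpha`
#'   (degrees in [0, 180]).
#' @param theta signed dihedral (degrees), recycled to `nrow(cv)`.
#' @param seed RNG seed for decoy placement.
#' @return list of class `toy_trajectory` with `frames` (list of matrices),
#'   `elements`, `roles` (a [role_map()]) and `times`.
#' @export
build_frames <- function(template, cv, theta = 0, seed = 1L) {
  stopifnot(inherits(template, "toy_template"),
            all(c("d_RuS", "d_RuOmin", "alpha") %in% names(cv)))
  n <- nrow(cv)
  theta <- rep_len(theta, n)
  bad <- which(cv$d_RuS < 0 | cv$d_RuOmin < 0 |
               cv$alpha < 0 | cv$alpha > 180 | !is.finite(cv$alpha))
  if (length(bad) > 0)
    stop("unrealizable CV tuple at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  set.seed(seed)
  dn <- template$d_RuN; b <- template$d_NC
  nd <- template$n_decoys
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    a <- cv$alpha[i] * pi / 180
    psi <- -theta[i] * pi / 180
    ru <- c(0, 0, 0)
    s  <- c(0, 0, cv$d_RuS[i])
    o  <- cv$d_RuOmin[i] * c(sin(a), 0, cos(a))
    n_c <- c(dn, 0, 0)
    c_c <- c(dn + b * cos(1.0), 0, b * sin(1.0))    # in the xz-plane
    n_t <- c(0, 0, -dn)
    c_t <- c(b * cos(psi), b * sin(psi), -dn)        # horizontal offset at N_T
    # decoys: random directions, radii beyond d_RuOmin + margin
    u <- matrix(stats::rnorm(3 * nd), nd, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- cv$d_RuOmin[i] + template$decoy_margin + stats::runif(nd, 0, 2)
    frames[[i]] <- rbind(ru, s, n_c, c_c, n_t, c_t, o, u * r)
    dimnames(frames[[i]]) <- NULL
  }
  roles <- role_map(Ru = 1, S = 2, N_C = 3, C_C = 4, N_T = 5, C_T = 6,
                    solvent_O = seq.int(7, 7 + nd))
  structure(list(frames = frames,
                 elements = c("Ru", "S", "N", "C", "N", "C", rep("O", nd + 1)),
                 roles = roles,
                 times = seq_len(n) - 1),
            class = "toy_trajectory")
}
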
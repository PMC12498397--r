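# Chelate planarity/rigidity descriptors and the correlation/regression
# analyses linking molecular descriptors to photosubstitution quantum yields.

#' Fold a signed dihedral onto [0, 90] degrees
#'
#' `90 - |90 - (|theta| mod 180)|`: 0 corresponds to a completely flat (planar)
#' chelate, 90 to a maximally bent one, and bending in either direction is
#' treated equally (the planes are unordered, so 180 degrees is again
#' coplanar). Idempotent and even.
#'
#' @param theta_signed dihedral(s) in degrees.
#' @return folded angle(s) in [0, 90].
#' @export
fold_theta <- function(theta_signed) {
  90 - abs(90 - (abs(theta_signed) %% 180))
}

#' Planarity and rigidity of the bidentate chelate
#'
#' Planarity `mu_theta` is the mean of the folded dihedral over a trajectory;
#' rigidity `sigma_theta` is its standard deviation (population convention,
#' i.e. 1/n, by default).
#'
#' @param theta_series signed dihedrals (degrees), length >= 2.
#' @param population use the population (1/n) standard deviation; set `FALSE`
#'   for the sample (1/(n-1)) convention.
#' @return list of class `planarity_result`: `mu_theta`, `sigma_theta`,
#'   `n_frames`.
#' @export
planarity_rigidity <- function(theta_series, population = TRUE) {
  theta_series <- theta_series[!is.na(theta_series)]
  if (length(theta_series) < 2) stop("need at least 2 frames")
  f <- fold_theta(theta_series)
  n <- length(f)
  mu <- mean(f)
  sg <- stats::sd(f) * if (population) sqrt((n - 1) / n) else 1
  structure(list(mu_theta = mu, sigma_theta = sg, n_frames = n),
            class = "planarity_result")
}

#' @export
print.planarity_result <- function(x, ...) {
  cat(sprintf("<planarity_result> mu(theta) = %.1f deg, sigma(theta) = %.1f deg (n = %d)\n",
              x$mu_theta, x$sigma_theta, x$n_frames))
  invisible(x)
}

#' Spearman rank correlation with exact small-n permutation p-value
#'
#' rho is the Pearson correlation of average ranks (midranks for ties). The
#' two-sided p-value is computed by exact enumeration of all n! pairings for
#' `n <= exact_max` (evaluated in memory-bounded chunks), and by the
#' t-distribution approximation `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @param exact_max largest n for which the exact permutation p is used.
#' @return list of class `correlation_result`: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rank <- function(x, y, exact_max = 10L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    p <- .spearman_exact_p(rx, ry, rho)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

# Exact two-sided permutation p-value for Spearman rho. With the rank
# multisets fixed, rho is affine in S = sum(rx_perm * ry), so |rho| >= |rho0|
# is decided from S alone. Permutations are enumerated once and S evaluated by
# a chunked matrix product.
.spearman_exact_p <- function(rx, ry, rho0) {
  n <- length(rx)
  mx <- mean(rx); my <- mean(ry)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  perms <- .all_permutations(n)
  np <- nrow(perms)
  count <- 0L
  chunk <- 200000L
  for (i0 in seq(1L, np, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, np)
    block <- matrix(rx[perms[i0:i1, ]], ncol = n)
    S <- as.vector(block %*% ry)
    rho_p <- (S / n - mx * my) * n / (n - 1) / (sx * sy)
    count <- count + sum(abs(rho_p) >= abs(rho0) - 1e-12)
  }
  count / np
}

# All permutations of 1..n as an (n!) x n integer matrix, built level by level.
.all_permutations <- function(n) {
  p <- matrix(1L, 1, 1)
  if (n == 1) return(p)
  for (k in 2:n) {
    nr <- nrow(p)
    out <- matrix(0L, nr * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * nr + seq_len(nr)
      if (pos > 1) out[rows, seq_len(pos - 1)] <- p[, seq_len(pos - 1), drop = FALSE]
      out[rows, pos] <- k
      if (pos < k) out[rows, (pos + 1):k] <- p[, pos:(k - 1), drop = FALSE]
    }
    p <- out
  }
  p
}

#' Ordinary least squares with a t-scaled confidence band
#'
#' Fits `y ~ x` and propagates the standard error of the regression residuals:
#' the band half-width at `x*` is
#' `t_crit * s * sqrt(1/n + (x* - mean(x))^2 / sum((x - mean(x))^2))` with
#' `s = sqrt(SS_res / (n - 2))` and `t_crit` the two-sided critical value of
#' the t-distribution at the requested confidence and `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors, n >= 3; `x` must not be constant.
#' @param confidence confidence level (default 0.95).
#' @return list of class `regression_result`: `slope`, `intercept`, `R2`,
#'   `residual_se`, `dof`, `t_crit`, `band` (data.frame `x`, `fit`,
#'   `half_width` at the data), and `band_at(xstar)`.
#' @export
linear_fit_ci <- function(x, y, confidence = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0) stop("constant x: fit undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  dof <- n - 2
  s <- sqrt(ssr / dof)
  tc <- stats::qt(1 - (1 - confidence) / 2, df = dof)
  sxx <- sum((x - mean(x))^2)
  half <- function(xstar) tc * s * sqrt(1 / n + (xstar - mean(x))^2 / sxx)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]), R2 = r2,
                 residual_se = s, dof = dof, t_crit = tc,
                 band = data.frame(x = x, fit = co[1] + co[2] * x,
                                   half_width = half(x)),
                 band_at = half, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g + %.4g x; R2 = %.3f (n = %d)\n",
              x$intercept, x$slope, x$R2, x$n))
  invisible(x)
}

#' Packaged compound tables
#'
#' Loads the fixture tables for the nine-complex [Ru(tpy)(N-N)(AcMet)]2+
#' series: measured photophysics (extinction coefficients, photosubstitution
#' quantum yields under green/515 nm and red/625 nm light, emission and singlet
#' oxygen yields), computed triplet-barrier energies (MLCT->MC and MLCT->TS,
#' kJ/mol), and the cis/trans attack percentages from the sampling study.
#'
#' The photoinactive complex Ru1 has an empty quantum-yield cell in the source
#' table; `zero_inactive = TRUE` (the default, and the convention used by the
#' correlation analyses) assigns it quantum yield 0 so it enters rank and
#' regression analyses as the least photoactive member.
#'
#' @param zero_inactive replace missing quantum yields of photoinactive
#'   compounds by 0.
#' @return list of data.frames: `photophysics`, `barriers`, `attack`.
#' @export
compound_tables <- function(zero_inactive = TRUE) {
  path <- function(f) system.file("extdata", f, package = "photosub",
                                  mustWork = TRUE)
  ph <- utils::read.csv(path("photophysics.csv"), stringsAsFactors = FALSE)
  ba <- utils::read.csv(path("dft_barriers.csv"), stringsAsFactors = FALSE)
  at <- utils::read.csv(path("attack_pathways.csv"), stringsAsFactors = FALSE)
  ph$photoactive <- !(is.na(ph$phi_515) & is.na(ph$phi_625))
  if (zero_inactive) {
    ph$phi_515[is.na(ph$phi_515)] <- 0
    ph$phi_625[is.na(ph$phi_625)] <- 0
  }
  list(photophysics = ph, barriers = ba, attack = at)
}
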
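# Independent oracles used across the suite. Each is deliberately naive:
# straightforward summation, enumeration or closed form, sharing no code with
# the implementation it checks.

kT300 <- photosub::KB_KJMOL * 300

# brute-force Gaussian hill summation
oracle_hill_sum <- function(hills, x) {
  vapply(x, function(xi)
    sum(hills$height * exp(-(xi - hills$center)^2 / (2 * hills$sigma^2))),
    numeric(1))
}

# Pearson correlation of midranks, written out longhand
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# normal-equations least squares
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       R2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# minimax path value by exhaustive threshold enumeration: the lowest level L
# such that start and end are connected through bins with F <= L
oracle_minimax_level <- function(F, start, end) {
  nx <- nrow(F); ny <- ncol(F)
  for (L in sort(unique(as.vector(F)))) {
    ok <- F <= L
    if (!ok[start[1], start[2]] || !ok[end[1], end[2]]) next
    seen <- matrix(FALSE, nx, ny)
    stack <- list(start); seen[start[1], start[2]] <- TRUE
    while (length(stack) > 0) {
      u <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        vi <- u[1] + di; vj <- u[2] + dj
        if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
        if (!ok[vi, vj] || seen[vi, vj]) next
        seen[vi, vj] <- TRUE
        stack[[length(stack) + 1]] <- c(vi, vj)
      }
    }
    if (seen[end[1], end[2]]) return(L)
  }
  Inf
}

# exhaustive DFS over all simple paths (tiny grids only)
oracle_minimax_dfs <- function(F, start, end) {
  nx <- nrow(F); ny <- ncol(F)
  best <- Inf
  visit <- matrix(FALSE, nx, ny)
  rec <- function(i, j, mx) {
    mx <- max(mx, F[i, j])
    if (mx >= best) return()
    if (i == end[1] && j == end[2]) { best <<- mx; return() }
    visit[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      vi <- i + di; vj <- j + dj
      if (vi < 1 || vi > nx || vj < 1 || vj > ny || visit[vi, vj]) next
      rec(vi, vj, mx)
    }
    visit[i, j] <<- FALSE
  }
  rec(start[1], start[2], -Inf)
  best
}

# plain cross product
oracle_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# E[fold(theta)] for theta ~ N(mu, sd) by numerical integration
oracle_folded_mean <- function(mu, sd) {
  stats::integrate(function(t) photosub::fold_theta(t) * stats::dnorm(t, mu, sd),
                   mu - 10 * sd, mu + 10 * sd)$value
}

# wrap a grid matrix as an fes_grid with everything sampled
grid_from_matrix <- function(F, xlim = c(0, 1), ylim = c(0, 1),
                             temperature = 300) {
  spec <- photosub::fes_grid_spec(xlim, ylim, nrow(F), ncol(F))
  photosub::fes_grid(spec, F, counts = matrix(1e6, nrow(F), ncol(F)),
                     temperature = temperature, min_count = 1)
}
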
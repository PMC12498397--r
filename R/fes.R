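# Free-energy surface reconstruction: metadynamics reweighting of per-window
# samples, binned 2D WHAM across umbrella windows, attack-geometry splitting,
# and the grid analyses every classifier reads (minima, saddles, minimum-energy
# paths under the minimax criterion).

#' Grid specification for a 2D FES
#'
#' @param xlim,ylim axis ranges (Angstrom). Defaults match the plotted
#'   (Ru-S, Ru-Omin) ranges of 2.0-6.0 Angstrom.
#' @param nx,ny number of bins per axis (default 60 x 60).
#' @param names axis names.
#' @return list of class `fes_grid_spec` with bin `breaks` and `centers`.
#' @export
fes_grid_spec <- function(xlim = c(2.0, 6.0), ylim = c(2.0, 6.0),
                          nx = 60L, ny = 60L,
                          names = c("d_RuS", "d_RuOmin")) {
  stopifnot(nx >= 2, ny >= 2, xlim[2] > xlim[1], ylim[2] > ylim[1])
  bx <- seq(xlim[1], xlim[2], length.out = nx + 1)
  by <- seq(ylim[1], ylim[2], length.out = ny + 1)
  structure(list(xlim = xlim, ylim = ylim, nx = as.integer(nx),
                 ny = as.integer(ny), names = names,
                 xbreaks = bx, ybreaks = by,
                 xcenters = (bx[-1] + bx[-(nx + 1)]) / 2,
                 ycenters = (by[-1] + by[-(ny + 1)]) / 2),
            class = "fes_grid_spec")
}

.bin_index <- function(x, breaks) {
  i <- findInterval(x, breaks, rightmost.closed = TRUE)
  i[i < 1 | i > length(breaks) - 1] <- NA_integer_
  i
}

#' Construct an FES grid object
#'
#' Internal-ish constructor; most users get `fes_grid`s from [wham_2d()] or
#' [boltzmann_invert()]. F is gauge-fixed so its minimum over sampled bins is
#' zero; unsampled bins (raw counts below `min_count`) carry `NA`.
#'
#' @param spec a [fes_grid_spec()].
#' @param F matrix (nx x ny) of free energies, kJ/mol.
#' @param counts matrix of per-bin sample counts.
#' @param temperature Kelvin.
#' @param min_count mask threshold: bins with fewer raw samples are unsampled.
#' @return object of class `fes_grid`.
#' @export
fes_grid <- function(spec, F, counts, temperature = 300, min_count = 5) {
  mask <- counts >= min_count & is.finite(F)
  F[!mask] <- NA_real_
  if (any(mask)) F <- F - min(F[mask])
  structure(list(spec = spec, F = F, counts = counts, sampled_mask = mask,
                 temperature = temperature, min_count = min_count),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid>", x$spec$nx, "x", x$spec$ny, "bins;",
      sum(x$sampled_mask), "sampled;",
      "F range", paste(round(range(x$F, na.rm = TRUE), 2), collapse = " - "),
      "kJ/mol\n")
  invisible(x)
}

#' Per-sample reweighting factors for biased samples
#'
#' Weights proportional to `exp(+beta * V_total)` where `V_total` is the
#' umbrella energy at the sample's restrained CV plus the final-time
#' metadynamics bias at the sample's biased CV (quasi-static approximation:
#' the well-tempered bias varies slowly at late times). The per-window maximum
#' bias is subtracted before exponentiation to guard overflow; weights are
#' normalised to mean 1 within each window.
#'
#' @param window_results list of `list(window, series, bias)` as returned by
#'   [run_window_schedule()], or a single such element.
#' @return list of numeric weight vectors, one per window.
#' @export
reweight_samples <- function(window_results) {
  if (!is.null(window_results$series)) window_results <- list(window_results)
  lapply(window_results, function(wr) {
    s <- wr$series
    sm <- if (!is.null(s$s2)) s$s2 else s$s1  # 1D: the only CV is biased
    v <- numeric(nrow(s))
    if (!is.null(wr$bias)) {
      v <- v + meta_bias(wr$bias, sm) + wall_energy(wr$bias, sm)
      if (!is.null(wr$bias$window))
        v <- v + umbrella_energy(wr$bias$window, s$s1)
    } else if (!is.null(wr$window)) {
      v <- v + umbrella_energy(wr$window, s$s1)
    }
    if (any(!is.finite(v))) stop("non-finite bias energy among samples")
    kT <- KB_KJMOL * attr(s, "params")$temperature
    w <- exp((v - max(v)) / kT)
    w / mean(w)
  })
}

#' Boltzmann inversion of unbiased samples (degenerate one-window WHAM)
#'
#' `F = -kT ln(histogram)`, gauge-fixed to min 0 over sampled bins.
#'
#' @param series a `cv_series` with 2 CV columns.
#' @param spec a [fes_grid_spec()].
#' @param temperature Kelvin.
#' @param min_count mask threshold.
#' @return `fes_grid`.
#' @export
boltzmann_invert <- function(series, spec, temperature = 300, min_count = 5) {
  xy <- .cv2(series)
  ix <- .bin_index(xy[, 1], spec$xbreaks)
  iy <- .bin_index(xy[, 2], spec$ybreaks)
  ok <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0, spec$nx, spec$ny)
  tb <- table(factor(ix[ok], levels = seq_len(spec$nx)),
              factor(iy[ok], levels = seq_len(spec$ny)))
  counts[] <- as.numeric(tb)
  F <- -KB_KJMOL * temperature * log(counts)
  F[!is.finite(F)] <- NA_real_
  fes_grid(spec, F, counts, temperature, min_count)
}

#' 2D WHAM across umbrella windows with metadynamics reweighting
#'
#' Each window's production is split into `n_segments` time segments; within a
#' segment the well-tempered bias is treated as static at its segment-midpoint
#' form (quasi-static approximation: tempered hills shrink, and the midpoint
#' centres the within-segment growth), so each (window, segment) pair enters
#' WHAM as one biased state with bias `umbrella(s1) + V_meta(s2, t_mid)`
#' evaluated at the bin centers.
#' Samples additionally carry a within-bin correction weight
#' `exp(beta * (V(sample) - V(bin center)))` so that steep biases (the 350
#' kJ/mol/A^2 restraint changes by several kJ/mol across one bin) do not
#' corrupt the binned estimator. The state free energies `f_j` are iterated to
#' self-consistency (gauge `f_1 = 0`) until `max |delta f_j| < tolerance`.
#'
#' @param window_results list of `list(window, series, bias)` from
#'   [run_window_schedule()].
#' @param spec a [fes_grid_spec()].
#' @param tolerance convergence tolerance on the state free energies, kJ/mol.
#' @param max_iter iteration cap; non-convergence yields a warning and a
#'   result flagged `converged = FALSE`.
#' @param min_count mask threshold on raw (unweighted) counts.
#' @param n_segments time segments per window for the quasi-static bias.
#' @param check_overlap error if adjacent windows share no sampled bins.
#' @param f_init optional warm-start state free energies (kJ/mol); a restart
#'   from a converged `wham$f` stops after a couple of iterations.
#' @param restrict_to_windows mask bins whose restrained coordinate lies more
#'   than one window spacing outside the span of window centers: umbrella
#'   windows only inform their restrained neighbourhood, and estimates in the
#'   exponential tails rest on a handful of heavily reweighted samples.
#' @return list with `grid` (an `fes_grid`) and `wham` (state free energies
#'   `f`, `iterations`, `residual`, `converged`).
#' @export
wham_2d <- function(window_results, spec, tolerance = 1e-6, max_iter = 10000L,
                    min_count = 5, n_segments = 10L, check_overlap = TRUE,
                    restrict_to_windows = TRUE, f_init = NULL) {
  stopifnot(tolerance > 0, n_segments >= 1)
  nwin <- length(window_results)
  nb <- spec$nx * spec$ny
  temperature <- attr(window_results[[1]]$series, "params")$temperature
  kT <- KB_KJMOL * temperature
  ctrs <- expand.grid(x = spec$xcenters, y = spec$ycenters)

  # incremental grid cache of the metadynamics bias along s2: hill lists grow
  # monotonically (and restart when per-window resetting), so each hill is
  # added to the cache exactly once
  g_h <- 0.005
  g_x <- seq(spec$ylim[1] - 0.5, spec$ylim[2] + 0.5, by = g_h)
  g_V <- numeric(length(g_x))
  cache_n <- 0L; cache_sig <- NULL
  cache_add <- function(hk_new) {
    for (i in seq_len(nrow(hk_new))) {
      idx <- which(abs(g_x - hk_new$center[i]) <= 6 * hk_new$sigma[i])
      if (length(idx) > 0)
        g_V[idx] <<- g_V[idx] +
          hk_new$height[i] * exp(-(g_x[idx] - hk_new$center[i])^2 /
                                   (2 * hk_new$sigma[i]^2))
    }
  }
  cache_eval <- function(xq) {
    i <- pmin(pmax(findInterval(xq, g_x), 1L), length(g_x) - 1L)
    w1 <- (xq - g_x[i]) / g_h
    (1 - w1) * g_V[i] + w1 * g_V[i + 1L]
  }

  states <- list()
  n_raw_win <- matrix(0, nb, nwin)
  for (j in seq_len(nwin)) {
    wr <- window_results[[j]]
    s <- wr$series
    ix <- .bin_index(s$s1, spec$xbreaks)
    iy <- .bin_index(s$s2, spec$ybreaks)
    ok <- !is.na(ix) & !is.na(iy)
    bin_all <- (iy - 1L) * spec$nx + ix
    cr <- table(bin_all[ok])
    n_raw_win[as.integer(names(cr)), j] <- as.numeric(cr)
    hills <- if (!is.null(wr$bias)) wr$bias$hills else
      data.frame(time = numeric(0), center = numeric(0),
                 sigma = numeric(0), height = numeric(0))
    sig <- if (nrow(hills) > 0) c(hills$time[1], hills$center[1]) else NULL
    if (!identical(sig, cache_sig) || nrow(hills) < cache_n) {
      g_V[] <- 0; cache_n <- 0L; cache_sig <- sig  # hill list restarted
    }
    seg_ends <- stats::quantile(seq_len(nrow(s)), seq_len(n_segments) / n_segments,
                                type = 1)
    seg_id <- findInterval(seq_len(nrow(s)), c(0, seg_ends), left.open = TRUE)
    u_bias <- umbrella_energy(wr$window, spec$xcenters)
    for (k in seq_len(n_segments)) {
      sel <- which(seg_id == k & ok)
      if (length(sel) == 0) next
      # freeze the bias at the segment midpoint: growth within the segment is
      # then centred on the representative form
      t_mid <- (s$time[if (k == 1) 1L else seg_ends[k - 1]] +
                  s$time[seg_ends[k]]) / 2
      m <- findInterval(t_mid, hills$time)
      if (m > cache_n) {
        cache_add(hills[(cache_n + 1L):m, , drop = FALSE])
        cache_n <- m
      }
      # total bias at sample positions and at bin centers
      v_samp <- cache_eval(s$s2[sel]) + umbrella_energy(wr$window, s$s1[sel])
      y_bias <- cache_eval(spec$ycenters)
      if (!is.null(wr$bias)) {
        v_samp <- v_samp + wall_energy(wr$bias, s$s2[sel])
        y_bias <- y_bias + wall_energy(wr$bias, spec$ycenters)
      }
      c_bin <- rep(y_bias, each = spec$nx) + rep(u_bias, times = spec$ny)
      bins <- bin_all[sel]
      w <- exp((v_samp - c_bin[bins]) / kT)  # within-bin correction
      agg <- rowsum(w, group = bins)
      nv <- numeric(nb)
      nv[as.integer(rownames(agg))] <- agg[, 1]
      states[[length(states) + 1L]] <-
        list(n = nv, c = c_bin, N = sum(nv))
    }
  }

  if (check_overlap && nwin > 1) {
    # pool walkers per center; require sampled-bin overlap between neighbours
    cc <- vapply(window_results, function(wr) wr$window$center, numeric(1))
    uc <- sort(unique(cc))
    pooled <- vapply(uc, function(cv) rowSums(n_raw_win[, cc == cv, drop = FALSE]),
                     numeric(nb))
    for (j in seq_len(length(uc) - 1)) {
      if (!any(pooled[, j] > 0 & pooled[, j + 1] > 0))
        stop(sprintf(
          "umbrella windows at centers %.3f and %.3f share no sampled bins",
          uc[j], uc[j + 1]))
    }
  }

  ns <- length(states)
  N <- vapply(states, `[[`, numeric(1), "N")
  expb <- vapply(states, function(st) exp(-st$c / kT), numeric(nb))
  num <- rowSums(vapply(states, `[[`, numeric(nb), "n"))
  f <- if (is.null(f_init)) numeric(ns) else rep_len(f_init, ns)
  iter <- 0L; resid <- Inf
  repeat {
    iter <- iter + 1L
    denom <- as.vector(expb %*% (N * exp(f / kT)))
    P <- num / pmax(denom, .Machine$double.xmin)
    fn <- -kT * log(pmax(colSums(P * expb), .Machine$double.xmin))
    fn <- fn - fn[1]
    resid <- max(abs(fn - f))
    f <- fn
    if (resid < tolerance || iter >= max_iter) break
  }
  converged <- resid < tolerance
  if (!converged)
    warning("WHAM did not converge in ", max_iter,
            " iterations (residual ", signif(resid, 3), " kJ/mol)")

  denom <- as.vector(expb %*% (N * exp(f / kT)))
  P <- num / pmax(denom, .Machine$double.xmin)
  F <- -kT * log(P)
  F[num <= 0] <- NA_real_
  Fm <- matrix(F, spec$nx, spec$ny)
  counts <- matrix(rowSums(n_raw_win), spec$nx, spec$ny)
  if (restrict_to_windows) {
    cc <- vapply(window_results, function(wr) wr$window$center, numeric(1))
    pad <- if (length(cc) > 1) min(diff(sort(cc))) else
      2 * sqrt(KB_KJMOL * temperature / window_results[[1]]$window$k)
    out_of_band <- spec$xcenters < min(cc) - pad | spec$xcenters > max(cc) + pad
    Fm[out_of_band, ] <- NA_real_
  }
  grid <- fes_grid(spec, Fm, counts, temperature, min_count)
  list(grid = grid,
       wham = list(f = f, iterations = iter, residual = resid,
                   converged = converged, temperature = temperature))
}

# Sum of Gaussian hills (rows of a hills data.frame) at positions x,
# evaluated in memory-bounded chunks.
.gauss_sum <- function(hills, x) {
  if (nrow(hills) == 0) return(numeric(length(x)))
  out <- numeric(length(x))
  chunk <- 20000L
  for (i0 in seq(1L, length(x), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(x))
    d <- outer(x[i0:i1], hills$center, "-")
    out[i0:i1] <- as.vector(
      exp(-(d^2) / (2 * rep(hills$sigma^2, each = i1 - i0 + 1))) %*% hills$height)
  }
  out
}

# Metadynamics-only per-sample weights (umbrella handled inside WHAM via f_j).
reweight_meta_only <- function(window_results) {
  lapply(window_results, function(wr) {
    s <- wr$series
    v <- if (!is.null(wr$bias)) meta_bias(wr$bias, s$s2) + wall_energy(wr$bias, s$s2)
         else numeric(nrow(s))
    kT <- KB_KJMOL * attr(s, "params")$temperature
    w <- exp((v - max(v)) / kT)
    w / mean(w)
  })
}

#' Split samples by attack geometry
#'
#' Partition by the S-Ru-Omin angle: cis when `alpha <= 90` degrees (90 exactly
#' is assigned to cis, the documented tie rule), trans when `alpha > 90`.
#'
#' @param samples data.frame with an `alpha` column (degrees).
#' @return list with elements `cis` and `trans` (row subsets).
#' @export
split_by_attack <- function(samples) {
  stopifnot("alpha" %in% names(samples))
  is_cis <- samples$alpha <= 90
  list(cis = samples[is_cis, , drop = FALSE],
       trans = samples[!is_cis, , drop = FALSE])
}

#' Mask-aware Gaussian smoothing of an FES grid
#'
#' Convolves the free-energy surface with a truncated Gaussian kernel,
#' renormalising the kernel over sampled bins so the mask neither shrinks nor
#' bleeds. Reconstructed surfaces carry per-bin statistical noise comparable
#' to kT; smoothing at a fraction of the physical feature width (wells here
#' are ~0.3 Angstrom wide, i.e. several bins) suppresses spurious local minima
#' without displacing real ones.
#'
#' @param grid an `fes_grid`.
#' @param sigma_bins kernel standard deviation in bins.
#' @return the smoothed `fes_grid` (counts and mask unchanged).
#' @export
smooth_fes <- function(grid, sigma_bins = 1.5) {
  if (sigma_bins <= 0) return(grid)
  r <- max(1L, ceiling(3 * sigma_bins))
  ker <- stats::dnorm(-r:r, sd = sigma_bins)
  F <- grid$F; mask <- grid$sampled_mask
  F0 <- ifelse(mask, F, 0)
  W0 <- ifelse(mask, 1, 0)
  conv1 <- function(M, along) {
    out <- matrix(0, nrow(M), ncol(M))
    for (k in -r:r) {
      w <- ker[k + r + 1]
      if (along == 1) {
        src <- max(1, 1 - k):min(nrow(M), nrow(M) - k)
        out[src + k, ] <- out[src + k, ] + w * M[src, ]
      } else {
        src <- max(1, 1 - k):min(ncol(M), ncol(M) - k)
        out[, src + k] <- out[, src + k] + w * M[, src]
      }
    }
    out
  }
  num <- conv1(conv1(F0, 1), 2)
  den <- conv1(conv1(W0, 1), 2)
  Fs <- ifelse(mask & den > 0, num / den, NA_real_)
  Fs <- Fs - min(Fs[mask], na.rm = TRUE)
  grid$F <- Fs
  grid
}

#' Minima and saddles of an FES grid
#'
#' Minima are sampled bins strictly below all sampled 8-neighbours whose escape
#' depth (minimax barrier to any deeper minimum) is at least `min_depth`; the
#' global minimum always qualifies. For each retained pair of minima the
#' connecting saddle (the highest bin on the minimax path) is reported once.
#'
#' @param grid an `fes_grid`.
#' @param min_depth minimum escape depth, kJ/mol.
#' @param interior_only require all 8 neighbours of a minimum to be sampled.
#'   Bins on the sampled-mask boundary are one-sided estimates and, on
#'   reconstructed surfaces, collect reweighting-tail artifacts.
#' @return data.frame with columns `kind` ("minimum"/"saddle"), `ix`, `iy`,
#'   `s1`, `s2`, `F`, `depth` (escape depth for minima, barrier above the
#'   higher of the two connected minima for saddles).
#' @export
find_features <- function(grid, min_depth = 1.0, interior_only = FALSE) {
  F <- grid$F; mask <- grid$sampled_mask
  nx <- grid$spec$nx; ny <- grid$spec$ny
  if (!any(mask)) stop("grid has no sampled bins")
  cand <- which(mask, arr.ind = TRUE)
  is_min <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    f0 <- F[i, j]; ok <- TRUE; any_nb <- FALSE; n_nb <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || !mask[ii, jj]) next
      any_nb <- TRUE; n_nb <- n_nb + 1L
      if (F[ii, jj] <= f0) { ok <- FALSE; break }
    }
    is_min[r] <- ok && any_nb && (!interior_only || n_nb == 8L)
  }
  mins <- cand[is_min, , drop = FALSE]
  if (nrow(mins) == 0)
    return(data.frame(kind = character(0), ix = integer(0), iy = integer(0),
                      s1 = numeric(0), s2 = numeric(0), F = numeric(0),
                      depth = numeric(0)))
  fmin <- F[mins]
  ord <- order(fmin)
  mins <- mins[ord, , drop = FALSE]; fmin <- fmin[ord]

  nm <- nrow(mins)
  # minimax levels between all pairs via repeated Dijkstra from each minimum
  lev <- matrix(Inf, nm, nm)
  if (nm > 1) {
    for (a in seq_len(nm - 1)) {
      dj <- .minimax_dijkstra(grid, mins[a, ])
      for (b in (a + 1):nm) {
        idx <- (mins[b, 2] - 1L) * nx + mins[b, 1]
        lev[a, b] <- lev[b, a] <- dj$dist[idx]
      }
    }
  }
  # escape depth: to any strictly deeper minimum
  depth <- rep(Inf, nm)
  if (nm > 1) {
    for (a in 2:nm) {
      deeper <- which(fmin < fmin[a] - 1e-12)
      if (length(deeper) > 0)
        depth[a] <- min(lev[a, deeper]) - fmin[a]
    }
  }
  keep <- depth >= min_depth
  # re-merge: drop shallow minima
  mins <- mins[keep, , drop = FALSE]; fmin <- fmin[keep]; depth <- depth[keep]
  nm2 <- nrow(mins)
  out <- data.frame(kind = rep("minimum", nm2), ix = mins[, 1], iy = mins[, 2],
                    s1 = grid$spec$xcenters[mins[, 1]],
                    s2 = grid$spec$ycenters[mins[, 2]],
                    F = fmin, depth = depth)
  if (nm2 > 1) {
    for (a in seq_len(nm2 - 1)) {
      dj <- .minimax_dijkstra(grid, mins[a, ])
      for (b in (a + 1):nm2) {
        idx <- (mins[b, 2] - 1L) * nx + mins[b, 1]
        sb <- dj$argmax[[idx]]
        if (is.null(sb)) next
        out <- rbind(out, data.frame(
          kind = "saddle", ix = sb[1], iy = sb[2],
          s1 = grid$spec$xcenters[sb[1]], s2 = grid$spec$ycenters[sb[2]],
          F = F[sb[1], sb[2]],
          depth = F[sb[1], sb[2]] - max(fmin[a], fmin[b])))
      }
    }
    out <- out[!duplicated(out[, c("kind", "ix", "iy")]), ]
  }
  rownames(out) <- NULL
  out
}

# Minimax Dijkstra from a source bin over sampled bins. Path cost is
# lexicographic (max F along path, then integrated F) so ties break toward the
# lower path. Returns per-bin minimax level, the predecessor array and, for
# each bin, the arg-max bin along the optimal path.
.minimax_dijkstra <- function(grid, source) {
  F <- grid$F; mask <- grid$sampled_mask
  nx <- grid$spec$nx; ny <- grid$spec$ny
  nb <- nx * ny
  Fv <- as.vector(F)
  sampled <- as.vector(mask)
  src <- (source[2] - 1L) * nx + source[1]
  if (!sampled[src]) stop("source bin is not sampled")
  dist <- rep(Inf, nb); tot <- rep(Inf, nb)
  prev <- rep(NA_integer_, nb)
  argm <- vector("list", nb)
  visited <- logical(nb)
  dist[src] <- Fv[src]; tot[src] <- Fv[src]
  argm[[src]] <- c(source[1], source[2])
  off_i <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  off_j <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  repeat {
    d <- dist; d[visited] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    cands <- which(d == d[u])
    if (length(cands) > 1) u <- cands[which.min(tot[cands])]
    visited[u] <- TRUE
    ui <- ((u - 1L) %% nx) + 1L
    uj <- ((u - 1L) %/% nx) + 1L
    for (k in 1:8) {
      vi <- ui + off_i[k]; vj <- uj + off_j[k]
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      v <- (vj - 1L) * nx + vi
      if (!sampled[v] || visited[v]) next
      ndist <- max(dist[u], Fv[v])
      ntot <- tot[u] + Fv[v]
      if (ndist < dist[v] - 1e-15 ||
          (abs(ndist - dist[v]) <= 1e-15 && ntot < tot[v])) {
        dist[v] <- ndist; tot[v] <- ntot; prev[v] <- u
        argm[[v]] <- if (Fv[v] >= dist[u] - 1e-15 && Fv[v] >= ndist - 1e-15)
          c(vi, vj) else argm[[u]]
      }
    }
  }
  list(dist = dist, tot = tot, prev = prev, argmax = argm, source = src)
}

#' Minimum-energy path between two bins
#'
#' 8-connected path through sampled bins minimising the maximum free energy
#' along it (minimax / watershed criterion); among minimax-optimal paths the
#' one with the lower integrated F is returned.
#'
#' @param grid an `fes_grid`.
#' @param start,end length-2 integer bin indices `c(ix, iy)`, or length-2
#'   numeric CV coordinates if `as_coords = TRUE`.
#' @param as_coords interpret `start`/`end` as CV coordinates.
#' @return data.frame path (ordered start to end) with `ix`, `iy`, `s1`, `s2`,
#'   `F`; attribute `max_F` carries the minimax value.
#' @export
minimum_energy_path <- function(grid, start, end, as_coords = FALSE) {
  spec <- grid$spec
  to_bin <- function(p) {
    if (as_coords)
      c(.bin_index(p[1], spec$xbreaks), .bin_index(p[2], spec$ybreaks))
    else as.integer(p)
  }
  sb <- to_bin(start); eb <- to_bin(end)
  for (b in list(sb, eb))
    if (any(is.na(b)) || !grid$sampled_mask[b[1], b[2]])
      stop("start/end bin is not sampled")
  dj <- .minimax_dijkstra(grid, sb)
  nx <- spec$nx
  eidx <- (eb[2] - 1L) * nx + eb[1]
  if (!is.finite(dj$dist[eidx])) {
    # find the blocking level: lowest threshold at which the two become connected
    lv <- sort(unique(grid$F[grid$sampled_mask]))
    blocking <- NA_real_
    for (L in lv) {
      if (.connected_at_level(grid, sb, eb, L)) { blocking <- L; break }
    }
    stop("no sampled path between bins; blocking contour level ",
         if (is.na(blocking)) "unreachable (disconnected mask)"
         else paste0(signif(blocking, 6), " kJ/mol"))
  }
  path_idx <- eidx
  while (!is.na(dj$prev[path_idx[1]]))
    path_idx <- c(dj$prev[path_idx[1]], path_idx)
  ix <- ((path_idx - 1L) %% nx) + 1L
  iy <- ((path_idx - 1L) %/% nx) + 1L
  out <- data.frame(ix = ix, iy = iy,
                    s1 = spec$xcenters[ix], s2 = spec$ycenters[iy],
                    F = grid$F[cbind(ix, iy)])
  attr(out, "max_F") <- dj$dist[eidx]
  out
}

# Are two bins connected through sampled bins with F <= level?
.connected_at_level <- function(grid, a, b, level) {
  ok <- grid$sampled_mask & grid$F <= level + 1e-12
  if (!ok[a[1], a[2]] || !ok[b[1], b[2]]) return(FALSE)
  nx <- grid$spec$nx; ny <- grid$spec$ny
  seen <- matrix(FALSE, nx, ny)
  stack <- list(a); seen[a[1], a[2]] <- TRUE
  off_i <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  off_j <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  while (length(stack) > 0) {
    u <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    if (u[1] == b[1] && u[2] == b[2]) return(TRUE)
    for (k in 1:8) {
      vi <- u[1] + off_i[k]; vj <- u[2] + off_j[k]
      if (vi < 1 || vi > nx || vj < 1 || vj > ny) next
      if (!ok[vi, vj] || seen[vi, vj]) next
      seen[vi, vj] <- TRUE
      stack[[length(stack) + 1]] <- c(vi, vj)
    }
  }
  FALSE
}
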
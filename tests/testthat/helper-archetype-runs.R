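# The archetype sampling + reconstruction runs are the expensive part of the
# suite; several acceptance checks read the same surfaces, so they are
# computed lazily once and cached for the session.

.archetype_cache <- new.env(parent = emptyenv())

archetype_run <- function(archetype, seed = 11L, n_walkers = 2L) {
  key <- paste(archetype, seed, n_walkers, sep = "_")
  if (!is.null(.archetype_cache[[key]])) return(.archetype_cache[[key]])
  pot <- photosub::archetype_potential(archetype)
  runs <- photosub::run_window_schedule(
    pot, photosub::make_window_schedule(),
    photosub::sim_params(n_steps = 1L, seed = seed), n_walkers = n_walkers)
  wh <- photosub::wham_2d(runs, photosub::fes_grid_spec())
  out <- list(potential = pot, runs = runs, grid = wh$grid, wham = wh$wham)
  .archetype_cache[[key]] <- out
  out
}

mlct_region <- function(seed = 12L) {
  key <- paste0("region_", seed)
  if (!is.null(.archetype_cache[[key]])) return(.archetype_cache[[key]])
  r <- photosub::absorption_region(photosub::simulate_langevin(
    photosub::harmonic_potential(c(150, 150), c(2.55, 4.5)),
    photosub::sim_params(n_steps = 5000L, seed = seed), n_equil = 500L))
  .archetype_cache[[key]] <- r
  r
}

fes_rmse_kt <- function(run) {
  g <- run$grid
  ctr <- as.matrix(expand.grid(x = g$spec$xcenters, y = g$spec$ycenters))
  Ftrue <- matrix(run$potential$energy(ctr), g$spec$nx, g$spec$ny)
  d <- (g$F - Ftrue)[g$sampled_mask]
  d <- d - mean(d)  # free additive gauge
  sqrt(mean(d^2)) / (photosub::KB_KJMOL * g$temperature)
}
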
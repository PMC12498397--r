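# End-to-end driver: archetype (or ingested) sampling -> attack split -> FES
# reconstruction -> absorption region -> mechanism classification ->
# descriptors, with full config/seed provenance on every artifact.

#' Pipeline configuration
#'
#' All defaults equal the enhanced-sampling protocol values: 20 umbrella
#' windows from 2.50 Angstrom in 0.15 steps (last center 5.35) with a
#' 350 kJ/mol/A^2 restraint and 5 ps / 40 ps equilibration / production per
#' window; well-tempered metadynamics with 2.0 kJ/mol initial hills of width
#' 0.1 Angstrom, pace 50 frames and bias factor 15; 300 K.
#'
#' @param archetype archetype surface to sample (see [archetype_potential()]),
#'   or `NULL` when `colvar_path` supplies measured CVs.
#' @param colvar_path optional COLVAR file to ingest instead of simulating.
#' @param cis_fraction true cis-attack probability for the attack-angle
#'   generator.
#' @param window_start,window_step,n_windows,window_k umbrella schedule.
#' @param equilibration_time,production_time per-window times, ps.
#' @param w0,sigma_g,pace,bias_factor metadynamics settings.
#' @param temperature,friction,timestep,mass engine settings.
#' @param theta_mean,theta_sd,theta_tau chelate dihedral OU settings (degrees,
#'   degrees, ps).
#' @param grid_xlim,grid_ylim,grid_nx,grid_ny FES grid.
#' @param n_walkers independent schedule replicas pooled into WHAM.
#' @param min_count sampled-mask threshold (reported in output metadata).
#' @param min_depth feature depth threshold, kJ/mol.
#' @param thresholds a [state_thresholds()].
#' @param seed master seed; all stage seeds derive from it.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(archetype = "dissociative", colvar_path = NULL,
                            cis_fraction = 0.627,
                            window_start = 2.50, window_step = 0.15,
                            n_windows = 20L, window_k = 350,
                            equilibration_time = 5, production_time = 40,
                            w0 = 2.0, sigma_g = 0.1, pace = 50L,
                            bias_factor = 15,
                            temperature = 300, friction = c(20, 1.5),
                            timestep = 0.002, mass = 1,
                            theta_mean = 15, theta_sd = 6, theta_tau = 1,
                            grid_xlim = c(2.0, 6.0), grid_ylim = c(2.0, 6.0),
                            grid_nx = 60L, grid_ny = 60L, n_walkers = 2L,
                            min_count = 5, min_depth = 2.5,
                            thresholds = state_thresholds(),
                            seed = 1L, outdir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Polynomial rolling hash over the JSON form of a config: cheap provenance
# fingerprint (mod 2^31 - 1 keeps every step exact in doubles).
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL  # where results land is not part of the analysis
  js <- jsonlite::toJSON(lapply(cfg, function(x)
    if (is.function(x)) "<function>" else x), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Stages: sample the archetype surface under the umbrella + metadynamics
#' protocol (or ingest a COLVAR file); attach attack angles and the chelate
#' dihedral from their generators; split samples by attack geometry;
#' reconstruct per-pathway free-energy surfaces with WHAM; locate the
#' photon-absorption region from an unbiased run; classify the mechanism;
#' compute planarity/rigidity descriptors. Artifacts (COLVAR, FES CSVs, JSON
#' report) are written to `cfg$outdir` when set, each carrying the config hash
#' and seed.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result`: `mechanism` (a
#'   `mechanism_report`), `attack` (an `attack_stats`), `planarity`,
#'   `fes` (per-pathway grids), `region`, `wham`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg)
  stage <- "setup"
  result <- tryCatch({
    params <- sim_params(temperature = cfg$temperature, friction = cfg$friction,
                         timestep = cfg$timestep, mass = cfg$mass,
                         n_steps = 1L, seed = cfg$seed)
    spec <- fes_grid_spec(cfg$grid_xlim, cfg$grid_ylim, cfg$grid_nx, cfg$grid_ny)

    stage <- "sampling"
    if (!is.null(cfg$colvar_path)) {
      samples <- read_colvar(cfg$colvar_path)
      if (!all(c("s1", "s2") %in% names(samples))) {
        m <- .cv2(samples)
        samples$s1 <- m[, 1]; samples$s2 <- m[, 2]
      }
      runs <- NULL
    } else {
      pot <- archetype_potential(cfg$archetype)
      schedule <- make_window_schedule(cfg$window_start, cfg$window_step,
                                       cfg$n_windows, cfg$window_k,
                                       cfg$equilibration_time,
                                       cfg$production_time)
      runs <- run_window_schedule(pot, schedule, params, w0 = cfg$w0,
                                  sigma = cfg$sigma_g,
                                  bias_factor = cfg$bias_factor,
                                  pace = cfg$pace, n_walkers = cfg$n_walkers)
      samples <- do.call(rbind, lapply(runs, function(r) r$series))
    }

    stage <- "colvar"
    n <- nrow(samples)
    att <- generate_attack_series(n, cfg$cis_fraction,
                                  cutoff = cfg$thresholds$interaction_cutoff,
                                  seed = cfg$seed + 1000L)
    theta <- generate_theta_series(cfg$theta_mean, cfg$theta_sd, n,
                                   relaxation_time = cfg$theta_tau,
                                   seed = cfg$seed + 2000L)
    samples$alpha <- att$alpha
    samples$theta <- theta
    samples$spin_Ru <- spin_surrogate(samples$s1, samples$s2)

    stage <- "attack statistics"
    qsamp <- data.frame(alpha = samples$alpha, d_RuOmin = samples$s2)
    attack <- attack_statistics(qsamp, cfg$thresholds$interaction_cutoff)

    stage <- "fes"
    if (!is.null(runs)) {
      wh <- wham_2d(runs, spec, min_count = cfg$min_count)
      fes <- list(cis = wh$grid, trans = wh$grid)
      wham_state <- wh$wham
    } else {
      halves <- split_by_attack(samples)
      fes <- lapply(halves, function(h)
        boltzmann_invert(h, spec, cfg$temperature, cfg$min_count))
      wham_state <- NULL
    }

    stage <- "absorption region"
    mlct_center <- if (!is.null(cfg$archetype))
      as.numeric(archetype_potential(cfg$archetype)$known_minima[1, ])
    else c(2.55, 4.5)
    singlet <- harmonic_potential(k = c(150, 150), center = mlct_center)
    region <- absorption_region(simulate_langevin(
      singlet,
      sim_params(cfg$temperature, cfg$friction, cfg$timestep, cfg$mass,
                 n_steps = 5000L, seed = cfg$seed + 3000L),
      n_equil = 500L))

    stage <- "mechanism"
    mech <- classify_mechanism(fes$cis, fes$trans, region, cfg$thresholds,
                               cis_pct = attack$cis_pct,
                               trans_pct = attack$trans_pct,
                               spin_field = spin_surrogate,
                               min_depth = cfg$min_depth)

    stage <- "descriptors"
    plan <- planarity_rigidity(samples$theta)

    out <- structure(list(mechanism = mech, attack = attack, planarity = plan,
                          fes = fes, region = region, wham = wham_state,
                          samples = samples, config_hash = hash,
                          seed = cfg$seed),
                     class = "pipeline_result")

    if (!is.null(cfg$outdir)) {
      stage <- "write outputs"
      dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
      prov <- data.frame(time = samples$time, s1 = samples$s1, s2 = samples$s2,
                         alpha = samples$alpha, theta = samples$theta,
                         spin_Ru = samples$spin_Ru)
      write_colvar(prov, file.path(cfg$outdir, "COLVAR"))
      write_fes(fes$cis, file.path(cfg$outdir, "fes_cis.csv"))
      if (!identical(fes$cis, fes$trans))
        write_fes(fes$trans, file.path(cfg$outdir, "fes_trans.csv"))
      report <- list(
        config_hash = hash, seed = cfg$seed,
        archetype = cfg$archetype,
        mechanism = mech$mechanism, pathway = mech$pathway,
        borderline = mech$borderline,
        cis_pct = attack$cis_pct, trans_pct = attack$trans_pct,
        mu_theta = plan$mu_theta, sigma_theta = plan$sigma_theta,
        intermediates = mech$intermediates,
        region_center = region$center, region_semi_axes = region$semi_axes,
        min_count = cfg$min_count)
      jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    }
    out
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> seed", x$seed, "config", x$config_hash, "\n")
  print(x$mechanism)
  print(x$attack)
  print(x$planarity)
  invisible(x)
}
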
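# Electronic-state labelling, the photon-absorption region, attack statistics
# and the photosubstitution mechanism classifier.

#' State-assignment thresholds
#'
#' Defaults follow the triplet-state anchors for this family of complexes:
#' Mulliken spin on Ru of about 0.7 (+/- `mlct_band`) with the thioether still
#' bound marks the MLCT state; spin beyond 1.2 marks metal-centred (MC)
#' character; 4.0 Angstrom is the maximum separation at which Ru still
#' interacts with the leaving S or incoming O; a Ru-O distance at or below
#' 2.5 Angstrom marks a true coordination bond (triplet product).
#'
#' @param mlct_spin centre of the MLCT spin band.
#' @param mlct_band half-width of the MLCT spin band.
#' @param mc_spin MC spin threshold (> `mlct_spin`).
#' @param interaction_cutoff interaction cutoff, Angstrom (> `product_bond`).
#' @param product_bond coordination-bond distance, Angstrom.
#' @param margin softness (Angstrom) of the heptacoordinate call: an
#'   intermediate whose Ru-Omin lies strictly within `margin` of the cutoff is
#'   transient (interchange-associative) rather than a true intermediate.
#' @return list of class `state_thresholds`.
#' @export
state_thresholds <- function(mlct_spin = 0.7, mlct_band = 0.2, mc_spin = 1.2,
                             interaction_cutoff = 4.0, product_bond = 2.5,
                             margin = 0.25) {
  if (mc_spin <= mlct_spin) stop("mc_spin must exceed mlct_spin")
  if (interaction_cutoff <= product_bond)
    stop("interaction_cutoff must exceed product_bond")
  structure(list(mlct_spin = mlct_spin, mlct_band = mlct_band,
                 mc_spin = mc_spin, interaction_cutoff = interaction_cutoff,
                 product_bond = product_bond, margin = margin),
            class = "state_thresholds")
}

#' cis/trans attack statistics
#'
#' Among samples whose Ru-Omin distance is below `cutoff`, the percentage with
#' a cis (alpha <= 90 deg) versus trans (alpha > 90 deg) angle of incidence,
#' reported to one decimal.
#'
#' @param samples data.frame with `alpha` and `d_RuOmin` columns.
#' @param cutoff interaction cutoff, Angstrom (> 0).
#' @return list of class `attack_stats`: `cis_pct`, `trans_pct`, `n_qualifying`,
#'   `n_total`. With zero qualifying samples the percentages are `NA` and
#'   `empty = TRUE` (never 0/0).
#' @export
attack_statistics <- function(samples, cutoff = 4.0) {
  stopifnot(cutoff > 0, all(c("alpha", "d_RuOmin") %in% names(samples)))
  q <- samples[!is.na(samples$d_RuOmin) & samples$d_RuOmin < cutoff &
                 !is.na(samples$alpha), , drop = FALSE]
  n <- nrow(q)
  if (n == 0)
    return(structure(list(cis_pct = NA_real_, trans_pct = NA_real_,
                          n_qualifying = 0L, n_total = nrow(samples),
                          empty = TRUE), class = "attack_stats"))
  n_cis <- sum(q$alpha <= 90)
  structure(list(cis_pct = round(100 * n_cis / n, 1),
                 trans_pct = round(100 * (n - n_cis) / n, 1),
                 n_qualifying = n, n_total = nrow(samples), empty = FALSE),
            class = "attack_stats")
}

#' @export
print.attack_stats <- function(x, ...) {
  if (x$empty) cat("<attack_stats> no qualifying samples of", x$n_total, "\n")
  else cat(sprintf("<attack_stats> cis %.1f%% / trans %.1f%% (n = %d of %d)\n",
                   x$cis_pct, x$trans_pct, x$n_qualifying, x$n_total))
  invisible(x)
}

#' Electronic-state label for a CV frame
#'
#' Sequential rules on (spin, Ru-S, Ru-Omin): MC when spin is at or above the
#' MC threshold with the Ru-S bond already stretched past a coordination bond;
#' MLCT when spin sits in the MLCT band with S still close; P (triplet aqua
#' product) when the water oxygen is coordinated and S has left; pentacoordinate
#' when both partners are beyond the interaction cutoff; otherwise unassigned.
#'
#' @param cv one-row data.frame (or list) with `d_RuS`, `d_RuOmin`, `spin_Ru`.
#' @param thr a [state_thresholds()].
#' @return character label: one of "MC", "MLCT", "P", "pentacoordinate",
#'   "unassigned". Vectorised over rows.
#' @export
label_state <- function(cv, thr = state_thresholds()) {
  if (is.null(cv$spin_Ru) || any(is.na(cv$spin_Ru)))
    stop("spin_Ru is required for state labelling")
  n <- length(cv$spin_Ru)
  out <- rep("unassigned", n)
  spin <- cv$spin_Ru; ds <- cv$d_RuS; do <- cv$d_RuOmin
  mc <- spin >= thr$mc_spin & ds > thr$product_bond
  mlct <- !mc & abs(spin - thr$mlct_spin) <= thr$mlct_band & ds <= 3.0
  p <- !mc & !mlct & do <= thr$product_bond & ds > thr$interaction_cutoff
  penta <- !mc & !mlct & !p & ds > thr$interaction_cutoff &
    do > thr$interaction_cutoff
  out[mc] <- "MC"; out[mlct] <- "MLCT"; out[p] <- "P"
  out[penta] <- "pentacoordinate"
  out
}

#' Photon-absorption region from unbiased singlet-state dynamics
#'
#' Axis-aligned ellipse centred at the per-CV means of an unbiased run, with
#' semi-axes 1.96 times the per-CV standard deviations. The per-axis convention
#' follows from computing per-CV standard deviations (not a covariance
#' ellipse); for independent Gaussian CVs its joint coverage is the analytic
#' value `(2 * pnorm(1.96) - 1)^2 +` cross terms, about 0.91, not 0.95.
#'
#' @param series `cv_series` with at least 100 frames (columns `s1`/`s2` or
#'   `d_RuS`/`d_RuOmin`).
#' @param z quantile multiplier (1.96 for the 95% per-axis convention).
#' @return list of class `absorption_region`: `center`, `semi_axes`,
#'   `degenerate`.
#' @export
absorption_region <- function(series, z = 1.96) {
  xy <- .cv2(series)
  if (nrow(xy) < 100) stop("need at least 100 frames for the absorption region")
  ctr <- colMeans(xy)
  sds <- apply(xy, 2, stats::sd)
  degenerate <- all(sds == 0)
  if (degenerate)
    warning("zero variance in both CVs: degenerate point region")
  structure(list(center = ctr, semi_axes = z * sds, z = z,
                 degenerate = degenerate),
            class = "absorption_region")
}

#' Does a point fall inside an absorption region?
#'
#' @param region an [absorption_region()].
#' @param s1,s2 coordinates (vectorised).
#' @return logical vector.
#' @export
in_region <- function(region, s1, s2) {
  a <- max(region$semi_axes[1], 1e-12)
  b <- max(region$semi_axes[2], 1e-12)
  ((s1 - region$center[1]) / a)^2 + ((s2 - region$center[2]) / b)^2 <= 1
}

#' Classify the photosubstitution mechanism from cis/trans FES grids
#'
#' Applies the intermediate taxonomy along the minimum-energy path (MEP) from
#' the photon-absorption region to the aqua-product region of the dominant
#' pathway's surface. Only reactive minima (MC, P, pentacoordinate,
#' heptacoordinate; spin-gated when a spin field is supplied) lying on or near
#' the MEP define the mechanism -- the taxonomy concerns intermediates along
#' the reaction path, not remote pockets. A pentacoordinate minimum (both
#' coordinates beyond the interaction cutoff) implies a dissociative
#' mechanism; a heptacoordinate minimum (both within the cutoff, beyond the
#' MLCT region) implies an associative mechanism, downgraded to
#' interchange-associative when its Ru-Omin hovers strictly within
#' `thr$margin` of the cutoff; with no such intermediates the mechanism is
#' interchange, subtyped by whether Ru-S crosses the cutoff before
#' (dissociative) or after (associative) Ru-Omin does along the MEP, and left
#' plain when the path is flat (barrier below 1 kT). With no reactive minima
#' beyond the MLCT region at all, the verdict is photoinactive.
#'
#' @param cis_grid,trans_grid `fes_grid`s on shared axes (either may be NULL
#'   if a pathway was never sampled; at least one required).
#' @param region an [absorption_region()] marking the MLCT (photon-absorption)
#'   bins.
#' @param thr a [state_thresholds()].
#' @param cis_pct,trans_pct qualifying-sample percentages (from
#'   [attack_statistics()]); the dominant pathway's grid is classified. Both
#'   pathways are always reported.
#' @param spin_field optional function `(d_RuS, d_RuOmin) -> spin` gating MC
#'   labels; when absent, geometry-only rules apply.
#' @param min_depth feature depth threshold passed to [find_features()],
#'   kJ/mol. The default of 1 kT at 300 K treats shallower basins as thermal
#'   or statistical texture, not intermediates.
#' @param smooth_sigma mask-aware smoothing (in bins, see [smooth_fes()])
#'   applied to both grids before feature analysis; 0 disables it. Grids from
#'   finite sampling need this to keep statistical bin noise from reading as
#'   intermediates.
#' @return list of class `mechanism_report`: `mechanism`, `pathway`,
#'   `cis_pct`, `trans_pct`, `intermediates` (data.frame with labels),
#'   `path` (MEP bins), `barrier`, `borderline`, `notes`.
#' @export
classify_mechanism <- function(cis_grid, trans_grid, region,
                               thr = state_thresholds(),
                               cis_pct = NA_real_, trans_pct = NA_real_,
                               spin_field = NULL, min_depth = 2.5,
                               smooth_sigma = 1.5) {
  grids <- list(cis = cis_grid, trans = trans_grid)
  grids <- grids[!vapply(grids, is.null, logical(1))]
  if (length(grids) == 0) stop("at least one pathway grid is required")
  if (smooth_sigma > 0) grids <- lapply(grids, smooth_fes, sigma_bins = smooth_sigma)

  label_min <- function(m, grid) {
    inside <- in_region(region, m$s1, m$s2)
    lab <- character(nrow(m))
    for (r in seq_len(nrow(m))) {
      s1 <- m$s1[r]; s2 <- m$s2[r]
      lab[r] <-
        if (inside[r]) "MLCT"
        else if (s1 > thr$interaction_cutoff && s2 <= thr$product_bond) "P"
        else if (s1 > thr$interaction_cutoff && s2 > thr$interaction_cutoff)
          "pentacoordinate"
        else if (s1 < thr$interaction_cutoff && s2 < thr$interaction_cutoff)
          "heptacoordinate"
        else "MC"
    }
    if (!is.null(spin_field)) {
      sp <- spin_field(m$s1, m$s2)
      lab[lab == "MC" & sp < thr$mc_spin] <- "other"
    }
    lab
  }

  feats <- lapply(grids, find_features, min_depth = min_depth,
                  interior_only = TRUE)
  mk_intermediates <- function(which_g) {
    f <- feats[[which_g]]; f <- f[f$kind == "minimum", , drop = FALSE]
    f$label <- label_min(f, grids[[which_g]])
    f
  }

  # dominant pathway = larger qualifying percentage (fall back to first grid)
  dom <- if (!is.na(cis_pct) && !is.na(trans_pct) && length(grids) == 2)
    if (cis_pct >= trans_pct) "cis" else "trans"
  else names(grids)[1]
  if (!dom %in% names(grids)) dom <- names(grids)[1]
  grid <- grids[[dom]]
  kT <- KB_KJMOL * grid$temperature
  intermediates <- mk_intermediates(which(names(grids) == dom))
  reactive_labels <- c("MC", "P", "pentacoordinate", "heptacoordinate")

  # start bin: sampled bin nearest the absorption-region center
  spec <- grid$spec
  sampled <- which(grid$sampled_mask, arr.ind = TRUE)
  d2 <- (spec$xcenters[sampled[, 1]] - region$center[1])^2 +
    (spec$ycenters[sampled[, 2]] - region$center[2])^2
  start_bin <- sampled[which.min(d2), ]

  # product bin: lowest-F sampled bin with S departed and O coordinated
  prod_ok <- sampled[spec$xcenters[sampled[, 1]] > thr$interaction_cutoff &
                       spec$ycenters[sampled[, 2]] <= thr$product_bond, ,
                     drop = FALSE]
  if (nrow(prod_ok) == 0) {
    # fall back to any dissociated region
    prod_ok <- sampled[spec$xcenters[sampled[, 1]] > thr$interaction_cutoff, ,
                       drop = FALSE]
  }
  if (nrow(prod_ok) == 0) {
    any_reactive <- any(vapply(seq_along(grids), function(gi)
      any(mk_intermediates(gi)$label %in% reactive_labels), logical(1)))
    return(structure(list(
      mechanism = if (any_reactive) "indeterminate" else "photoinactive",
      pathway = dom, cis_pct = cis_pct, trans_pct = trans_pct,
      intermediates = intermediates, path = NULL, barrier = NA_real_,
      borderline = FALSE,
      notes = if (any_reactive)
        "no product region sampled and no photoinactive signature"
      else "no reactive minima and no product region sampled"),
      class = "mechanism_report"))
  }
  prod_bin <- prod_ok[which.min(grid$F[prod_ok]), ]
  mep <- tryCatch(minimum_energy_path(grid, start_bin, prod_bin),
                  error = function(e) e)
  if (inherits(mep, "error")) {
    any_reactive <- any(intermediates$label %in% reactive_labels)
    return(structure(list(
      mechanism = if (any_reactive) "indeterminate" else "photoinactive",
      pathway = dom, cis_pct = cis_pct, trans_pct = trans_pct,
      intermediates = intermediates, path = NULL, barrier = NA_real_,
      borderline = FALSE,
      notes = paste("absorption region and product region are not connected",
                    "through sampled bins:", conditionMessage(mep))),
      class = "mechanism_report"))
  }
  barrier <- max(mep$F) - mep$F[1]

  # intermediates that matter sit on (or within path_margin of) the
  # minimum-energy path; remote statistical pockets do not define a mechanism
  path_margin <- 0.25
  near_path <- vapply(seq_len(nrow(intermediates)), function(r) {
    min(sqrt((mep$s1 - intermediates$s1[r])^2 +
               (mep$s2 - intermediates$s2[r])^2)) <= path_margin
  }, logical(1))
  intermediates$on_path <- near_path
  mins_path <- intermediates[near_path &
                               intermediates$label %in% reactive_labels, ,
                             drop = FALSE]

  if (nrow(mins_path) == 0) {
    return(structure(list(
      mechanism = "photoinactive", pathway = dom,
      cis_pct = cis_pct, trans_pct = trans_pct,
      intermediates = intermediates, path = mep, barrier = barrier,
      borderline = FALSE,
      notes = "no reactive minima along the minimum-energy path beyond the MLCT region"),
      class = "mechanism_report"))
  }

  has_penta <- any(mins_path$label == "pentacoordinate")
  hepta <- mins_path[mins_path$label == "heptacoordinate", , drop = FALSE]
  borderline <- FALSE

  if (has_penta) {
    mech <- "dissociative"
  } else if (nrow(hepta) > 0) {
    transient <- (thr$interaction_cutoff - hepta$s2) < thr$margin
    borderline <- any(abs((thr$interaction_cutoff - hepta$s2) - thr$margin) <
                        0.05)
    mech <- if (all(transient)) "interchange_associative" else "associative"
  } else if (barrier < kT) {
    mech <- "interchange"
  } else {
    # crossing order along the MEP
    s1_cross <- match(TRUE, mep$s1 > thr$interaction_cutoff)
    s2_cross <- match(TRUE, mep$s2 < thr$interaction_cutoff)
    mech <- if (is.na(s2_cross) || (!is.na(s1_cross) && s1_cross <= s2_cross))
      "interchange_dissociative" else "interchange_associative"
  }

  structure(list(mechanism = mech, pathway = dom,
                 cis_pct = cis_pct, trans_pct = trans_pct,
                 intermediates = intermediates, path = mep, barrier = barrier,
                 borderline = borderline,
                 notes = sprintf("MEP barrier %.2f kJ/mol (%.2f kT)",
                                 barrier, barrier / kT)),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("<mechanism_report>\n")
  cat("  mechanism:", x$mechanism,
      if (isTRUE(x$borderline)) "(borderline)", "\n")
  cat("  dominant pathway:", x$pathway, "\n")
  if (!is.na(x$cis_pct))
    cat(sprintf("  attack: cis %.1f%% / trans %.1f%%\n", x$cis_pct, x$trans_pct))
  if (!is.null(x$intermediates) && nrow(x$intermediates) > 0) {
    cat("  minima:\n")
    print(x$intermediates[, c("label", "s1", "s2", "F", "depth")])
  }
  cat("  ", x$notes, "\n")
  invisible(x)
}
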
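# File formats: PLUMED-dialect COLVAR tables, multi-frame XYZ, role-map JSON
# and FES serialisation. All text, all round-trip safe at double precision.

#' Write / read a COLVAR table
#'
#' PLUMED dialect: a `#! FIELDS time <cv names...>` header line followed by
#' whitespace-separated numeric columns. Unknown columns are preserved. Units
#' are Angstrom / ps / kJ/mol throughout.
#'
#' @param series data.frame whose first column is `time`.
#' @param path file path.
#' @return `read_colvar` returns a data.frame of class `cv_series` (column
#'   order-independent; extra columns kept).
#' @export
write_colvar <- function(series, path) {
  stopifnot("time" %in% names(series))
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("time", setdiff(names(series), "time"))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  num <- vapply(series[cols], is.numeric, logical(1))
  body <- do.call(paste, c(lapply(seq_along(cols), function(k) {
    v <- series[[cols[k]]]
    if (num[k]) sprintf("%.17g", as.numeric(v)) else as.character(v)
  }), sep = " "))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#! FIELDS"))
    stop("not a COLVAR file (missing '#! FIELDS' header): ", path)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", header), "\\s+")[[1]]
  if (!"time" %in% fields)
    stop("COLVAR file lacks mandatory column: time")
  tab <- tryCatch(
    utils::read.table(path, skip = 1, col.names = fields),
    error = function(e) stop("malformed COLVAR row in ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) != length(fields))
    stop("column count mismatch in ", path)
  tab <- tab[, c("time", setdiff(fields, "time")), drop = FALSE]
  class(tab) <- c("cv_series", "data.frame")
  tab
}

#' Write / read multi-frame XYZ
#'
#' Standard XYZ: per frame an atom count line, a comment line (carrying the
#' frame time), then `element x y z` rows in Angstrom.
#'
#' @param traj list with `frames` (list of n x 3 matrices), `elements`,
#'   optional `times`; a `toy_trajectory` works directly.
#' @param path file path.
#' @return `read_xyz` returns such a list (without roles).
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  times <- if (!is.null(traj$times)) traj$times else seq_along(traj$frames) - 1
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d time %.17g", i - 1, times[i]), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", traj$elements,
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ atom count at line ", i)
    cm <- lines[i + 1L]
    t <- suppressWarnings(as.numeric(sub(".*time\\s+", "", cm)))
    rows <- strsplit(trimws(lines[i + 1L + seq_len(nat)]), "\\s+")
    el <- vapply(rows, `[[`, character(1), 1)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, if (is.na(t)) length(frames) - 1 else t)
    if (is.null(elements)) elements <- el
    i <- i + 2L + nat
  }
  list(frames = frames, elements = elements, times = times)
}

#' Write / read a role map as JSON
#'
#' @param roles a [role_map()].
#' @param path file path.
#' @return `read_role_map` returns a [role_map()].
#' @export
write_role_map <- function(roles, path) {
  jsonlite::write_json(unclass(roles), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_role_map
#' @export
read_role_map <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  role_map(Ru = x$Ru, S = x$S, N_C = x$N_C, C_C = x$C_C, N_T = x$N_T,
           C_T = x$C_T, solvent_O = x$solvent_O)
}

#' Serialise an FES grid to CSV (+ JSON metadata)
#'
#' Long format: one row per bin with `s1`, `s2`, `F`, `count`, `sampled`.
#' Metadata (axes, temperature, mask threshold) goes to `<path>.meta.json`.
#'
#' @param grid an `fes_grid`.
#' @param path CSV file path.
#' @return `read_fes` reconstructs the `fes_grid`.
#' @export
write_fes <- function(grid, path) {
  spec <- grid$spec
  long <- expand.grid(ix = seq_len(spec$nx), iy = seq_len(spec$ny))
  long$s1 <- spec$xcenters[long$ix]
  long$s2 <- spec$ycenters[long$iy]
  long$F <- as.vector(grid$F)
  long$count <- as.vector(grid$counts)
  long$sampled <- as.vector(grid$sampled_mask)
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(xlim = spec$xlim, ylim = spec$ylim, nx = spec$nx, ny = spec$ny,
               names = spec$names, temperature = grid$temperature,
               min_count = grid$min_count)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  long <- utils::read.csv(path)
  spec <- fes_grid_spec(xlim = meta$xlim, ylim = meta$ylim, nx = meta$nx,
                        ny = meta$ny, names = meta$names)
  F <- matrix(NA_real_, meta$nx, meta$ny)
  counts <- matrix(0, meta$nx, meta$ny)
  F[cbind(long$ix, long$iy)] <- long$F
  counts[cbind(long$ix, long$iy)] <- long$count
  fes_grid(spec, F, counts, temperature = meta$temperature,
           min_count = meta$min_count)
}
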
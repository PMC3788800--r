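# Readers and writers for the plain-text exchange formats (ESRI ASCII grid,
# GeoJSON, CSV, YAML config) and the top-level pipeline runner.

#' Write a grid as an ESRI ASCII raster
#'
#' Single-band plain-text raster with NODATA_value -9999; values are written
#' with enough digits for a lossless double round-trip.
#'
#' @param g a `grid`
#' @param path output path (conventionally .asc)
#' @return the path, invisibly
#' @export
write_grid_asc <- function(g, path) {
  stopifnot(is_grid(g))
  d <- dim(g)
  v <- g$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", d[2]),
               sprintf("nrows %d", d[1]),
               sprintf("xllcorner %.10g", g$origin[1]),
               sprintf("yllcorner %.10g", g$origin[2] - d[1] * g$cell_size),
               sprintf("cellsize %.10g", g$cell_size),
               "NODATA_value -9999"), con)
  for (r in seq_len(d[1]))
    writeLines(paste(formatC(v[r, ], format = "g", digits = 10), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII raster as a grid
#'
#' @param path input path
#' @return a `grid`
#' @export
read_grid_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  ln <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(ln) && grepl("^[A-Za-z]", ln[i])) {
    kv <- strsplit(trimws(ln[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII raster (missing header fields): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = ln[i:length(ln)], quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("malformed ASCII raster (cell count mismatch): ", path)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  grid(m, cell_size = hdr$cellsize, origin = c(x0, y0 + nr * hdr$cellsize))
}

coords_list <- function(xy) lapply(seq_len(nrow(xy)), function(i) c(xy[i, 1], xy[i, 2]))

#' Write stream features as GeoJSON
#' @param streams list of stream features
#' @param path output path
#' @return the path, invisibly
#' @export
write_streams_geojson <- function(streams, path) {
  feats <- lapply(streams, function(s) list(
    type = "Feature",
    geometry = list(type = "LineString", coordinates = coords_list(s$xy)),
    properties = list(order = s$order, perennial = isTRUE(s$perennial),
                      large_river = isTRUE(s$large_river))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read stream features from GeoJSON
#' @param path input path
#' @return list of stream features
#' @export
read_streams_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  lapply(js$features, function(f) list(
    xy = do.call(rbind, lapply(f$geometry$coordinates, unlist)),
    order = as.integer(f$properties$order),
    perennial = isTRUE(f$properties$perennial),
    large_river = isTRUE(f$properties$large_river)))
}

#' Write wetland features as GeoJSON
#' @param wetlands list of wetland features
#' @param path output path
#' @return the path, invisibly
#' @export
write_wetlands_geojson <- function(wetlands, path) {
  feats <- lapply(wetlands, function(w) {
    ring <- rbind(w$xy, w$xy[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(coords_list(ring))),
         properties = list(area_ha = w$area_ha, kind = w$kind))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read wetland features from GeoJSON
#' @param path input path
#' @return list of wetland features
#' @export
read_wetlands_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  lapply(js$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    xy <- ring[-nrow(ring), , drop = FALSE]
    list(xy = xy, centroid = colMeans(xy),
         area_ha = as.numeric(f$properties$area_ha),
         kind = as.character(f$properties$kind))
  })
}

#' Write occurrences as CSV
#' @param records occurrence data.frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records[, c("species", "x", "y", "date", "accuracy_m",
                               "quality_rank")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read occurrences from CSV
#' @param path input path
#' @return occurrence data.frame
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("no such occurrence file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "date", "accuracy_m", "quality_rank")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("occurrence file missing column(s): ", paste(miss, collapse = ", "))
  out$date <- as.Date(out$date)
  out
}

#' Write a layer stack to a directory
#'
#' One ASCII raster per grid, streams and wetlands as GeoJSON.
#'
#' @param stack a `layer_stack`
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$grids))
    write_grid_asc(stack$grids[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_streams_geojson(stack$streams, file.path(dir, "streams.geojson"))
  write_wetlands_geojson(stack$wetlands, file.path(dir, "wetlands.geojson"))
  invisible(dir)
}

#' Read a layer stack from a directory
#' @param dir directory written by [write_stack()]
#' @return a `layer_stack`
#' @export
read_stack <- function(dir) {
  asc <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(asc)) stop("no rasters found in ", dir)
  grids <- stats::setNames(lapply(asc, read_grid_asc),
                           sub("\\.asc$", "", basename(asc)))
  streams <- if (file.exists(file.path(dir, "streams.geojson")))
    read_streams_geojson(file.path(dir, "streams.geojson")) else list()
  wetlands <- if (file.exists(file.path(dir, "wetlands.geojson")))
    read_wetlands_geojson(file.path(dir, "wetlands.geojson")) else list()
  layer_stack(grids, streams, wetlands)
}

#' Load a pipeline run configuration
#'
#' YAML configuration with sections `landscape` (any [landscape_params()]
#' argument), `groups`, `bins`, `seed`, `n_points`, `bias`, `output_dir` and
#' `thresholds` (any [model_options()] value). Every default is the
#' published table value; unknown keys raise an error naming the valid ones.
#'
#' @param path YAML file, or NULL for an all-default configuration
#' @return list with `landscape` (a `landscape_params`), `groups`, `bins`,
#'   `seed`, `n_points`, `bias`, `output_dir`, `options`, `overrides`
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  valid <- c("landscape", "groups", "bins", "seed", "n_points", "bias",
             "output_dir", "thresholds")
  bad <- setdiff(names(raw), valid)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  lp_args <- raw$landscape
  if (!is.null(lp_args)) {
    bad <- setdiff(names(lp_args), names(formals(landscape_params)))
    if (length(bad))
      stop("unknown landscape key(s): ", paste(bad, collapse = ", "),
           "; valid keys are: ",
           paste(names(formals(landscape_params)), collapse = ", "))
  }
  landscape <- do.call(landscape_params, as.list(lp_args))
  groups <- raw$groups %||% c("wetland", "riparian", "raptor", "sparse_grassland")
  bad <- setdiff(groups, c("wetland", "riparian", "raptor", "sparse_grassland"))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  bins <- raw$bins %||% 10
  if (bins < 2) stop("bins must be at least 2")
  overrides <- as.list(raw$thresholds)
  options <- do.call(model_options, overrides)
  list(landscape = landscape, groups = groups, bins = bins,
       seed = raw$seed %||% 1L, n_points = raw$n_points %||% 500,
       bias = raw$bias %||% 2, output_dir = raw$output_dir %||% "stopover_run",
       options = options, overrides = overrides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full modeling pipeline on a synthetic landscape
#'
#' Sequences generate -> model -> validate -> sensitivity -> exposure for
#' every requested bird group, writing the landscape, MIS rasters,
#' sensitivity tables, exposure surfaces and a JSON report to the output
#' directory. All randomness is drawn from per-stage sub-seeds of the single
#' configured seed, so two runs with the same configuration are identical.
#'
#' @param config a configuration list from [load_config()] (or a path to a
#'   YAML config file)
#' @param quiet suppress progress messages
#' @return invisible list with the stack, wind grid, and per-group results
#' @export
run_pipeline <- function(config = load_config(), quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("stopover pipeline run, seed %d", config$seed),
           sprintf("groups: %s", paste(config$groups, collapse = ", ")))
  if (length(config$overrides))
    log <- c(log, paste("table-value override:",
                        names(config$overrides), "=",
                        vapply(config$overrides, function(x)
                          paste(x, collapse = ","), "")))
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max - 1L, 2L + 2L * length(config$groups)))
  say("generating landscape (%d x %d cells)...",
      config$landscape$extent_cells[1], config$landscape$extent_cells[2])
  stack <- generate_landscape(config$landscape, seed = seeds[1])
  wind <- generate_wind_potential(stack, seed = seeds[2])
  write_stack(stack, file.path(out_dir, "landscape"))
  write_grid_asc(wind, file.path(out_dir, "wind_potential.asc"))
  results <- list()
  for (gi in seq_along(config$groups)) {
    gname <- config$groups[gi]
    say("modeling %s birds...", gname)
    model <- migration_model(stack, gname, options = config$options)
    write_grid_asc(model$mis, file.path(out_dir, paste0("mis_", gname, ".asc")))
    occ <- generate_occurrences(model$mis, n = config$n_points,
                                bias = config$bias, seed = seeds[2 + 2 * gi - 1])
    write_occurrences(occ, file.path(out_dir, paste0("occurrences_", gname, ".csv")))
    filtered <- thin_min_distance(filter_by_accuracy(occ))
    valpts <- stratified_subsample(filtered, seed = seeds[2 + 2 * gi])
    bw <- boyce(model, valpts, k = config$bins)
    sens <- sensitivity(model)
    utils::write.csv(sens$table,
                     file.path(out_dir, paste0("sensitivity_", gname, ".csv")),
                     row.names = FALSE)
    write_grid_asc(sens$uncertainty,
                   file.path(out_dir, paste0("uncertainty_", gname, ".asc")))
    exp_rep <- exposure_report(model, wind, partials = sens$partials)
    write_grid_asc(exp_rep$exposure, file.path(out_dir, paste0("exposure_", gname, ".asc")))
    write_grid_asc(exp_rep$classes, file.path(out_dir, paste0("exposure_class_", gname, ".asc")))
    if (!is.null(exp_rep$sd))
      write_grid_asc(exp_rep$sd, file.path(out_dir, paste0("exposure_sd_", gname, ".asc")))
    utils::write.csv(exp_rep$overlap,
                     file.path(out_dir, paste0("overlap_", gname, ".csv")),
                     row.names = FALSE)
    results[[gname]] <- list(model = model, boyce = bw, sensitivity = sens,
                             exposure = exp_rep, n_validation = nrow(valpts))
    log <- c(log, sprintf("%s: boyce %.3f (p %.4g, %d bins), %d validation points",
                          gname, bw$rho, bw$p_value, bw$k_effective, nrow(valpts)))
  }
  # cumulative top-two-quantile concentration across groups
  masks <- lapply(results, function(r) r$exposure$mig_mask)
  cum <- cumulative_mask(masks)
  wind_mask <- results[[1]]$exposure$wind_mask
  cum_overlap <- overlap_percentages(cum, wind_mask)
  write_grid_asc(cum, file.path(out_dir, "cumulative_top2_mask.asc"))
  report <- list(
    seed = config$seed,
    groups = lapply(results, function(r) list(
      boyce = r$boyce$rho, boyce_p = r$boyce$p_value,
      k_effective = r$boyce$k_effective,
      n_validation = r$n_validation,
      overlap = r$exposure$overlap)),
    cumulative_overlap = as.list(cum_overlap))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log, sprintf("cumulative top-two overlap: %.1f%% of migration area, %.1f%% of wind area",
                            cum_overlap[1], cum_overlap[2])),
             file.path(out_dir, "run_log.txt"))
  say("done; outputs in %s", out_dir)
  invisible(list(stack = stack, wind = wind, groups = results,
                 cumulative_overlap = cum_overlap))
}
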
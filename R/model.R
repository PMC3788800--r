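# The four group model specifications and their evaluation against a layer
# stack. Each model is MIS_c = normalize( sum_i w_i * normalize(f_ci * prod m) ),
# the migratory importance score for cell c: factors f in [0, 1], multiplicative
# modifiers m in [0, 2] applied before per-term normalization, weights w
# applied after, and a final normalization to [0, 1].

#' Default model parameterization
#'
#' All tunable table values of the four group models, overridable one by one
#' (e.g. for sensitivity experiments or small-extent test landscapes).
#' Elevation and proximity class boundaries are closed on the left.
#'
#' @param ... named overrides of any default
#' @return named list of parameters
#' @export
model_options <- function(...) {
  defaults <- list(
    elevation_breaks_m   = c(2438, 2743),
    elevation_values     = c(1, 0.5, 0.1),
    proximity_breaks_m   = c(5000, 10000),
    proximity_values     = c(2, 1.5, 1),
    proximity_min_order  = 3,
    flyway_value         = 1.25,
    density_radius_m     = 5000,
    density_anchors      = c(2, 28),      # wetlands/km^2 at ramp start / top
    density_low_value    = 0.25,
    wetland_size_breaks_ha = c(5, 15),
    wetland_size_values  = c(0, 0.5, 1),  # <5 / 5-15 / >15 ha
    decay_max_dist_m     = 500,
    buffer_dist_m        = 1000,
    tpi_windows_cells    = c(20, 50),
    tpi_threshold        = 1,
    stream_value_large   = 1,
    stream_value_order34 = 0.5,
    stream_value_order2  = 0.25,
    riparian_perennial_value    = 1,
    riparian_intermittent_value = 0.25,
    forage_values        = c(grain = 1, hay_pasture = 0.5),
    landcover_values     = c(shortmix_prairie = 1, medtall_grass = 0.5,
                             arid_shrub = 0.25),
    structural_values    = c(forest_riparian = 2, riparian_woodland_shrubland = 1.5,
                             shrub_riparian = 1.25, grass_riparian = 1),
    orientation_halo_m   = 500)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(defaults))
    if (length(bad))
      stop("unknown model option(s): ", paste(bad, collapse = ", "),
           "; valid options are: ", paste(names(defaults), collapse = ", "))
    defaults[names(ov)] <- ov
  }
  defaults
}

new_term <- function(factor, modifiers, weight, label) {
  list(factor = factor, modifiers = modifiers, weight = weight, label = label)
}

#' Canonical model specification for a bird group
#'
#' Returns the published term structure for one of the four functional
#' groups: ordered terms of (factor, modifiers, weight). Wetland birds weight
#' wetland density 3x; riparian birds weight streams 2x; raptor and sparse
#' grassland terms are unweighted.
#'
#' @param group one of "wetland", "riparian", "raptor", "sparse_grassland"
#' @return object of class `group_model_spec`
#' @export
canned_spec <- function(group = c("wetland", "riparian", "raptor", "sparse_grassland")) {
  group <- match.arg(group)
  terms <- switch(group,
    wetland = list(
      new_term("streams_wetland", character(0), 1, "Streams"),
      new_term("wetland_density",
               c("elevation", "river_proximity", "flyway"), 3, "Wetland density"),
      new_term("wetland_size",
               c("elevation", "river_proximity", "flyway"), 1, "Wetland size"),
      new_term("forage", "river_proximity", 1, "Forage availability"),
      new_term("takeoff_buffer", character(0), 1, "Take-off/approach buffer")),
    riparian = list(
      new_term("streams_riparian",
               c("stream_orientation", "cottonwood", "willow", "structural_diversity"),
               2, "Streams"),
      new_term("wetland_density",
               c("elevation", "river_proximity"), 1, "Wetland density")),
    raptor = list(
      new_term("topography", "topo_orientation", 1, "Topography"),
      new_term("updrafts", character(0), 1, "Updrafts"),
      new_term("thermals", character(0), 1, "Thermal formation"),
      new_term("streams_raptor", c("stream_orientation", "cottonwood"),
               1, "Streams")),
    sparse_grassland = list(
      new_term("grassland_landcover", "bare_ground", 1, "Land cover"),
      new_term("prairie_dog", character(0), 1, "Prairie dog occurrence")))
  season <- if (group == "raptor") "fall" else "spring"
  structure(list(group = group, season = season, terms = terms),
            class = "group_model_spec")
}

#' @export
print.group_model_spec <- function(x, ...) {
  cat(sprintf("<group_model_spec> %s birds (%s migration), %d terms\n",
              x$group, x$season, length(x$terms)))
  for (t in x$terms)
    cat(sprintf("  w=%g  %s%s\n", t$weight, t$label,
                if (length(t$modifiers))
                  paste0(" * ", paste(t$modifiers, collapse = " * ")) else ""))
  invisible(x)
}

modifier_label <- function(modifier_id) {
  switch(modifier_id,
         elevation = "elevation", river_proximity = "river proximity",
         flyway = "flyway location", stream_orientation = "orientation",
         topo_orientation = "orientation", cottonwood = "cottonwood abundance",
         willow = "willow abundance", structural_diversity = "structural diversity",
         bare_ground = "bare ground", modifier_id)
}

stream_template <- function(stack) stack$grids[[1]]

need_layer <- function(stack, name) {
  if (!name %in% names(stack$grids))
    stop("stack is missing required layer '", name, "'")
  stack$grids[[name]]
}

stream_factor_features <- function(streams, valuer) {
  out <- list()
  for (s in streams) {
    v <- valuer(s)
    if (v > 0) out[[length(out) + 1L]] <- list(xy = s$xy, value = v)
  }
  out
}

#' Build a model factor layer from a layer stack
#'
#' Values each factor exactly per its published table: stream classes, the
#' wetland density ramp, wetland size classes, crop forage classes, the 1-km
#' take-off/approach buffer, topographic position, updraft matching, the
#' bare-ground thermal index (with croplands added), grassland land cover
#' classes and the prairie-dog index.
#'
#' @param factor_id one of the registered factor ids (see [canned_spec()])
#' @param stack a `layer_stack`
#' @param options a [model_options()] list
#' @return a factor `grid` in [0, 1]
#' @export
prepare_factor <- function(factor_id, stack, options = model_options()) {
  o <- options
  tpl <- stream_template(stack)
  switch(factor_id,
    streams_wetland = rasterize_valued_features(
      stream_factor_features(stack$streams, function(s) {
        if (isTRUE(s$large_river)) o$stream_value_large
        else if (s$order %in% 3:4) o$stream_value_order34
        else if (s$order == 2) o$stream_value_order2 else 0
      }), tpl),
    streams_riparian = inverse_distance_decay(
      rasterize_valued_features(
        stream_factor_features(stack$streams, function(s) {
          if (s$order >= 2 && s$order <= 7)
            if (isTRUE(s$perennial)) o$riparian_perennial_value
            else o$riparian_intermittent_value
          else 0
        }), tpl),
      max_dist = o$decay_max_dist_m),
    streams_raptor = inverse_distance_decay(
      rasterize_valued_features(
        stream_factor_features(stack$streams, function(s) {
          if (isTRUE(s$large_river)) o$stream_value_large
          else if (s$order %in% 3:4) o$stream_value_order34 else 0
        }), tpl),
      max_dist = o$decay_max_dist_m),
    wetland_density = density_to_importance(
      focal_wetland_density(stack$wetlands, tpl, radius = o$density_radius_m),
      lower = o$density_anchors[1], upper = o$density_anchors[2],
      low_value = o$density_low_value),
    wetland_size = rasterize_valued_features(
      lapply(stack$wetlands, function(w)
        list(xy = w$xy, polygon = TRUE, value = wetland_size_value(w$area_ha, o))),
      tpl),
    forage = {
      cr <- need_layer(stack, "crops")$values
      v <- matrix(0, nrow(cr), ncol(cr))
      v[cr == crop_codes()[["grain"]]] <- o$forage_values[["grain"]]
      v[cr == crop_codes()[["hay_pasture"]]] <- o$forage_values[["hay_pasture"]]
      v[is.na(cr)] <- NA
      grid_like(tpl, v)
    },
    takeoff_buffer = {
      src <- grid_like(tpl, pmax(
        prepare_factor("streams_wetland", stack, o)$values,
        prepare_factor("wetland_size", stack, o)$values))
      buffer_carry_value(src, dist = o$buffer_dist_m)
    },
    topography = topographic_position(need_layer(stack, "elevation"),
                                      windows = o$tpi_windows_cells,
                                      threshold = o$tpi_threshold),
    updrafts = updraft_factor(need_layer(stack, "aspect"),
                              need_layer(stack, "wind_direction_category")),
    thermals = {
      bg <- need_layer(stack, "bare_ground")$values
      cr <- need_layer(stack, "crops")$values
      grid_like(tpl, pmax(bg, as.numeric(cr > 0)))
    },
    grassland_landcover = {
      lc <- need_layer(stack, "land_cover")$values
      codes <- landcover_codes()
      v <- matrix(0, nrow(lc), ncol(lc))
      for (nm in names(o$landcover_values))
        v[lc == codes[[nm]]] <- o$landcover_values[[nm]]
      v[is.na(lc)] <- NA
      grid_like(tpl, v)
    },
    prairie_dog = need_layer(stack, "prairie_dog"),
    stop("unknown factor id '", factor_id, "'"))
}

wetland_size_value <- function(area_ha, o) {
  br <- o$wetland_size_breaks_ha; vv <- o$wetland_size_values
  if (area_ha < br[1]) vv[1] else if (area_ha <= br[2]) vv[2] else vv[3]
}

#' Build a model modifier layer from a layer stack
#'
#' Elevation and river-proximity class steps, the flyway bump, per-feature
#' stream/ridge orientation (northness in [1, 2] carried along each feature's
#' footprint and a short halo), cottonwood / willow / bare-ground indices
#' mapped linearly from [0, 1] to [1, 2], and riparian structural diversity
#' classes. Modifiers are neutral (1) outside their feature support.
#'
#' @param modifier_id one of the registered modifier ids
#' @param stack a `layer_stack`
#' @param options a [model_options()] list
#' @return a modifier `grid` in [0, 2]
#' @export
prepare_modifier <- function(modifier_id, stack, options = model_options()) {
  o <- options
  tpl <- stream_template(stack)
  switch(modifier_id,
    elevation = {
      z <- need_layer(stack, "elevation")$values
      v <- ifelse(z < o$elevation_breaks_m[1], o$elevation_values[1],
                  ifelse(z < o$elevation_breaks_m[2], o$elevation_values[2],
                         o$elevation_values[3]))
      grid_like(tpl, v)
    },
    river_proximity = {
      big <- stream_factor_features(stack$streams,
               function(s) as.numeric(s$order >= o$proximity_min_order))
      if (!length(big)) return(grid_like(tpl, matrix(o$proximity_values[3],
                                                     nrow(tpl$values), ncol(tpl$values))))
      r <- rasterize_valued_features(big, tpl)
      d <- grid_distance_to(tpl, !is.na(r$values) & r$values > 0)$values
      v <- ifelse(d < o$proximity_breaks_m[1], o$proximity_values[1],
                  ifelse(d < o$proximity_breaks_m[2], o$proximity_values[2],
                         o$proximity_values[3]))
      v[is.na(tpl$values)] <- NA
      grid_like(tpl, v)
    },
    flyway = {
      f <- need_layer(stack, "flyway_mask")$values
      grid_like(tpl, ifelse(f > 0, o$flyway_value, 1))
    },
    stream_orientation = orientation_modifier(
      lapply(stack$streams, function(s) if (s$order >= 2) s$xy else NULL),
      tpl, halo = o$orientation_halo_m),
    topo_orientation = {
      tp <- prepare_factor("topography", stack, o)
      ridge_orientation_modifier(tp, tpl)
    },
    cottonwood = grid_like(tpl, 1 + need_layer(stack, "cottonwood")$values),
    willow = grid_like(tpl, 1 + need_layer(stack, "willow")$values),
    bare_ground = grid_like(tpl, 1 + need_layer(stack, "bare_ground")$values),
    structural_diversity = {
      lc <- need_layer(stack, "land_cover")$values
      codes <- landcover_codes()
      v <- matrix(1, nrow(lc), ncol(lc))
      for (nm in names(o$structural_values))
        v[lc == codes[[nm]]] <- o$structural_values[[nm]]
      v[is.na(lc)] <- NA
      grid_like(tpl, v)
    },
    stop("unknown modifier id '", modifier_id, "'"))
}

# Northness of each feature applied along its rasterized footprint and a halo
# of `halo` meters (so modifiers cover decayed stream factors); neutral 1
# elsewhere. Nearer features win where halos overlap.
orientation_modifier <- function(feature_xys, tpl, halo = 500) {
  feature_xys <- feature_xys[!vapply(feature_xys, is.null, TRUE)]
  nr <- nrow(tpl$values); nc <- ncol(tpl$values)
  out <- matrix(1, nr, nc)
  if (length(feature_xys)) {
    best <- matrix(Inf, nr, nc)
    halo_sq <- (halo / tpl$cell_size)^2
    for (xy in feature_xys) {
      north <- min_rect_northness(xy)
      r <- rasterize_valued_features(list(list(xy = xy, value = 1)), tpl)
      dsq <- dist_transform_sq(!is.na(r$values) & r$values > 0)
      sel <- dsq <= halo_sq & dsq < best
      out[sel] <- north
      best[sel] <- dsq[sel]
    }
  }
  out[is.na(tpl$values)] <- NA
  grid_like(tpl, out)
}

# Northness of each connected ridge component of the TPI factor, applied on
# the component's cells; neutral 1 elsewhere.
ridge_orientation_modifier <- function(topo_factor, tpl) {
  lab <- label_components(!is.na(topo_factor$values) & topo_factor$values > 0)
  out <- matrix(1, nrow(lab), ncol(lab))
  cc <- cell_centers(tpl)
  for (id in setdiff(unique(as.vector(lab)), 0L)) {
    idx <- which(lab == id, arr.ind = TRUE)
    xy <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
    if (nrow(unique(xy)) < 2) next     # single-cell ridge: no orientation
    out[lab == id] <- min_rect_northness(xy)
  }
  out[is.na(tpl$values)] <- NA
  grid_like(tpl, out)
}

# Build all factor and modifier layers a spec needs (cached by id).
build_layers <- function(spec, stack, options) {
  fids <- unique(vapply(spec$terms, `[[`, "", "factor"))
  mids <- unique(unlist(lapply(spec$terms, `[[`, "modifiers")))
  list(factors = stats::setNames(lapply(fids, prepare_factor, stack = stack,
                                        options = options), fids),
       modifiers = stats::setNames(lapply(mids, prepare_modifier, stack = stack,
                                          options = options), mids))
}

# Evaluate a spec from prebuilt layers.
evaluate_spec <- function(spec, layers) {
  terms <- lapply(spec$terms, function(t) {
    normalize01(apply_modifiers(layers$factors[[t$factor]],
                                layers$modifiers[t$modifiers]))
  })
  weights <- vapply(spec$terms, `[[`, 0, "weight")
  combine_mis(terms, weights)
}

#' Deductive migratory-concentration model for one bird group
#'
#' Evaluates a group model specification against a landscape: each factor is
#' built from the stack, multiplied by its modifiers, normalized to [0, 1],
#' weighted, summed and renormalized, giving the migratory importance score
#' (MIS) raster. The returned object supports `print`, `summary`, `coef`,
#' `plot`, `predict` (scores at point locations) and `simulate` (biased
#' occurrence points).
#'
#' @param stack a `layer_stack`
#' @param group one of "wetland", "riparian", "raptor", "sparse_grassland"
#' @param spec optional custom `group_model_spec` (defaults to the published
#'   spec for `group`)
#' @param options a [model_options()] list of table-value overrides
#' @return object of class `migration_model` with elements `mis` (a `grid` in
#'   [0, 1]), `spec`, `layers`, `options`, `stack`
#' @export
migration_model <- function(stack, group = c("wetland", "riparian", "raptor",
                                             "sparse_grassland"),
                            spec = NULL, options = model_options()) {
  stopifnot(inherits(stack, "layer_stack"))
  if (is.null(spec)) {
    group <- match.arg(group)
    spec <- canned_spec(group)
  } else group <- spec$group
  if (!length(spec$terms)) stop("spec needs at least one term")
  layers <- build_layers(spec, stack, options)
  mis <- evaluate_spec(spec, layers)
  structure(list(group = group, spec = spec, options = options,
                 layers = layers, mis = mis, stack = stack),
            class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat(sprintf("<migration_model> %s birds (%s migration)\n",
              x$spec$group, x$spec$season))
  print(x$spec)
  v <- x$mis$values[!is.na(x$mis$values)]
  cat(sprintf("MIS: %d cells, mean %.3f, %.1f%% zero\n",
              length(v), mean(v), 100 * mean(v == 0)))
  invisible(x)
}

#' @export
summary.migration_model <- function(object, k = 5, ...) {
  v <- object$mis$values[!is.na(object$mis$values)]
  qc <- quantile_classify(object$mis, k = k)
  out <- list(group = object$spec$group, season = object$spec$season,
              n_terms = length(object$spec$terms),
              weights = stats::setNames(vapply(object$spec$terms, `[[`, 0, "weight"),
                                        vapply(object$spec$terms, `[[`, "", "label")),
              n_cells = length(v), mean = mean(v), sd = stats::sd(v),
              prop_zero = mean(v == 0), quantile_breaks = qc$breaks,
              k_effective = qc$k_effective)
  class(out) <- "summary.migration_model"
  out
}

#' @export
print.summary.migration_model <- function(x, ...) {
  cat(sprintf("Migratory importance model: %s birds (%s)\n", x$group, x$season))
  cat(sprintf("%d terms; weights: %s\n", x$n_terms,
              paste(sprintf("%s=%g", names(x$weights), x$weights), collapse = ", ")))
  cat(sprintf("MIS over %d cells: mean %.3f (sd %.3f), %.1f%% zero\n",
              x$n_cells, x$mean, x$sd, 100 * x$prop_zero))
  cat(sprintf("Quantile breaks (k_eff = %d): %s\n", x$k_effective,
              paste(signif(x$quantile_breaks, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.migration_model <- function(object, ...) {
  stats::setNames(vapply(object$spec$terms, `[[`, 0, "weight"),
                  vapply(object$spec$terms, `[[`, "", "label"))
}

#' @export
plot.migration_model <- function(x, ...) {
  plot(x$mis, main = sprintf("MIS: %s birds", x$spec$group), ...)
}

#' Extract model scores at point locations
#'
#' @param object a `migration_model`
#' @param newdata data.frame with columns `x`, `y` (projected meters)
#' @param ... unused
#' @return numeric vector of MIS values (NA outside the extent)
#' @export
predict.migration_model <- function(object, newdata, ...) {
  grid_extract(object$mis, newdata$x, newdata$y)
}

#' Simulate occurrence points from a model
#'
#' Draws occurrence sets biased toward high model scores via
#' [generate_occurrences()].
#'
#' @param object a `migration_model`
#' @param nsim number of occurrence sets
#' @param seed integer seed
#' @param n,bias,n_species passed to [generate_occurrences()]
#' @param ... unused
#' @return a list of occurrence data.frames (length `nsim`)
#' @export
simulate.migration_model <- function(object, nsim = 1, seed = 1, n = 500,
                                     bias = 2, n_species = 10, ...) {
  lapply(seq_len(nsim), function(i)
    generate_occurrences(object$mis, n = n, bias = bias,
                         n_species = n_species, seed = seed + i - 1L))
}
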
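# Grid-algebra building blocks shared by the four group models: kernel
# density of wetlands, the density->importance ramp, inverse-distance-squared
# decay, carry-value buffering, topographic position, updraft matching,
# modifier application and the weighted model combination.

#' Wetland density within a circular window
#'
#' Counts wetland representative points (polygon centroids) within a circular
#' window around each cell center and divides by the window area, giving
#' wetlands per square kilometer. Counting centroids avoids double-counting
#' polygons that span several cells.
#'
#' @param wetlands wetland set (see [generate_landscape()]): list of features
#'   each with `centroid` (x, y) — or a 2-column matrix of points.
#' @param template a `grid`
#' @param radius window radius in meters (default 5000)
#' @return a `grid` of densities (wetlands / km^2)
#' @export
focal_wetland_density <- function(wetlands, template, radius = 5000) {
  stopifnot(is_grid(template))
  if (radius < template$cell_size)
    stop("density window radius must be at least one cell")
  pts <- wetland_points(wetlands)
  counts <- matrix(0, nrow(template$values), ncol(template$values))
  cc <- cell_centers(template)
  r2 <- radius^2
  for (i in seq_len(nrow(pts))) {
    dx2 <- (cc$x - pts[i, 1])^2
    dy2 <- (cc$y - pts[i, 2])^2
    cols <- which(dx2 <= r2); rows <- which(dy2 <= r2)
    if (!length(cols) || !length(rows)) next
    hit <- outer(dy2[rows], dx2[cols], "+") <= r2
    counts[rows, cols] <- counts[rows, cols] + hit
  }
  dens <- counts / (pi * (radius / 1000)^2)
  dens[is.na(template$values)] <- NA
  grid_like(template, dens)
}

wetland_points <- function(wetlands) {
  if (is.matrix(wetlands)) return(wetlands)
  if (!length(wetlands)) return(matrix(numeric(0), 0, 2))
  do.call(rbind, lapply(wetlands, function(w) {
    if (!is.null(w$centroid)) rbind(w$centroid) else rbind(colMeans(w$xy))
  }))
}

#' Map wetland density to a migration importance factor
#'
#' Below `lower` wetlands/km^2 the factor is 0 (no importance); importance
#' rises linearly from `low_value` at `lower` to 1 at `upper`, and clamps at 1
#' above `upper`.
#'
#' @param density a `grid` of wetland densities (per km^2), non-negative
#' @param lower,upper ramp anchors in wetlands/km^2 (defaults 2 and 28)
#' @param low_value factor value at the lower anchor (default 0.25)
#' @return a factor `grid` in [0, 1]
#' @export
density_to_importance <- function(density, lower = 2, upper = 28, low_value = 0.25) {
  stopifnot(is_grid(density))
  d <- density$values
  if (any(d < 0, na.rm = TRUE)) stop("densities must be non-negative")
  v <- low_value + (d - lower) / (upper - lower) * (1 - low_value)
  v <- pmin(v, 1)
  v[d < lower] <- 0
  grid_like(density, v)
}

# distinct positive values of a grid, decreasing
positive_levels <- function(g) {
  v <- unique(g$values[!is.na(g$values) & g$values > 0])
  sort(v, decreasing = TRUE)
}

#' Inverse-distance-squared decay around valued source cells
#'
#' Source cells (positive values) keep their value; a non-source cell at
#' center-to-center distance `d <= max_dist` from its nearest source takes
#' `v * min(1, (cell_size/d)^2)` where `v` is the nearest source's value
#' (ties between equally near sources resolved toward the larger value);
#' beyond `max_dist` the result is 0.
#'
#' @param valued a `grid` with values in [0, 1]; positive cells are sources
#' @param max_dist decay cutoff in meters (default 500)
#' @return a `grid` in [0, 1]
#' @export
inverse_distance_decay <- function(valued, max_dist = 500) {
  stopifnot(is_grid(valued))
  v <- valued$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("source values must lie in [0, 1]")
  cs <- valued$cell_size
  levels <- positive_levels(valued)
  out <- matrix(0, nrow(v), ncol(v))
  if (length(levels)) {
    dsq <- lapply(levels, function(lv) dist_transform_sq(!is.na(v) & v == lv))
    dall <- Reduce(pmin, dsq)
    assigned <- matrix(FALSE, nrow(v), ncol(v))
    maxd_cells_sq <- (max_dist / cs)^2
    for (i in seq_along(levels)) {
      sel <- !assigned & dsq[[i]] == dall & dall > 0 & dall <= maxd_cells_sq
      if (any(sel)) {
        d_m <- sqrt(dall[sel]) * cs
        out[sel] <- levels[i] * pmin(1, (cs / d_m)^2)
        assigned[sel] <- TRUE
      }
    }
    src <- !is.na(v) & v > 0
    out[src] <- v[src]
  }
  out[is.na(v)] <- NA
  grid_like(valued, out)
}

#' Carry feature values through a buffer
#'
#' Every cell within `dist` (center-to-center) of a valued source cell takes
#' that source's value; overlapping buffers combine by maximum. Used for the
#' 1-km take-off/approach buffer around valued wetlands and streams.
#'
#' @param valued a `grid`; positive cells are sources
#' @param dist buffer distance in meters (default 1000)
#' @return a `grid`
#' @export
buffer_carry_value <- function(valued, dist = 1000) {
  stopifnot(is_grid(valued))
  if (dist <= 0) stop("buffer distance must be positive")
  v <- valued$values
  cs <- valued$cell_size
  out <- matrix(0, nrow(v), ncol(v))
  maxd_cells_sq <- (dist / cs)^2
  for (lv in positive_levels(valued)) {
    dsq <- dist_transform_sq(!is.na(v) & v == lv)
    out <- pmax(out, lv * (dsq <= maxd_cells_sq))
  }
  out[is.na(v)] <- NA
  grid_like(valued, out)
}

# Standardized topographic position: elevation minus its circular focal mean,
# divided by the standard deviation of that difference over unmasked cells.
# `window` is the window diameter in cells.
standardized_tpi <- function(elev, window) {
  radius <- floor(window / 2)
  if (2 * radius + 1 > min(dim(elev)))
    stop("TPI window larger than grid")
  tpi <- elev$values - focal_disc_mean(elev$values, radius)
  s <- stats::sd(tpi[!is.na(tpi)])
  # a relief-free surface has only FFT round-off in tpi; treat it as flat
  relief <- diff(range(elev$values, na.rm = TRUE))
  if (!is.finite(s) || s <= 1e-9 * max(1, relief)) tpi[] <- 0 * tpi
  else tpi <- tpi / s
  grid_like(elev, tpi)
}

#' Ridge / prominent-landform factor from topographic position
#'
#' Computes the topographic position index (elevation minus the mean
#' elevation in a circular window) at two window sizes, standardizes each by
#' its own standard deviation, and flags cells whose standardized TPI exceeds
#' `threshold` in either window — tall ridges, foothills and hogbacks under
#' the usual landform convention. Window sizes are diameters in cells.
#'
#' @param elev elevation `grid`
#' @param windows two window diameters in cells (default `c(20, 50)`)
#' @param threshold standardized-TPI cutoff (default 1)
#' @return a binary factor `grid` (1 = ridge-like landform)
#' @export
topographic_position <- function(elev, windows = c(20, 50), threshold = 1) {
  stopifnot(is_grid(elev))
  stp <- lapply(windows, function(w) standardized_tpi(elev, w))
  hit <- Reduce(`|`, lapply(stp, function(s) s$values > threshold))
  out <- grid_like(elev, ifelse(hit, 1, 0))
  out$values[is.na(elev$values)] <- NA
  attr(out, "stpi") <- grid_like(elev, Reduce(`+`, lapply(stp, as.matrix)) / length(stp))
  out
}

#' Updraft factor from aspect and prevailing wind direction
#'
#' Both aspect and prevailing wind are classified into the 8 compass
#' categories; equal categories score 1 (wind meets the slope head-on),
#' circularly adjacent categories (45 degrees apart) score 0.75, anything
#' else 0. Flat cells score 0.
#'
#' @param aspect a `grid` of downslope azimuths in degrees (flat cells -1),
#'   as produced by [aspect_from_elevation()]
#' @param wind_category a `grid` of prevailing-wind compass categories 1..8
#' @return a factor `grid` with values in {0, 0.75, 1}
#' @export
updraft_factor <- function(aspect, wind_category) {
  check_geometry(aspect, wind_category)
  w <- wind_category$values
  ok <- is.na(w) | (w %in% 1:8)
  if (!all(ok)) stop("wind categories must lie in 1..8")
  a <- compass_category(aspect$values)
  dd <- abs(a - w)
  dd <- pmin(dd, 8 - dd)
  out <- ifelse(is.na(a) | is.na(w), 0,
                ifelse(dd == 0, 1, ifelse(dd == 1, 0.75, 0)))
  out[is.na(aspect$values) | is.na(w)] <- NA
  out[!is.na(aspect$values) & aspect$values < 0 & !is.na(w)] <- 0  # flat
  grid_like(aspect, out)
}

#' Multiply a factor by its modifiers
#'
#' Cellwise product of a factor layer (values in [0, 1]) with one or more
#' modifier layers (values in [0, 2]): a 0 modifier removes the factor, 1
#' leaves it unchanged, 2 doubles it.
#'
#' @param factor_layer a `grid` in [0, 1]
#' @param modifiers list of modifier `grid`s in [0, 2] (may be empty)
#' @return a `grid`
#' @export
apply_modifiers <- function(factor_layer, modifiers = list()) {
  stopifnot(is_grid(factor_layer))
  out <- factor_layer
  for (m in modifiers) {
    check_geometry(factor_layer, m)
    if (any(m$values < 0 | m$values > 2, na.rm = TRUE))
      stop("modifier values must lie in [0, 2]")
    out <- grid_like(out, out$values * m$values)
  }
  out
}

#' Weighted combination of modified, normalized factor terms
#'
#' The migratory importance score: each term (already modified and normalized
#' to [0, 1]) is multiplied by its positive weight, the weighted terms are
#' summed, and the sum is normalized to [0, 1]. Multiplying all weights by a
#' common positive constant therefore leaves the result unchanged.
#'
#' @param terms list of `grid`s in [0, 1]
#' @param weights positive weights, one per term
#' @return a `grid` in [0, 1]
#' @export
combine_mis <- function(terms, weights = rep(1, length(terms))) {
  if (!length(terms)) stop("at least one term is required")
  if (length(weights) != length(terms)) stop("one weight per term required")
  if (any(weights <= 0)) stop("weights must be positive")
  acc <- grid_like(terms[[1]], terms[[1]]$values * weights[1])
  for (i in seq_along(terms)[-1]) {
    check_geometry(acc, terms[[i]])
    acc <- grid_like(acc, acc$values + weights[i] * terms[[i]]$values)
  }
  normalize01(acc)
}
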
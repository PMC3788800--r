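# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_stack <- function(size = 60, seed = 11) {
  key <- sprintf("stack_%d_%d", size, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_landscape(
      landscape_params(extent_cells = c(size, size)), seed = seed)
  .fixtures[[key]]
}

# grid with values 1..(nr*nc) laid out column-major, all distinct
seq_grid <- function(nr = 10, nc = 10, cell_size = 90) {
  grid(matrix(seq_len(nr * nc), nr, nc), cell_size = cell_size,
       origin = c(0, nr * cell_size))
}

# uniform random grid with a fixed seed
runif_grid <- function(nr, nc, seed, cell_size = 90) {
  set.seed(seed)
  grid(matrix(runif(nr * nc), nr, nc), cell_size = cell_size,
       origin = c(0, nr * cell_size))
}

# brute-force all-pairs nearest-source computation used as the oracle for
# the distance-based operators: for every cell, the distance to the nearest
# positive-valued source cell and the value of that source (ties between
# equally near sources resolved toward the larger value).
brute_nearest_source <- function(g) {
  v <- g$values; cs <- g$cell_size
  nr <- nrow(v); nc <- ncol(v)
  src <- which(!is.na(v) & v > 0, arr.ind = TRUE)
  dist <- matrix(Inf, nr, nc); val <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!nrow(src)) break
    d <- sqrt((src[, 1] - r)^2 + (src[, 2] - c)^2) * cs
    dmin <- min(d)
    vbest <- max(v[src[d <= dmin + 1e-9, , drop = FALSE]])
    dist[r, c] <- dmin; val[r, c] <- vbest
  }
  list(dist = dist, val = val)
}

# A fully hand-built 6x6 landscape (200-m cells, extent 1.2 x 1.2 km) whose
# every factor and modifier can be recomputed with pencil-and-paper
# arithmetic. Model options shrink the window/buffer distances so each
# operation is exercised at this extent.
toy_stack <- function() {
  cs <- 200; nr <- 6; nc <- 6
  tpl <- grid(matrix(0, nr, nc), cell_size = cs, origin = c(0, nr * cs))
  elev <- matrix(rep(c(2000, 2000, 2500, 2500, 2800, 2800), times = nc), nr, nc)
  codes <- landcover_codes()
  lc <- matrix(codes[["medtall_grass"]], nr, nc)
  lc[, 1] <- codes[["shortmix_prairie"]]; lc[, 3] <- codes[["arid_shrub"]]
  lc[, 4] <- codes[["forest_riparian"]]; lc[, 6] <- codes[["grass_riparian"]]
  crops <- matrix(0, nr, nc); crops[1, 6] <- 1; crops[2, 6] <- 2
  flyway <- matrix(0, nr, nc); flyway[, 4:6] <- 1
  cotton <- matrix(0.2, nr, nc); cotton[, 2] <- 1
  grids <- list(
    elevation = grid_like(tpl, elev),
    aspect = aspect_from_elevation(grid_like(tpl, elev)),
    land_cover = grid_like(tpl, lc),
    bare_ground = grid_like(tpl, matrix(0.5, nr, nc)),
    cottonwood = grid_like(tpl, cotton),
    willow = grid_like(tpl, matrix(0.25, nr, nc)),
    prairie_dog = grid_like(tpl, matrix(0.3, nr, nc)),
    wind_direction_category = grid_like(tpl, matrix(1, nr, nc)),
    crops = grid_like(tpl, crops),
    flyway_mask = grid_like(tpl, flyway))
  streams <- list(
    list(xy = rbind(c(300, 1150), c(300, 50)),   # large river down column 2
         order = 7L, perennial = TRUE, large_river = TRUE),
    list(xy = rbind(c(50, 300), c(1150, 300)),   # order-3 stream along row 5
         order = 3L, perennial = TRUE, large_river = FALSE),
    list(xy = rbind(c(900, 1150), c(900, 700)),  # intermittent order-2, col 5
         order = 2L, perennial = FALSE, large_river = FALSE))
  mk_wet <- function(ctr, area) {
    half <- 30
    list(xy = cbind(ctr[1] + c(-half, half, half, -half),
                    ctr[2] + c(-half, -half, half, half)),
         centroid = ctr, area_ha = area, kind = "palustrine")
  }
  wetlands <- list(mk_wet(c(700, 900), 20),   # cell (2,4): >15 ha
                   mk_wet(c(900, 700), 8),    # cell (3,5): 5-15 ha
                   mk_wet(c(900, 900), 3))    # cell (2,5): <5 ha
  list(stack = layer_stack(grids, streams, wetlands),
       opts = model_options(density_radius_m = 500,
                            proximity_breaks_m = c(400, 800),
                            buffer_dist_m = 300))
}

# a tiny hand-positioned occurrence table
occ_df <- function(x, y, quality = seq_along(x), species = "sp01",
                   accuracy = 50) {
  data.frame(species = rep_len(species, length(x)), x = x, y = y,
             date = as.Date("2012-04-15"), accuracy_m = rep_len(accuracy, length(x)),
             quality_rank = quality, stringsAsFactors = FALSE)
}
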
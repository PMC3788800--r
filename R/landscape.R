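# Synthetic landscape generator. Emulates the structure of the GIS inputs the
# four group models consume — a mountain/basin elevation surface with ridges,
# a branching stream network, clustered wetlands, categorical land cover,
# 0-1 probability surfaces, a prevailing-wind grid and a flyway mask — plus
# biased occurrence points and a wind-development-potential surface, so the
# whole pipeline runs and is testable without any external data.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- (-r):r
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  k / sum(k)
}

# spatially correlated standard-normal field (edge-corrected Gaussian blur of
# white noise)
smooth_field <- function(nr, nc, range_cells = 10) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  k <- gauss_kernel(range_cells)
  f <- conv2_centered(z, k) / conv2_centered(matrix(1, nr, nc), k)
  (f - mean(f)) / stats::sd(f)
}

# clamp to [0, 1] preserving matrix shape (pmin/pmax would drop dims)
clamp01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }

unit01 <- function(m) {
  rg <- range(m, na.rm = TRUE)
  if (rg[2] == rg[1]) return(m * 0)
  (m - rg[1]) / (rg[2] - rg[1])
}

#' Land cover class codes
#'
#' Integer codes used in the `land_cover` grid. Classes 1-3 are the grassland
#' / shrubland types valued by the sparse-grassland model; 4-7 are the
#' riparian structural-diversity classes; 8-9 carry no model value.
#' @return named integer vector
#' @export
landcover_codes <- function() {
  c(shortmix_prairie = 1L, medtall_grass = 2L, arid_shrub = 3L,
    forest_riparian = 4L, riparian_woodland_shrubland = 5L,
    shrub_riparian = 6L, grass_riparian = 7L,
    conifer_forest = 8L, barren_other = 9L)
}

#' Crop class codes
#' @return named integer vector (0 = no crop)
#' @export
crop_codes <- function() c(none = 0L, grain = 1L, hay_pasture = 2L)

#' Parameters of a synthetic landscape
#'
#' @param extent_cells integer pair (rows, cols)
#' @param cell_size cell size in meters (default 90)
#' @param n_ridges number of Gaussian ridges in the elevation surface
#' @param ridge_orientation_mix fraction of north-south oriented ridges (and
#'   stream trunks) in [0, 1]
#' @param n_stream_trunks number of stream trunk polylines
#' @param wetland_cluster_count number of wetland clusters
#' @param wetlands_per_cluster wetlands per cluster
#' @param wetland_area_range (min, max) wetland area in hectares; areas are
#'   drawn log-uniformly, spanning the <5 / 5-15 / >15 ha model classes
#' @param elevation_range (min, max) elevation in meters
#' @param flyway_split_col first column inside the eastern (Central) flyway;
#'   default 60 percent of the width
#' @param crop_fraction fraction of the extent under crops in [0, 1]
#' @return object of class `landscape_params`
#' @export
landscape_params <- function(extent_cells = c(100, 100), cell_size = 90,
                             n_ridges = 6, ridge_orientation_mix = 0.7,
                             n_stream_trunks = 4,
                             wetland_cluster_count = 5, wetlands_per_cluster = 200,
                             wetland_area_range = c(0.5, 40),
                             elevation_range = c(1200, 3100),
                             flyway_split_col = NULL,
                             crop_fraction = 0.1) {
  extent_cells <- as.integer(extent_cells)
  if (length(extent_cells) != 2L || any(is.na(extent_cells)) || any(extent_cells <= 0))
    stop("extent_cells must be a positive (rows, cols) pair")
  if (cell_size <= 0) stop("cell_size must be positive")
  if (ridge_orientation_mix < 0 || ridge_orientation_mix > 1 ||
      crop_fraction < 0 || crop_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (wetland_area_range[1] >= wetland_area_range[2])
    stop("wetland_area_range must be (min, max) with min < max")
  if (elevation_range[1] >= elevation_range[2])
    stop("elevation_range must be (min, max) with min < max")
  if (is.null(flyway_split_col)) flyway_split_col <- ceiling(0.6 * extent_cells[2])
  structure(list(extent_cells = extent_cells, cell_size = cell_size,
                 n_ridges = n_ridges, ridge_orientation_mix = ridge_orientation_mix,
                 n_stream_trunks = n_stream_trunks,
                 wetland_cluster_count = wetland_cluster_count,
                 wetlands_per_cluster = wetlands_per_cluster,
                 wetland_area_range = wetland_area_range,
                 elevation_range = elevation_range,
                 flyway_split_col = as.integer(flyway_split_col),
                 crop_fraction = crop_fraction),
            class = "landscape_params")
}

#' Assemble and validate a layer stack
#'
#' @param grids named list of `grid`s (elevation, aspect, land_cover,
#'   bare_ground, cottonwood, willow, prairie_dog, wind_direction_category,
#'   crops, flyway_mask)
#' @param streams list of stream features (`xy`, `order` 0-7, `perennial`,
#'   `large_river`)
#' @param wetlands list of wetland features (`xy` polygon, `centroid`,
#'   `area_ha`, `kind`)
#' @param params optional `landscape_params` provenance
#' @return object of class `layer_stack`
#' @export
layer_stack <- function(grids, streams = list(), wetlands = list(), params = NULL) {
  st <- structure(list(grids = grids, streams = streams, wetlands = wetlands,
                       params = params), class = "layer_stack")
  validate_stack(st)
  st
}

#' Check the structural invariants of a layer stack
#'
#' All grids share geometry; probability surfaces lie in [0, 1]; wind
#' categories are in 1..8; stream orders in 0..7; wetland areas positive.
#'
#' @param stack a `layer_stack`
#' @return TRUE invisibly (stops on violation)
#' @export
validate_stack <- function(stack) {
  gs <- stack$grids
  if (!length(gs)) stop("stack has no grids")
  ref <- gs[[1]]
  for (nm in names(gs))
    if (!same_geometry(ref, gs[[nm]]))
      stop("grid '", nm, "' does not share the stack geometry")
  for (nm in intersect(c("bare_ground", "cottonwood", "willow", "prairie_dog"), names(gs))) {
    v <- gs[[nm]]$values
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("probability grid '", nm, "' outside [0, 1]")
  }
  if ("wind_direction_category" %in% names(gs)) {
    w <- gs$wind_direction_category$values
    if (!all(is.na(w) | w %in% 1:8)) stop("wind categories must be 1..8")
  }
  for (s in stack$streams)
    if (is.na(s$order) || s$order < 0 || s$order > 7)
      stop("stream order must lie in 0..7")
  for (w in stack$wetlands)
    if (!is.finite(w$area_ha) || w$area_ha <= 0)
      stop("wetland areas must be positive")
  invisible(TRUE)
}

#' @export
print.layer_stack <- function(x, ...) {
  d <- dim(x$grids[[1]])
  cat(sprintf("<layer_stack> %d x %d cells @ %.6g m\n", d[1], d[2],
              x$grids[[1]]$cell_size))
  cat("  grids:   ", paste(names(x$grids), collapse = ", "), "\n")
  cat(sprintf("  streams: %d features; wetlands: %d features\n",
              length(x$streams), length(x$wetlands)))
  invisible(x)
}

#' Generate a synthetic landscape
#'
#' Builds a complete input landscape with the structure the four group models
#' assume: an elevation surface that is a sloped plane plus anisotropic
#' Gaussian ridges (orientation mixture controlled by
#' `ridge_orientation_mix`), aspect derived from elevation, a branching
#' stream network whose trunks follow valley lines, clustered wetlands with a
#' log-uniform size distribution, spatially correlated categorical land cover
#' covering every class the models value, 0-1 probability surfaces
#' (cottonwood, willow, bare ground, prairie dog), a spatially coherent
#' 8-category prevailing-wind grid, crop patches and a flyway mask.
#'
#' @param params a `landscape_params` object
#' @param seed integer seed; identical (params, seed) give identical stacks
#' @return a `layer_stack`
#' @export
generate_landscape <- function(params = landscape_params(), seed = 1) {
  stopifnot(inherits(params, "landscape_params"))
  with_seed(seed, build_landscape(params))
}

build_landscape <- function(p) {
  nr <- p$extent_cells[1]; nc <- p$extent_cells[2]; cs <- p$cell_size
  template <- grid(matrix(0, nr, nc), cell_size = cs, origin = c(0, nr * cs))

  elev <- gen_elevation(p, template)
  streams <- gen_streams(p, elev)
  wetlands <- gen_wetlands(p, template)

  elev_n <- unit01(elev$values)
  east <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)

  # distance to low-order-and-up streams, for riparian bands and indices
  sgrid <- rasterize_valued_features(
    lapply(streams, function(s) if (s$order >= 2) list(xy = s$xy, value = 1) else NULL)[
      vapply(streams, function(s) s$order >= 2, TRUE)],
    template)
  dstream <- grid_distance_to(template, sgrid$values > 0)$values

  lc <- gen_landcover(p, elev_n, east, dstream, nr, nc)
  codes <- landcover_codes()

  bare <- clamp01(0.45 * unit01(smooth_field(nr, nc, 8)) +
                  0.45 * (lc %in% c(codes["arid_shrub"], codes["barren_other"])) +
                  0.10 * east)
  riparian_boost <- exp(-dstream / 300) * (1 - elev_n)
  cotton <- clamp01(0.25 * unit01(smooth_field(nr, nc, 10)) + 0.75 * riparian_boost)
  willow <- clamp01(0.35 * unit01(smooth_field(nr, nc, 10)) + 0.65 * riparian_boost)
  prairie <- lc %in% c(codes["shortmix_prairie"], codes["medtall_grass"])
  pdog <- clamp01(0.55 * unit01(smooth_field(nr, nc, 12)) * prairie + 0.1 * east)

  wind_az <- (270 + 60 * smooth_field(nr, nc, 15)) %% 360
  windcat <- matrix(compass_category(wind_az), nr, nc)

  crops <- gen_crops(p, elev_n, nr, nc)
  flyway <- matrix(0, nr, nc)
  flyway[, seq_len(nc) >= p$flyway_split_col] <- 1

  grids <- list(
    elevation = elev,
    aspect = aspect_from_elevation(elev),
    land_cover = grid_like(template, lc),
    bare_ground = grid_like(template, bare),
    cottonwood = grid_like(template, cotton),
    willow = grid_like(template, willow),
    prairie_dog = grid_like(template, pdog),
    wind_direction_category = grid_like(template, windcat),
    crops = grid_like(template, crops),
    flyway_mask = grid_like(template, flyway))
  layer_stack(grids, streams, wetlands, p)
}

gen_elevation <- function(p, template) {
  nr <- p$extent_cells[1]; nc <- p$extent_cells[2]
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  # gentle regional slope in a random direction
  th0 <- stats::runif(1, 0, 2 * pi)
  base <- 300 * ((col * cos(th0) + row * sin(th0)) / max(nr, nc))
  z <- base + 40 * smooth_field(nr, nc, 6)
  for (i in seq_len(p$n_ridges)) {
    ns <- stats::runif(1) < p$ridge_orientation_mix
    az <- if (ns) stats::rnorm(1, 0, 12) else stats::rnorm(1, 90, 12)
    thr <- az * pi / 180
    r0 <- stats::runif(1, 0.1 * nr, 0.9 * nr)
    c0 <- stats::runif(1, 0.1 * nc, 0.9 * nc)
    sa <- stats::runif(1, 2, 5)                      # across-crest sd (cells)
    sl <- stats::runif(1, 0.15, 0.35) * min(nr, nc)  # along-crest sd
    h <- stats::runif(1, 250, 700)
    dx <- col - c0; dy <- r0 - row                   # east / north offsets
    along <- dx * sin(thr) + dy * cos(thr)
    across <- dx * cos(thr) - dy * sin(thr)
    z <- z + h * exp(-(across^2) / (2 * sa^2)) * exp(-(along^2) / (2 * sl^2))
  }
  zr <- p$elevation_range
  grid_like(template, zr[1] + unit01(z) * (zr[2] - zr[1]))
}

gen_streams <- function(p, elev) {
  nr <- nrow(elev$values); nc <- ncol(elev$values); cs <- elev$cell_size
  x_of <- function(c) (c - 0.5) * cs
  y_of <- function(r) (nr - r + 0.5) * cs
  feats <- list()
  if (p$n_stream_trunks < 1) return(feats)
  orders <- c(7L, if (p$n_stream_trunks > 1)
    sample(3:6, p$n_stream_trunks - 1L, replace = TRUE))
  for (t in seq_len(p$n_stream_trunks)) {
    ns <- stats::runif(1) < max(p$ridge_orientation_mix, 0.5)
    if (ns) {
      cpos <- sample(seq(0.15 * nc, 0.85 * nc), 1)
      verts <- matrix(NA_real_, nr, 2)
      for (r in seq_len(nr)) {
        cand <- unique(pmin(pmax(round(cpos) + (-1:1), 1), nc))
        sc <- elev$values[r, cand] + stats::rnorm(length(cand), 0, 15)
        cpos <- cand[which.min(sc)]
        verts[r, ] <- c(x_of(cpos), y_of(r))
      }
    } else {
      rpos <- sample(seq(0.15 * nr, 0.85 * nr), 1)
      verts <- matrix(NA_real_, nc, 2)
      for (cl in seq_len(nc)) {
        cand <- unique(pmin(pmax(round(rpos) + (-1:1), 1), nr))
        sc <- elev$values[cand, cl] + stats::rnorm(length(cand), 0, 15)
        rpos <- cand[which.min(sc)]
        verts[cl, ] <- c(x_of(cl), y_of(rpos))
      }
    }
    feats[[length(feats) + 1L]] <- list(
      xy = verts, order = orders[t], perennial = TRUE,
      large_river = orders[t] >= 7L)
    # tributaries off this trunk
    ntrib <- 1L + stats::rpois(1, 2)
    for (k in seq_len(ntrib)) {
      vi <- sample(seq_len(nrow(verts)), 1)
      base_dir <- if (ns) c(0, 1) else c(1, 0)
      side <- sample(c(-1, 1), 1)
      ang <- stats::runif(1, 30, 70) * pi / 180 * side
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
      dirv <- as.numeric(rot %*% base_dir)
      len <- stats::runif(1, 8, 25) * cs
      mid <- verts[vi, ] + dirv * len / 2 + stats::rnorm(2, 0, 1.5 * cs)
      end <- verts[vi, ] + dirv * len
      ord <- sample(0:4, 1)
      feats[[length(feats) + 1L]] <- list(
        xy = rbind(verts[vi, ], mid, end), order = ord,
        perennial = ord >= 4L || (ord >= 2L && stats::runif(1) < 0.5),
        large_river = FALSE)
    }
  }
  feats
}

gen_wetlands <- function(p, template) {
  if (p$wetland_cluster_count < 1 || p$wetlands_per_cluster < 1) return(list())
  nr <- p$extent_cells[1]; nc <- p$extent_cells[2]; cs <- p$cell_size
  W <- nc * cs; H <- nr * cs
  feats <- list()
  centers <- cbind(stats::runif(p$wetland_cluster_count, 0.1 * W, 0.9 * W),
                   stats::runif(p$wetland_cluster_count, 0.1 * H, 0.9 * H))
  la <- log(p$wetland_area_range)
  for (i in seq_len(p$wetland_cluster_count)) {
    for (j in seq_len(p$wetlands_per_cluster)) {
      ctr <- centers[i, ] + stats::rnorm(2, 0, 700)
      ctr <- pmin(pmax(ctr, 0.02 * c(W, H)), 0.98 * c(W, H))
      area <- exp(stats::runif(1, la[1], la[2]))
      half <- sqrt(area * 1e4) / 2
      poly <- cbind(ctr[1] + c(-half, half, half, -half),
                    ctr[2] + c(-half, -half, half, half))
      feats[[length(feats) + 1L]] <- list(
        xy = poly, centroid = ctr, area_ha = area,
        kind = sample(c("lacustrine", "palustrine"), 1, prob = c(0.2, 0.8)))
    }
  }
  feats
}

gen_landcover <- function(p, elev_n, east, dstream, nr, nc) {
  codes <- landcover_codes()
  u1 <- smooth_field(nr, nc, 9)
  u2 <- smooth_field(nr, nc, 6)
  lc <- matrix(codes[["barren_other"]], nr, nc)
  score <- u1 + 1.3 * east - 1.2 * elev_n     # prairie pull: low, eastern
  qs <- stats::quantile(score, c(0.35, 0.6, 0.85))
  lc[score <= qs[1]] <- codes[["arid_shrub"]]
  lc[score > qs[1] & score <= qs[2]] <- codes[["barren_other"]]
  lc[score > qs[2] & score <= qs[3]] <- codes[["medtall_grass"]]
  lc[score > qs[3]] <- codes[["shortmix_prairie"]]
  lc[elev_n > stats::quantile(elev_n, 0.8)] <- codes[["conifer_forest"]]
  rip <- dstream <= 200                       # riparian band along streams
  lc[rip & u2 > 1] <- codes[["forest_riparian"]]
  lc[rip & u2 <= 1 & u2 > 0.2] <- codes[["riparian_woodland_shrubland"]]
  lc[rip & u2 <= 0.2 & u2 > -0.8] <- codes[["shrub_riparian"]]
  lc[rip & u2 <= -0.8] <- codes[["grass_riparian"]]
  lc
}

gen_crops <- function(p, elev_n, nr, nc) {
  crops <- matrix(0, nr, nc)
  if (p$crop_fraction <= 0) return(crops)
  u <- smooth_field(nr, nc, 7)
  suit <- u - 1.5 * elev_n
  thr <- stats::quantile(suit, 1 - p$crop_fraction)
  sel <- suit > thr
  kind <- smooth_field(nr, nc, 7)
  crops[sel & kind > 0] <- crop_codes()[["grain"]]
  crops[sel & kind <= 0] <- crop_codes()[["hay_pasture"]]
  crops
}

#' Sample occurrence points biased toward high model scores
#'
#' Cells are sampled with probability proportional to `mis^bias` (bias 0 is
#' uniform over unmasked cells); each point falls uniformly inside its cell.
#' Points are assigned round-robin to `n_species` synthetic species, each
#' with its own spring migration window, and get randomized positional
#' accuracy and quality-rank fields so the validation filters are
#' exercisable.
#'
#' @param mis a `grid` with values in [0, 1] (a migratory importance score)
#' @param n number of points (>= 1)
#' @param bias non-negative sampling exponent (default 2)
#' @param n_species number of species labels (default 10)
#' @param seed integer seed
#' @param windows optional data.frame (species, start_mmdd, end_mmdd) of
#'   migration windows; synthesized when NULL
#' @param year calendar year for the dates (default 2012)
#' @return data.frame with columns species, x, y, date, accuracy_m,
#'   quality_rank (quality_rank 1 = best); migration windows attached as
#'   attribute `windows`
#' @export
generate_occurrences <- function(mis, n, bias = 2, n_species = 10, seed = 1,
                                 windows = NULL, year = 2012) {
  stopifnot(is_grid(mis), n >= 1, bias >= 0)
  v <- mis$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("mis values must lie in [0, 1]")
  with_seed(seed, {
    ok <- which(!is.na(v))
    w <- v[ok]^bias
    if (sum(w) == 0)
      stop("degenerate sampling distribution: all-zero scores with positive bias")
    idx <- ok[sample.int(length(ok), n, replace = TRUE, prob = w)]
    nr <- nrow(v)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    cs <- mis$cell_size
    x <- mis$origin[1] + (cols - 1L) * cs + stats::runif(n, 0, cs)
    y <- mis$origin[2] - (rows - 1L) * cs - stats::runif(n, 0, cs)
    spp <- sprintf("sp%02d", seq_len(n_species))
    if (is.null(windows)) {
      start <- as.Date(sprintf("%d-03-01", year)) +
        sample.int(60, n_species, replace = TRUE) - 1L
      len <- sample(30:60, n_species, replace = TRUE)
      windows <- data.frame(species = spp,
                            start_mmdd = format(start, "%m-%d"),
                            end_mmdd = format(start + len, "%m-%d"),
                            stringsAsFactors = FALSE)
    }
    species <- rep_len(spp, n)
    wi <- match(species, windows$species)
    d0 <- as.Date(paste(year, windows$start_mmdd[wi], sep = "-"))
    d1 <- as.Date(paste(year, windows$end_mmdd[wi], sep = "-"))
    date <- d0 + floor(stats::runif(n) * (as.numeric(d1 - d0) + 1))
    out <- data.frame(species = species, x = x, y = y, date = date,
                      accuracy_m = round(stats::rlnorm(n, log(100), 1)),
                      quality_rank = sample.int(5L, n, replace = TRUE),
                      stringsAsFactors = FALSE)
    attr(out, "windows") <- windows
    out
  })
}

#' Synthetic wind-development-potential surface
#'
#' A [0, 1] surface positively associated with ridge-like topographic
#' position (weight `ridge_weight`) plus an eastward gradient and smooth
#' noise, emulating the spatial pattern of a wind-resource model: high along
#' ridges and in the eastern part of the extent.
#'
#' @param stack a `layer_stack`
#' @param ridge_weight weight of the topographic-position signal in [0, 1]
#' @param seed integer seed
#' @param windows TPI window diameters in cells (default `c(20, 50)`)
#' @return a `grid` in [0, 1]
#' @export
generate_wind_potential <- function(stack, ridge_weight = 0.6, seed = 1,
                                    windows = c(20, 50)) {
  stopifnot(inherits(stack, "layer_stack"),
            ridge_weight >= 0, ridge_weight <= 1)
  elev <- stack$grids$elevation
  tp <- topographic_position(elev, windows = windows)
  stpi <- attr(tp, "stpi")$values
  rk <- matrix(rank(stpi, ties.method = "average") / length(stpi),
               nrow(stpi), ncol(stpi))
  nr <- nrow(stpi); nc <- ncol(stpi)
  east <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  with_seed(seed, {
    z <- unit01(smooth_field(nr, nc, 10))
    raw <- ridge_weight * rk + 0.3 * east + 0.2 * z
    grid_like(elev, unit01(raw))
  })
}
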
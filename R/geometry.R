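# Geometric sub-procedures: line/polygon rasterization, minimum-area
# rectangle orientation, aspect, compass categories, component labeling.

# Cells traversed by one segment, via Amanatides-Woo voxel walking on the
# grid. Returns an integer matrix with columns (row, col); empty if the
# segment misses the grid entirely.
cells_on_segment <- function(g, x0, y0, x1, y1) {
  d <- dim(g); cs <- g$cell_size
  # continuous grid coordinates: u along columns (east), v along rows (south)
  u0 <- (x0 - g$origin[1]) / cs; v0 <- (g$origin[2] - y0) / cs
  u1 <- (x1 - g$origin[1]) / cs; v1 <- (g$origin[2] - y1) / cs
  # clip to [0, nc] x [0, nr] (Liang-Barsky)
  du <- u1 - u0; dv <- v1 - v0
  t0 <- 0; t1 <- 1
  for (cl in list(c(-du, u0 - 0), c(du, d[2] - u0), c(-dv, v0 - 0), c(dv, d[1] - v0))) {
    p <- cl[1]; q <- cl[2]
    if (abs(p) < 1e-12) { if (q < 0) return(matrix(integer(0), 0, 2)) }
    else { t <- q / p
      if (p < 0) { if (t > t1) return(matrix(integer(0), 0, 2)); if (t > t0) t0 <- t }
      else { if (t < t0) return(matrix(integer(0), 0, 2)); if (t < t1) t1 <- t } }
  }
  eps <- 1e-9
  us <- u0 + t0 * du; vs <- v0 + t0 * dv
  ue <- u0 + t1 * du; ve <- v0 + t1 * dv
  ci <- min(max(floor(us + eps * sign(du)), 0), d[2] - 1)
  ri <- min(max(floor(vs + eps * sign(dv)), 0), d[1] - 1)
  ce <- min(max(floor(ue - eps * sign(du)), 0), d[2] - 1)
  re <- min(max(floor(ve - eps * sign(dv)), 0), d[1] - 1)
  stepc <- sign(ue - us); stepr <- sign(ve - vs)
  tdc <- if (stepc != 0) abs(1 / (ue - us)) else Inf
  tdr <- if (stepr != 0) abs(1 / (ve - vs)) else Inf
  tmc <- if (stepc > 0) (ci + 1 - us) * tdc else if (stepc < 0) (us - ci) * tdc else Inf
  tmr <- if (stepr > 0) (ri + 1 - vs) * tdr else if (stepr < 0) (vs - ri) * tdr else Inf
  rows <- integer(0); cols <- integer(0)
  r <- ri; c <- ci
  nmax <- (abs(ce - ci) + abs(re - ri) + 2L) * 2L
  for (it in seq_len(nmax)) {
    rows <- c(rows, r); cols <- c(cols, c)
    if (r == re && c == ce) break
    if (tmc < tmr) { c <- c + stepc; tmc <- tmc + tdc }
    else { r <- r + stepr; tmr <- tmr + tdr }
    if (c < 0 || c >= d[2] || r < 0 || r >= d[1]) break
  }
  cbind(row = as.integer(rows) + 1L, col = as.integer(cols) + 1L)
}

cells_on_polyline <- function(g, xy) {
  n <- nrow(xy)
  if (n == 1L) {
    rc <- cell_at(g, xy[1, 1], xy[1, 2])
    return(rc[!is.na(rc[, 1]), , drop = FALSE])
  }
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L))
    out[[i]] <- cells_on_segment(g, xy[i, 1], xy[i, 2], xy[i + 1, 1], xy[i + 1, 2])
  rc <- do.call(rbind, out)
  unique(rc)
}

# Cells covered by a polygon: centers inside (even-odd rule) plus boundary
# cells, so very small polygons still occupy their centroid cell.
cells_in_polygon <- function(g, xy) {
  d <- dim(g); cs <- g$cell_size
  cc <- cell_centers(g)
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  cols <- which(cc$x >= xr[1] - cs & cc$x <= xr[2] + cs)
  rows <- which(cc$y >= yr[1] - cs & cc$y <= yr[2] + cs)
  inside_rc <- NULL
  if (length(cols) && length(rows)) {
    px <- rep(cc$x[cols], each = length(rows))
    py <- rep(cc$y[rows], times = length(cols))
    ins <- point_in_polygon(px, py, xy)
    inside_rc <- cbind(row = rep(rows, times = length(cols))[ins],
                       col = rep(cols, each = length(rows))[ins])
  }
  ring <- rbind(xy, xy[1, , drop = FALSE])
  rc <- rbind(inside_rc, cells_on_polyline(g, ring))
  unique(rc)
}

point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    denom <- yj - yi
    if (abs(denom) > 0) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / denom + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Rasterize valued features onto a grid template
#'
#' Each feature is a polyline (or single point) carrying a scalar value; the
#' cells it traverses take that value, and overlapping features combine by
#' maximum. Cells touched by no feature are 0. An empty feature set yields an
#' all-zero grid.
#'
#' @param features list of features, each a list with `xy` (n x 2 coordinate
#'   matrix) and `value` (scalar); polygons may set `polygon = TRUE` to fill
#'   their interior.
#' @param template a `grid` defining the geometry (its NoData mask is kept)
#' @return a `grid` of feature values
#' @export
rasterize_valued_features <- function(features, template) {
  stopifnot(is_grid(template))
  out <- matrix(0, nrow(template$values), ncol(template$values))
  for (f in features) {
    if (is.null(f$value)) stop("every feature needs a value attribute")
    if (f$value == 0) next
    rc <- if (isTRUE(f$polygon)) cells_in_polygon(template, f$xy)
          else cells_on_polyline(template, f$xy)
    if (nrow(rc)) out[rc] <- pmax(out[rc], f$value)
  }
  out[is.na(template$values)] <- NA
  grid_like(template, out)
}

#' Orientation (northness) of a feature via its minimum-area rectangle
#'
#' Computes the minimum-area bounding rectangle of the vertices (rotating
#' calipers over the convex hull), takes the azimuth theta of the rectangle's
#' long axis (in [0, 180) degrees, 0 = north), and returns the northness
#' index `2 - delta/90` where `delta = min(theta, 180 - theta)` is the
#' deviation from north. A due north-south feature scores 2, due east-west
#' scores 1.
#'
#' @param xy n x 2 matrix of vertex coordinates (projected meters)
#' @return scalar in [1, 2]
#' @export
min_rect_northness <- function(xy) {
  xy <- as.matrix(xy)
  xy <- xy[!duplicated(xy), , drop = FALSE]
  if (nrow(xy) < 2L) stop("geometry needs at least 2 distinct vertices")
  dir <- min_rect_long_axis(xy)
  az <- (atan2(dir[1], dir[2]) * 180 / pi) %% 180
  delta <- min(az, 180 - az)
  2 - delta / 90
}

# unit direction (dx, dy) of the long axis of the minimum-area rectangle
min_rect_long_axis <- function(xy) {
  h <- grDevices::chull(xy)
  pts <- xy[h, , drop = FALSE]
  if (nrow(pts) < 3L || hull_area(pts) < 1e-9) {
    # collinear: direction of the farthest pair
    dmat <- as.matrix(stats::dist(xy))
    ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
    v <- xy[ij[2], ] - xy[ij[1], ]
    return(v / sqrt(sum(v^2)))
  }
  n <- nrow(pts)
  best <- Inf; best_dir <- c(0, 1)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- pts %*% u; pv <- pts %*% v
    wu <- max(pu) - min(pu); wv <- max(pv) - min(pv)
    area <- wu * wv
    if (area < best - 1e-12) {
      best <- area
      best_dir <- if (wu >= wv) u else v
    }
  }
  best_dir
}

hull_area <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  abs(sum(pts[, 1] * pts[j, 2] - pts[j, 1] * pts[, 2])) / 2
}

#' Aspect (downslope azimuth) from elevation
#'
#' Central-difference gradient (one-sided at edges); aspect is the compass
#' azimuth of the steepest *descent* direction in degrees (0 = north,
#' clockwise). Flat cells (zero gradient) are coded -1; NoData stays `NA`.
#'
#' @param elev elevation `grid` (meters)
#' @return a `grid` of azimuths in [0, 360) with flat cells -1
#' @export
aspect_from_elevation <- function(elev) {
  stopifnot(is_grid(elev))
  z <- elev$values; cs <- elev$cell_size
  nr <- nrow(z); nc <- ncol(z)
  gx <- matrix(NA_real_, nr, nc); gy <- matrix(NA_real_, nr, nc)
  # east-west gradient (x increases with column)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * cs)
  gx[, 1] <- (z[, min(2, nc)] - z[, 1]) / cs
  gx[, nc] <- (z[, nc] - z[, max(nc - 1, 1)]) / cs
  # north-south gradient (y increases toward row 1)
  if (nr >= 3) gy[2:(nr - 1), ] <- (z[1:(nr - 2), ] - z[3:nr, ]) / (2 * cs)
  gy[1, ] <- (z[1, ] - z[min(2, nr), ]) / cs
  gy[nr, ] <- (z[max(nr - 1, 1), ] - z[nr, ]) / cs
  az <- (atan2(-gx, -gy) * 180 / pi) %% 360
  flat <- abs(gx) < 1e-9 & abs(gy) < 1e-9
  az[flat] <- -1
  az[is.na(z)] <- NA
  grid_like(elev, az)
}

#' Eight-way compass category of an azimuth
#'
#' Categories 1..8 = N, NE, E, SE, S, SW, W, NW, each a 45-degree sector
#' centered on the cardinal/intercardinal direction. Negative input (flat
#' flag) and `NA` return `NA`.
#'
#' @param az azimuth in degrees
#' @return integer category 1..8
#' @export
compass_category <- function(az) {
  out <- (floor((az + 22.5) / 45) %% 8) + 1
  out[!is.finite(az) | az < 0] <- NA
  as.integer(out)
}

# Connected-component labeling (8-connectivity) of a logical matrix.
# Returns an integer matrix, 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  mask[is.na(mask)] <- FALSE
  todo <- which(mask)
  nextlab <- 0L
  stack <- integer(length(todo))
  for (s in todo) {
    if (lab[s] != 0L) next
    nextlab <- nextlab + 1L
    top <- 1L; stack[1L] <- s; lab[s] <- nextlab
    while (top > 0L) {
      idx <- stack[top]; top <- top - 1L
      r <- ((idx - 1L) %% nr) + 1L
      c <- ((idx - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        jdx <- (cc - 1L) * nr + rr
        if (mask[jdx] && lab[jdx] == 0L) {
          lab[jdx] <- nextlab
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- jdx
        }
      }
    }
  }
  lab
}
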
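#' Single-band raster grid
#'
#' Lightweight container for a single-band raster: a numeric matrix of cell
#' values (rows run north to south), a cell size in meters and the projected
#' coordinates of the upper-left corner. `NA` values mark NoData cells.
#'
#' @param values numeric matrix of cell values; `NA` = NoData.
#' @param cell_size cell edge length in meters (default 90, the native
#'   resolution of the models).
#' @param origin length-2 numeric, projected `(x, y)` of the upper-left
#'   *corner* of the grid.
#' @return An object of class `grid`.
#' @export
grid <- function(values, cell_size = 90, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a single positive number")
  if (length(origin) != 2L || any(!is.finite(origin)))
    stop("origin must be a finite (x, y) pair")
  if (any(is.infinite(values), na.rm = TRUE))
    stop("grid values must be finite where unmasked")
  structure(list(values = values, cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "grid")
}

#' @export
is_grid <- function(x) inherits(x, "grid")

#' @export
dim.grid <- function(x) dim(x$values)

#' @export
as.matrix.grid <- function(x, ...) x$values

#' Replace the values of a grid, keeping its geometry
#' @param g a `grid`
#' @param values replacement matrix (same shape)
#' @return a `grid`
#' @export
grid_like <- function(g, values) {
  if (!identical(dim(g$values), dim(as.matrix(values))))
    stop("replacement values do not match grid shape")
  grid(values, g$cell_size, g$origin)
}

#' @export
print.grid <- function(x, ...) {
  d <- dim(x)
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid> %d x %d cells, %.6g m resolution\n", d[1], d[2], x$cell_size))
  cat(sprintf("  origin (UL corner): (%.6g, %.6g)\n", x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  values: [%.6g, %.6g], %d NoData cells\n",
                min(v), max(v), sum(is.na(x$values))))
  else cat("  all cells NoData\n")
  invisible(x)
}

#' @export
plot.grid <- function(x, main = NULL, col = grDevices::hcl.colors(64, "YlOrBr", rev = TRUE), ...) {
  cc <- cell_centers(x)
  # image() wants x ascending and z[x, y]; transpose and flip rows
  z <- t(x$values[nrow(x$values):1, , drop = FALSE])
  graphics::image(cc$x, rev(cc$y), z, col = col, asp = 1, main = main,
                  xlab = "x (m)", ylab = "y (m)", useRaster = TRUE, ...)
  invisible(x)
}

#' Cell center coordinates
#' @param g a `grid`
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south) center coordinates.
#' @export
cell_centers <- function(g) {
  d <- dim(g)
  list(x = g$origin[1] + (seq_len(d[2]) - 0.5) * g$cell_size,
       y = g$origin[2] - (seq_len(d[1]) - 0.5) * g$cell_size)
}

#' Row/column index of the cell containing each point
#'
#' Points outside the extent get `NA`. Points exactly on an interior cell
#' boundary belong to the cell to the south/east (floor convention).
#'
#' @param g a `grid`
#' @param x,y projected coordinates
#' @return integer matrix with columns `row`, `col`
#' @export
cell_at <- function(g, x, y) {
  d <- dim(g)
  col <- floor((x - g$origin[1]) / g$cell_size) + 1L
  row <- floor((g$origin[2] - y) / g$cell_size) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1] |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#' @param g a `grid`
#' @param x,y projected coordinates
#' @return numeric vector (NA outside the extent or on NoData cells)
#' @export
grid_extract <- function(g, x, y) {
  rc <- cell_at(g, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- g$values[rc[ok, , drop = FALSE]]
  out
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$origin - b$origin) < tol)
}

check_geometry <- function(...) {
  gs <- list(...)
  for (i in seq_along(gs)[-1])
    if (!same_geometry(gs[[1]], gs[[i]]))
      stop("grids do not share geometry (shape, cell size, origin)")
  invisible(TRUE)
}

#' Normalize a non-negative grid to [0, 1]
#'
#' Divides by the maximum unmasked value, so the result always attains 1
#' wherever the input attains its maximum. An all-zero grid is returned
#' unchanged (all zeros) rather than raising: partial models produced by the
#' sensitivity analysis can legitimately zero out a factor.
#'
#' @param g a `grid` with non-negative unmasked values
#' @return a `grid` in [0, 1]
#' @export
normalize01 <- function(g) {
  stopifnot(is_grid(g))
  v <- g$values
  if (any(v < 0, na.rm = TRUE)) stop("normalize01 requires non-negative values")
  m <- suppressWarnings(max(v, na.rm = TRUE))
  if (!is.finite(m) || m == 0) return(g)
  grid_like(g, v / m)
}

#' Quantile classification of a grid
#'
#' Breaks at the empirical 1/k ... (k-1)/k quantiles (type 1, i.e. actual data
#' values, which makes the classification exactly invariant under strictly
#' increasing transforms of the values). Duplicate breaks arising from heavy
#' ties (e.g. a large mass of zero cells) are merged, reducing the effective
#' number of classes.
#'
#' @param g a `grid`
#' @param k target number of classes (default 5)
#' @return An object of class `quantile_class_grid`: list with `classes` (a
#'   `grid` of integer ranks 1..k_effective), `breaks` (strictly increasing
#'   upper break values) and `k_effective`.
#' @export
quantile_classify <- function(g, k = 5) {
  stopifnot(is_grid(g))
  if (k < 2) stop("k must be at least 2")
  x <- g$values[!is.na(g$values)]
  if (length(x) < k) stop("fewer unmasked cells than classes")
  if (min(x) == max(x))
    stop("degenerate quantiles: grid has no value variation")
  br <- unique(stats::quantile(x, probs = seq_len(k - 1) / k, type = 1, names = FALSE))
  br <- br[br < max(x)]           # never leave an empty top class
  cls <- matrix(findInterval(g$values, br, left.open = TRUE) + 1L,
                nrow(g$values), ncol(g$values))
  cls[is.na(g$values)] <- NA_integer_
  structure(list(classes = grid_like(g, cls), breaks = br,
                 k_effective = length(br) + 1L),
            class = "quantile_class_grid")
}

#' @export
print.quantile_class_grid <- function(x, ...) {
  cat(sprintf("<quantile classes> k_effective = %d, breaks: %s\n",
              x$k_effective, paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}

# ---- distance transforms -----------------------------------------------

# Exact 1-D squared distance transform (lower envelope of parabolas).
# f: squared-distance seeds (0 at sources, Inf elsewhere, finite after a
# first pass). Returns the transform; all-Inf input comes back unchanged.
dt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 0L
  for (q in fin) {
    if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; next }
    repeat {
      p <- v[k]
      s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) break
      } else break
    }
    if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf }
    else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf }
  }
  d <- numeric(n); j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < q) j <- j + 1L
    p <- v[j]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

# Exact squared Euclidean distance transform, in cell units, to TRUE cells
# of a logical matrix. Cells with no source anywhere return Inf.
dist_transform_sq <- function(src) {
  nr <- nrow(src); nc <- ncol(src)
  f <- matrix(Inf, nr, nc)
  f[src] <- 0
  for (j in seq_len(nc)) f[, j] <- dt1d(f[, j])
  for (i in seq_len(nr)) f[i, ] <- dt1d(f[i, ])
  f
}

#' Euclidean distance to source cells
#'
#' Exact center-to-center Euclidean distance (meters) from every cell to the
#' nearest cell where `source` is TRUE, computed with a separable exact
#' distance transform.
#'
#' @param g a `grid` providing the geometry
#' @param source logical matrix (same shape) marking source cells
#' @return a `grid` of distances in meters (`Inf` if no source exists)
#' @export
grid_distance_to <- function(g, source) {
  stopifnot(is_grid(g), identical(dim(source), dim(g$values)))
  grid_like(g, sqrt(dist_transform_sq(source)) * g$cell_size)
}

# ---- focal (moving window) statistics ----------------------------------

# 2-D linear convolution via FFT, zero padded ("full" convolution cropped so
# that out[i, j] = sum_{u,v} a[i-u+R1, j-v+R2] k[u, v] with the kernel center
# at (R1+1, R2+1) for an odd-sized kernel.
conv2_centered <- function(a, kern) {
  nr <- nrow(a); nc <- ncol(a)
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- a
  K <- matrix(0, pr, pc); K[seq_len(kr), seq_len(kc)] <- kern
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L; c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nr), c0 + seq_len(nc)]
}

disc_kernel <- function(radius_cells) {
  r <- as.integer(radius_cells)
  off <- -r:r
  k <- outer(off, off, function(i, j) as.numeric(i * i + j * j <= r * r))
  k
}

# Mean of m over a circular window of the given radius (cells), restricted to
# the window-grid intersection; NA cells contribute nothing.
focal_disc_mean <- function(m, radius_cells) {
  k <- disc_kernel(radius_cells)
  w <- !is.na(m)
  m0 <- m; m0[!w] <- 0
  num <- conv2_centered(m0, k)
  den <- conv2_centered(matrix(as.numeric(w), nrow(m), ncol(m)), k)
  den[den < 0.5] <- NA          # fully masked window
  out <- num / pmax(den, 0.5)
  out[is.na(den)] <- NA
  out
}
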
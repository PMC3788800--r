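test_that("wetland density is count per window area", {
  g <- grid(matrix(0, 21, 21), cell_size = 500, origin = c(0, 10500))
  # 157 wetland points uniformly inside a 5-km disc centered on cell (11, 11)
  ctr <- c(10.5 * 500, 10500 - 10.5 * 500)
  set.seed(9)
  th <- runif(157, 0, 2 * pi); rr <- 5000 * sqrt(runif(157))
  pts <- cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th))
  d <- focal_wetland_density(pts, g, radius = 5000)
  expect_equal(d$values[11, 11], 157 / (pi * 25), tolerance = 1e-12)
  # empty input and radius guard
  expect_true(all(as.matrix(focal_wetland_density(list(), g)) == 0))
  expect_error(focal_wetland_density(pts, g, radius = 100), "at least one cell")
  # single wetland at a cell center: 1/(pi*25) at every cell within 5 km
  one <- focal_wetland_density(rbind(ctr), g, radius = 5000)
  expect_equal(one$values[11, 11], 1 / (pi * 25))
  expect_equal(one$values[11, 1], 1 / (pi * 25))  # 5000 m away: on the rim, in
  expect_equal(one$values[1, 1], 0)               # 7071 m away: out
})

test_that("the density ramp reproduces the published anchors", {
  d <- grid(matrix(c(0, 1.99, 2, 15, 28, 40), 2, 3))
  f <- density_to_importance(d)
  expect_equal(as.vector(f$values), c(0, 0, 0.25, 0.25 + 13 / 26 * 0.75, 1, 1))
  expect_error(density_to_importance(grid(matrix(-1, 1, 1))), "non-negative")
})

test_that("inverse-distance-squared decay follows the stated form", {
  m <- matrix(0, 11, 11); m[6, 6] <- 1
  g <- grid(m, cell_size = 90, origin = c(0, 990))
  r <- inverse_distance_decay(g, max_dist = 500)
  expect_equal(r$values[6, 6], 1)                      # source keeps its value
  expect_equal(r$values[6, 8], (90 / 180)^2)            # d = 180 m -> 0.25
  expect_equal(r$values[6, 1], (90 / 450)^2)            # 450 m, still inside 500
  expect_equal(r$values[6, 2], (90 / 360)^2)
  expect_equal(r$values[1, 1], 0)                       # sqrt(50)*90 = 636 m > 500
  expect_error(inverse_distance_decay(grid(matrix(2, 2, 2))), "\\[0, 1\\]")
})

test_that("buffering carries the source value and max-combines overlaps", {
  m <- matrix(0, 21, 21); m[11, 3] <- 1; m[11, 14] <- 0.5
  g <- grid(m, cell_size = 100, origin = c(0, 2100))
  b <- buffer_carry_value(g, dist = 1000)
  expect_equal(b$values[11, 12], 1)     # 900 m from the 1-valued source
  expect_equal(b$values[20, 3], 1)      # 900 m south
  expect_equal(b$values[11, 21], 0.5)   # 700 m from the 0.5-valued source
  expect_equal(b$values[11, 18], 0.5)
  expect_equal(b$values[1, 21], 0)      # far from everything
  # overlap zone between the two sources takes the max
  expect_equal(b$values[11, 8], 1)      # 500 m from 1-source, 600 from 0.5
  expect_error(buffer_carry_value(g, dist = 0), "positive")
})

test_that("decay and buffer agree with a brute-force all-pairs oracle", {
  set.seed(31)
  m <- matrix(0, 50, 50)
  m[sample(2500, 12)] <- sample(c(0.25, 0.5, 1), 12, replace = TRUE)
  g <- grid(m, cell_size = 90, origin = c(0, 4500))
  oracle <- brute_nearest_source(g)
  dec <- inverse_distance_decay(g, max_dist = 500)$values
  buf <- buffer_carry_value(g, dist = 1000)$values
  want_dec <- ifelse(oracle$dist == 0, m,
                     ifelse(oracle$dist <= 500,
                            oracle$val * pmin(1, (90 / oracle$dist)^2), 0))
  expect_equal(dec, want_dec, tolerance = 1e-12)
  # buffer oracle: max over all sources within 1 km
  src <- which(m > 0, arr.ind = TRUE)
  want_buf <- matrix(0, 50, 50)
  for (r in 1:50) for (c in 1:50) {
    d <- sqrt((src[, 1] - r)^2 + (src[, 2] - c)^2) * 90
    if (any(d <= 1000)) want_buf[r, c] <- max(m[src[d <= 1000, , drop = FALSE]])
  }
  expect_equal(buf, want_buf, tolerance = 1e-12)
})

test_that("topographic position flags ridge crests and nothing on flat ground", {
  flat <- grid(matrix(1500, 40, 40), cell_size = 90)
  expect_true(all(as.matrix(topographic_position(flat, windows = c(10, 20))) == 0))
  # single sharp east-west Gaussian ridge through the middle rows
  z <- 1500 + 400 * exp(-outer((1:40 - 20.5)^2 / (2 * 2^2), rep(1, 40)))
  ridge <- grid(z, cell_size = 90)
  tp <- topographic_position(ridge, windows = c(10, 20))
  expect_true(all(tp$values[20:21, 5:36] == 1))      # crest flagged
  expect_true(all(tp$values[c(1:10, 31:40), ] == 0)) # plains not flagged
  valley <- grid(3000 - z, cell_size = 90)
  tv <- topographic_position(valley, windows = c(10, 20))
  expect_true(all(tv$values[20:21, ] == 0))          # valley floor never a ridge
  expect_error(topographic_position(flat, windows = c(10, 200)), "window")
})

test_that("updraft factor scores the aspect/wind category match", {
  mk <- function(az) grid(matrix(az, 2, 2))
  wind <- function(cat) grid(matrix(cat, 2, 2))
  expect_true(all(as.matrix(updraft_factor(mk(0), wind(1))) == 1))      # N vs N
  expect_true(all(as.matrix(updraft_factor(mk(0), wind(2))) == 0.75))   # N vs NE
  expect_true(all(as.matrix(updraft_factor(mk(350), wind(8))) == 0.75)) # N vs NW
  expect_true(all(as.matrix(updraft_factor(mk(0), wind(5))) == 0))      # N vs S
  expect_true(all(as.matrix(updraft_factor(mk(-1), wind(1))) == 0))     # flat
  expect_error(updraft_factor(mk(0), wind(9)), "1\\.\\.8")
})

test_that("modifiers multiply and are range-checked", {
  f <- grid(matrix(0.5, 3, 3))
  ones <- grid(matrix(1, 3, 3))
  expect_identical(as.matrix(apply_modifiers(f, list(ones))), as.matrix(f))
  zero <- grid(matrix(0, 3, 3))
  expect_true(all(as.matrix(apply_modifiers(f, list(zero, ones))) == 0))
  m2 <- grid(matrix(2, 3, 3)); m125 <- grid(matrix(1.25, 3, 3))
  expect_true(all(as.matrix(apply_modifiers(f, list(m2, m125))) == 1.25))
  expect_error(apply_modifiers(f, list(grid(matrix(2.5, 3, 3)))), "\\[0, 2\\]")
})

test_that("the weighted combination matches hand arithmetic and scales out weights", {
  t1 <- grid(matrix(c(0, 0.5, 1, 0.25, 0.75, 1, 0, 0.5, 0.25), 3, 3))
  t2 <- grid(matrix(c(1, 0, 0.5, 0.5, 0.25, 0, 1, 0, 0.75), 3, 3))
  mis <- combine_mis(list(t1, t2), weights = c(3, 1))
  # cell-by-cell oracle: s = 3*t1 + t2, then divide by its max
  s <- 3 * t1$values + t2$values
  expect_equal(as.matrix(mis), s / max(s), tolerance = 1e-15)
  expect_equal(as.matrix(combine_mis(list(t1, t2), c(30, 10))), as.matrix(mis))
  # a single term (or two identical terms) is returned unchanged
  expect_equal(as.matrix(combine_mis(list(t1), 5)), t1$values / max(t1$values))
  expect_equal(as.matrix(combine_mis(list(t1, t1), c(1, 3))),
               t1$values / max(t1$values))
  expect_error(combine_mis(list(t1), 0), "positive")
})
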
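test_that("accuracy filtering keeps precise records (with the literal reading as option)", {
  occ <- occ_df(x = c(0, 100, 200), y = c(0, 0, 0))
  occ$accuracy_m <- c(100, 400, 1000)
  kept <- filter_by_accuracy(occ)
  expect_equal(kept$accuracy_m, c(100, 400))
  expect_equal(nrow(filter_by_accuracy(occ[0, ])), 0)
  literal <- filter_by_accuracy(occ, direction = "min_error")
  expect_equal(literal$accuracy_m, c(400, 1000))
  expect_equal(nrow(filter_by_accuracy(occ, max_quality_rank = 1)), 1)
})

test_that("distance thinning keeps the better-quality point of close pairs", {
  pair <- occ_df(x = c(0, 500), y = c(0, 0), quality = c(2, 1))
  kept <- thin_min_distance(pair)
  expect_equal(kept$quality_rank, 1)        # 500 m apart: better point wins
  apart <- occ_df(x = c(0, 900), y = c(0, 0), quality = c(2, 1))
  expect_equal(nrow(thin_min_distance(apart)), 2)
  # chain of 3 at 500-m spacing, descending quality: first and third survive
  chain <- occ_df(x = c(0, 500, 1000), y = c(0, 0, 0), quality = c(1, 2, 3))
  expect_equal(thin_min_distance(chain)$x, c(0, 1000))
})

test_that("thinning is idempotent on random point sets", {
  set.seed(17)
  for (trial in 1:5) {
    occ <- occ_df(x = runif(80, 0, 5000), y = runif(80, 0, 5000),
                  quality = sample(1:5, 80, TRUE))
    once <- thin_min_distance(occ)
    expect_identical(thin_min_distance(once), once)
    d <- as.matrix(dist(once[, c("x", "y")]))
    expect_true(all(d[upper.tri(d)] >= 800))
  }
})

test_that("stratified subsampling caps per species and is reproducible", {
  occ <- occ_df(x = seq_len(28), y = rep(0, 28),
                species = c(rep("a", 25), rep("b", 3)), quality = 1)
  expect_warning(sub <- stratified_subsample(occ, seed = 3), "50")
  expect_equal(as.vector(table(sub$species)), c(10, 3))
  expect_identical(sub, suppressWarnings(stratified_subsample(occ, seed = 3)))
  expect_false(identical(sub$x,
    suppressWarnings(stratified_subsample(occ, seed = 4))$x))
})

test_that("strictly monotone area-adjusted frequencies give Boyce index +/-1", {
  # 25 x 40 grid, values 1..1000; bins engineered with shrinking area shares
  g <- seq_grid(25, 40)
  sizes <- c(400, 180, 120, 90, 70, 50, 40, 25, 15, 10)
  starts <- c(0, cumsum(sizes)[-10])
  pts_vals <- unlist(lapply(starts, function(s) s + 1:10))
  cc <- cell_centers(g)
  rc <- cbind(((pts_vals - 1) %% 25) + 1, ((pts_vals - 1) %/% 25) + 1)
  pts <- data.frame(x = cc$x[rc[, 2]], y = cc$y[rc[, 1]])
  b <- boyce(g, pts, k = 10)
  expect_equal(b$k_effective, 10)
  expect_equal(b$bins$area_fraction, sizes / 1000)
  expect_true(all(diff(b$bins$ratio) > 0))
  expect_equal(b$rho, 1, tolerance = 1e-14)
  expect_lt(b$p_value, 0.01)
  # growing area shares give strictly decreasing ratios: rho = -1
  sizes_r <- rev(sizes)
  starts_r <- c(0, cumsum(sizes_r)[-10])
  vals_r <- unlist(lapply(starts_r, function(s) s + 1:10))
  rc_r <- cbind(((vals_r - 1) %% 25) + 1, ((vals_r - 1) %/% 25) + 1)
  pts_r <- data.frame(x = cc$x[rc_r[, 2]], y = cc$y[rc_r[, 1]])
  b2 <- boyce(g, pts_r, k = 10)
  expect_true(all(diff(b2$bins$ratio) < 0))
  expect_equal(b2$rho, -1, tolerance = 1e-14)
  expect_gt(b2$p_value, 0.95)
  expect_error(boyce(g, pts[1:5, ], k = 10), "at least k")
})

test_that("bin fractions sum to one and ratios match their definition", {
  st <- fixture_stack(60)
  m <- migration_model(st, "sparse_grassland")
  occ <- generate_occurrences(m$mis, 300, bias = 2, seed = 8)
  b <- boyce(m, occ, k = 10)
  expect_equal(sum(b$bins$point_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(b$bins$area_fraction), 1, tolerance = 1e-9)
  expect_equal(b$bins$ratio,
               b$bins$point_fraction / b$bins$area_fraction)
})

test_that("the Boyce correlation matches an independent rank-correlation oracle", {
  ratio <- c(0.3, 1.7, 0.9, 1.1, 2.4, 0.2, 1.05, 3.0, 0.8, 1.4)
  rho_pkg <- stopover:::spearman_rho(ratio, seq_along(ratio))
  # brute-force Spearman: rank both sequences, Pearson on the ranks
  r1 <- rank(ratio); r2 <- rank(seq_along(ratio))
  oracle <- sum((r1 - mean(r1)) * (r2 - mean(r2))) /
    sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  expect_equal(rho_pkg, oracle, tolerance = 1e-12)
  # exact permutation p-value at k = 5 equals full enumeration
  r5 <- c(0.4, 1.2, 0.9, 2.0, 1.7)
  rho5 <- stopover:::spearman_rho(r5, 1:5)
  pm <- stopover:::all_perms(5)
  brute <- mean(apply(pm, 1, function(ix)
    cor(r5[ix], 1:5, method = "spearman")) >= rho5 - 1e-12)
  expect_equal(stopover:::boyce_p_value(r5, rho5), brute)
})

test_that("tied scores merge Boyce bins instead of fabricating thresholds", {
  v <- matrix(c(rep(0, 60), seq_len(40)), 10, 10)
  g <- grid(v, cell_size = 90, origin = c(0, 900))
  set.seed(2)
  # half the points on zero cells, half spread over the positive tail
  zero_cells <- which(v == 0, arr.ind = TRUE)[1:30, ]
  pos_cells <- which(v > 0, arr.ind = TRUE)
  cc <- cell_centers(g)
  pts <- data.frame(
    x = cc$x[c(zero_cells[, 2], pos_cells[, 2])],
    y = cc$y[c(zero_cells[, 1], pos_cells[, 1])])
  b <- boyce(g, pts, k = 10)
  expect_lt(b$k_effective, 10)
  expect_equal(sum(b$bins$point_fraction), 1)
})

test_that("expert scoring weights ratings by expertise", {
  expect_equal(expert_weighted_score(
    data.frame(model_rating = c(0, 0, 0), expertise = c(1, 1.5, 2))), 0)
  expect_equal(expert_weighted_score(
    data.frame(model_rating = 0.5, expertise = 2)), 1.0)
  expect_equal(expert_weighted_score(
    data.frame(model_rating = c(0.5, 1), expertise = c(1.75, 2))),
    mean(c(0.875, 2)))
  expect_error(expert_weighted_score(data.frame()[0, ]), "at least one")
  expect_error(expert_weighted_score(
    data.frame(model_rating = 0.3, expertise = 2)), "ratings")
  expect_error(expert_weighted_score(
    data.frame(model_rating = 0.5, expertise = 1.1)), "expertise")
})

test_that("migration-window filtering keeps in-window records per species", {
  occ <- occ_df(x = 1:4, y = 1:4, species = c("a", "a", "b", "c"))
  occ$date <- as.Date(c("2012-04-15", "2012-06-01", "2012-03-05", "2012-04-15"))
  win <- data.frame(species = c("a", "b"),
                    start_mmdd = c("04-01", "12-20"), end_mmdd = c("05-15", "03-10"))
  kept <- filter_by_migration_window(occ, win)
  expect_equal(kept$x, c(1, 3))   # b's window wraps the new year
})
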
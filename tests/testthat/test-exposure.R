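test_that("quantile recoding assigns the five levels by rank", {
  g <- seq_grid(10, 10)
  q <- quantile_recode(g)
  expect_equal(as.vector(table(q$values)), rep(20L, 5))
  expect_equal(q$values[g$values == 100], 1)           # top cell -> 1
  expect_equal(q$values[g$values == 1], 0)
  # monotone transform leaves the recoding unchanged
  expect_identical(quantile_recode(grid_like(g, g$values^3))$values, q$values)
  # merged bins keep the top levels anchored at 1
  v <- c(rep(0, 70), 1:30)
  qm <- quantile_recode(grid(matrix(v, 10, 10)))
  expect_equal(max(qm$values), 1)
  expect_true(all(qm$values %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("exposure is the symmetric product of recoded surfaces", {
  lv <- c(0, 0.25, 0.5, 0.75, 1)
  a <- grid(matrix(rep(lv, 5), 5, 5))
  b <- grid(matrix(rep(lv, each = 5), 5, 5))
  e <- exposure_product(a, b)
  # full 25-pair enumeration oracle: e[i, j] = lv[i] * lv[j]
  expect_equal(e$values, outer(lv, lv), tolerance = 1e-15)
  expect_equal(e$values[4, 4], 0.5625)     # high x high
  expect_true(all(e$values[1, ] == 0))     # absorbing zero
  expect_equal(exposure_product(b, a)$values, e$values)
  expect_error(exposure_product(a, grid(matrix(0.3, 5, 5))), "recoded")
})

test_that("exposure classes cover [0, 1] with the published boundaries", {
  lv <- c(0, 0.25, 0.5, 0.75, 1)
  products <- sort(unique(as.vector(outer(lv, lv))))
  g <- grid(matrix(products, 1, length(products)))
  cls <- exposure_class(g)
  want <- c(0, .0625, .125, .1875, .25, .375, .5, .5625, .75, 1)
  expect_equal(products, want)
  expect_equal(as.vector(cls$values), c(1, 1, 2, 2, 2, 3, 3, 4, 4, 5))
  expect_equal(attr(cls, "levels")[cls$values[g$values == 0.5625]], "high")
  expect_equal(attr(cls, "levels")[cls$values[g$values == 0]], "very_low")
  expect_error(exposure_class(grid(matrix(1.2, 1, 1))), "\\[0, 1\\]")
})

test_that("exposure SD is the population SD across models", {
  a <- grid(matrix(0, 2, 2)); b <- grid(matrix(0.5, 2, 2))
  s <- exposure_sd(list(a, b))
  expect_true(all(s$values == 0.25))
  expect_true(all(exposure_sd(list(b, b, b))$values == 0))
  set.seed(4)
  gs <- lapply(1:5, function(i) grid(matrix(runif(16), 4, 4)))
  expect_true(all(exposure_sd(gs)$values <= 0.5))
  expect_error(exposure_sd(list(a)), "at least two")
})

test_that("top-two-quantile masks and their overlaps behave like sets", {
  g <- seq_grid(10, 10)
  mask <- top2_mask(quantile_recode(g))
  expect_equal(sum(mask$values), 40)
  expect_error(top2_mask(quantile_recode(grid(matrix(1, 3, 3)))), "variation")
  # overlap identities on random masks: A*|mig| = B*|wind| = 100*|intersection|
  set.seed(12)
  for (trial in 1:5) {
    m1 <- grid(matrix(runif(100) < 0.4, 10, 10) * 1)
    m2 <- grid(matrix(runif(100) < 0.3, 10, 10) * 1)
    if (sum(m1$values) == 0 || sum(m2$values) == 0) next
    ov <- overlap_percentages(m1, m2)
    ni <- sum(m1$values * m2$values)
    expect_equal(ov[["pct_of_migration_area"]] * sum(m1$values),
                 100 * ni, tolerance = 1e-12)
    expect_equal(ov[["pct_of_wind_area"]] * sum(m2$values),
                 100 * ni, tolerance = 1e-12)
  }
  same <- grid(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(unname(overlap_percentages(same, same)), c(100, 100))
  disj <- grid(matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(unname(overlap_percentages(same, disj)), c(0, 0))
  expect_error(overlap_percentages(same, grid(matrix(0, 2, 2))), "empty")
  # |mig| = 50, |wind| = 20, |int| = 10 -> (20, 50)
  big <- grid(matrix(c(rep(1, 50), rep(0, 50)), 10, 10))
  small <- grid(matrix(c(rep(1, 10), rep(0, 40), rep(1, 10), rep(0, 40)), 10, 10))
  expect_equal(unname(overlap_percentages(big, small)), c(20, 50))
})

test_that("cumulative masks are unions", {
  a <- grid(matrix(c(1, 0, 0, 0), 2, 2))
  b <- grid(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(cumulative_mask(list(a))$values, a$values)
  u <- cumulative_mask(list(a, b))
  expect_equal(u$values, matrix(c(1, 1, 1, 0), 2, 2))
  expect_gte(sum(u$values), max(sum(a$values), sum(b$values)))
  comp <- grid_like(a, 1 - a$values)
  expect_true(all(cumulative_mask(list(a, comp))$values == 1))
})

test_that("mean_ci gives a symmetric normal-approximation interval", {
  mc <- mean_ci(c(10, 20))
  expect_equal(mc[["mean"]], 15)
  expect_equal(mc[["ci_high"]] - mc[["mean"]], mc[["mean"]] - mc[["ci_low"]])
  same <- mean_ci(c(7, 7, 7))
  expect_equal(unname(same), c(7, 7, 7))
  expect_error(mean_ci(5), "at least two")
})

test_that("the exposure report assembles the overlay end to end", {
  st <- fixture_stack(60)
  m <- migration_model(st, "raptor")
  wind <- generate_wind_potential(st, seed = 2, windows = c(10, 30))
  s <- sensitivity(m)
  er <- exposure_report(m, wind, partials = s$partials)
  expect_true(all(er$exposure$values >= 0 & er$exposure$values <= 1))
  prods <- sort(unique(as.vector(outer(c(0, .25, .5, .75, 1), c(0, .25, .5, .75, 1)))))
  expect_true(all(vapply(as.vector(er$exposure$values),
                         function(x) any(abs(x - prods) < 1e-9), TRUE)))
  expect_true(all(er$classes$values %in% 1:5))
  expect_true(all(er$sd$values <= 0.5))
  expect_equal(nrow(er$overlap), 2)
  expect_true(all(er$overlap$full_model >= 0 & er$overlap$full_model <= 100))
  expect_true(all(er$overlap$ci_low <= er$overlap$mean &
                  er$overlap$mean <= er$overlap$ci_high))
})
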
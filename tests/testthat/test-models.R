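test_that("canonical specs carry the published term structure and weights", {
  w <- canned_spec("wetland")
  expect_length(w$terms, 5)
  expect_equal(unname(sapply(w$terms, `[[`, "weight")), c(1, 3, 1, 1, 1))
  expect_equal(w$terms[[2]]$label, "Wetland density")
  expect_equal(w$terms[[2]]$weight, 3)
  r <- canned_spec("riparian")
  expect_length(r$terms, 2)
  expect_equal(r$terms[[1]]$label, "Streams")
  expect_equal(r$terms[[1]]$weight, 2)
  expect_equal(r$terms[[2]]$weight, 1)
  ra <- canned_spec("raptor")
  expect_length(ra$terms, 4)
  expect_true(all(sapply(ra$terms, `[[`, "weight") == 1))
  g <- canned_spec("sparse_grassland")
  expect_length(g$terms, 2)
  expect_error(canned_spec("penguin"))
})

test_that("factors take the published table values on the hand-built stack", {
  ts <- toy_stack(); st <- ts$stack; o <- ts$opts
  sw <- prepare_factor("streams_wetland", st, o)$values
  expect_true(all(sw[, 2] == 1))                 # large river
  expect_equal(sw[5, 4], 0.5)                    # order 3
  expect_equal(sw[2, 5], 0.25)                   # order 2
  expect_equal(sw[5, 2], 1)                      # crossing: max combine
  expect_equal(sw[1, 4], 0)
  ws <- prepare_factor("wetland_size", st, o)$values
  expect_equal(ws[2, 4], 1)                      # 20 ha
  expect_equal(ws[3, 5], 0.5)                    # 8 ha
  expect_equal(ws[2, 5], 0)                      # 3 ha: unvalued in size...
  wd <- prepare_factor("wetland_density", st, o)$values
  dens_235 <- 3 / (pi * 0.25)                    # ...but counted in density
  expect_equal(wd[2, 5], 0.25 + (dens_235 - 2) / 26 * 0.75)
  expect_equal(wd[6, 1], 0)                      # no wetland within 500 m
  fo <- prepare_factor("forage", st, o)$values
  expect_equal(fo[1, 6], 1); expect_equal(fo[2, 6], 0.5); expect_equal(fo[3, 6], 0)
  ra <- prepare_factor("streams_raptor", st, o)$values
  expect_equal(ra[2, 5], 0)                      # order-2 carries no raptor value
  expect_true(all(ra[, 2] == 1))
})

test_that("riparian stream values split by perenniality and decay with distance", {
  ts <- toy_stack(); st <- ts$stack; o <- ts$opts
  sr <- prepare_factor("streams_riparian", st, o)$values
  expect_true(all(sr[, 2] == 1))                 # perennial order 7
  expect_equal(sr[2, 5], 0.25)                   # intermittent order 2
  expect_equal(sr[1, 4], 0.25)                   # 200 m from it: full decay value
  # intermittent order-5 stream valued 0.25
  st2 <- st
  st2$streams <- list(list(xy = rbind(c(300, 1150), c(300, 50)),
                           order = 5L, perennial = FALSE, large_river = FALSE))
  expect_equal(prepare_factor("streams_riparian", st2, o)$values[3, 2], 0.25)
})

test_that("modifiers take the published class values on the hand-built stack", {
  ts <- toy_stack(); st <- ts$stack; o <- ts$opts
  el <- prepare_modifier("elevation", st, o)$values
  expect_true(all(el[1:2, ] == 1))       # 2000 m < 2438
  expect_true(all(el[3:4, ] == 0.5))     # 2500 m in [2438, 2743)
  expect_true(all(el[5:6, ] == 0.1))     # 2800 m > 2743
  pr <- prepare_modifier("river_proximity", st, o)$values
  expect_equal(pr[1, 2], 2)              # on an order>=3 stream
  expect_equal(pr[1, 4], 1.5)            # 400 m away (scaled class 2)
  expect_equal(pr[1, 6], 1)              # 800 m away
  fw <- prepare_modifier("flyway", st, o)$values
  expect_true(all(fw[, 4:6] == 1.25) && all(fw[, 1:3] == 1))
  cw <- prepare_modifier("cottonwood", st, o)$values
  expect_equal(cw[1, 2], 2)              # index 1 maps to 2
  expect_equal(cw[1, 1], 1.2)
  sdv <- prepare_modifier("structural_diversity", st, o)$values
  expect_equal(sdv[1, 4], 2)             # forest riparian
  expect_equal(sdv[1, 6], 1)             # grass riparian
  expect_equal(sdv[1, 3], 1)             # non-riparian: neutral
  so <- prepare_modifier("stream_orientation", st, o)$values
  expect_equal(so[3, 2], 2)              # north-south large river
  expect_equal(so[5, 5], 1)              # east-west order-3 stream
})

test_that("a single constant factor normalizes to MIS 1 everywhere", {
  ts <- toy_stack()
  spec <- structure(list(group = "sparse_grassland", season = "spring",
                         terms = list(list(factor = "prairie_dog",
                                           modifiers = character(0),
                                           weight = 1, label = "Prairie dog occurrence"))),
                    class = "group_model_spec")
  m <- migration_model(ts$stack, spec = spec, options = ts$opts)
  expect_true(all(m$mis$values == 1))
})

test_that("zeroed modifiers collapse the model to zero", {
  ts <- toy_stack()
  spec <- canned_spec("wetland")
  spec$terms <- spec$terms[2:3]   # both terms carry the elevation modifier
  o <- ts$opts; o$elevation_values <- c(0, 0, 0)
  m <- migration_model(ts$stack, spec = spec, options = o)
  expect_true(all(m$mis$values == 0))
})

test_that("MIS is invariant to rescaling all weights", {
  ts <- toy_stack()
  m1 <- migration_model(ts$stack, "wetland", options = ts$opts)
  spec2 <- canned_spec("wetland")
  for (i in seq_along(spec2$terms)) spec2$terms[[i]]$weight <- 2 * spec2$terms[[i]]$weight
  m2 <- migration_model(ts$stack, spec = spec2, options = ts$opts)
  expect_equal(m1$mis$values, m2$mis$values, tolerance = 1e-14)
})

test_that("removing an everywhere-neutral modifier leaves MIS bit-identical", {
  ts <- toy_stack(); st <- ts$stack
  st$grids$flyway_mask <- grid_like(st$grids$flyway_mask,
                                    matrix(0, 6, 6))   # flyway modifier == 1
  full <- migration_model(st, "wetland", options = ts$opts)
  spec <- canned_spec("wetland")
  for (i in seq_along(spec$terms))
    spec$terms[[i]]$modifiers <- setdiff(spec$terms[[i]]$modifiers, "flyway")
  dropped <- migration_model(st, spec = spec, options = ts$opts)
  expect_identical(full$mis$values, dropped$mis$values)
})

test_that("wetland MIS is zero far from any valued feature", {
  st <- generate_landscape(
    landscape_params(extent_cells = c(60, 60), wetland_cluster_count = 2,
                     wetlands_per_cluster = 25, n_stream_trunks = 2,
                     crop_fraction = 0.05), seed = 13)
  m <- migration_model(st, "wetland")
  L <- m$layers$factors
  far <- L$streams_wetland$values == 0 & L$wetland_density$values == 0 &
    L$wetland_size$values == 0 & L$forage$values == 0 &
    L$takeoff_buffer$values == 0
  expect_true(any(far))
  expect_true(all(m$mis$values[far] == 0))
})

test_that("model object methods behave like a fitted-model interface", {
  ts <- toy_stack()
  m <- migration_model(ts$stack, "wetland", options = ts$opts)
  expect_s3_class(m, "migration_model")
  expect_equal(unname(coef(m)), c(1, 3, 1, 1, 1))
  expect_equal(predict(m, data.frame(x = 300, y = 300)), m$mis$values[5, 2])
  occ <- simulate(m, nsim = 2, seed = 3, n = 40)
  expect_length(occ, 2)
  expect_equal(nrow(occ[[1]]), 40)
  expect_output(print(m), "wetland birds")
  expect_output(print(summary(m)), "Quantile breaks")
})

test_that("missing layers raise a configuration error naming the layer", {
  ts <- toy_stack(); st <- ts$stack
  st$grids$crops <- NULL
  expect_error(prepare_factor("forage", st, ts$opts), "crops")
  expect_error(prepare_factor("made_up", ts$stack, ts$opts), "unknown factor")
  expect_error(prepare_modifier("made_up", ts$stack, ts$opts), "unknown modifier")
})
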
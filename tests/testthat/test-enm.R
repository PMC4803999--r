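test_that("region backgrounds are the union of occupied regions", {
  g <- toy_grid(4, 4)
  regions <- env_raster("region", matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4), g)
  # two points in region 1 (west columns)
  occ <- occurrence_set("a", c(0.5, 1.5), c(1.5, 2.5))
  m <- make_background(regions, occ)
  expect_equal(m$included, regions$values == 1)
  # points in both regions -> union
  occ2 <- occurrence_set("a", c(0.5, 3.5), c(1.5, 2.5))
  expect_true(all(make_background(regions, occ2)$included))
  # a point on an unlabelled cell is ignored with a warning
  regions$values[1, 1] <- NA; regions$mask[1, 1] <- FALSE
  occ3 <- occurrence_set("a", c(0.5, 1.5), c(3.5, 2.5))
  expect_warning(m3 <- make_background(regions, occ3), "ignored")
  expect_equal(sum(m3$included), sum(regions$values == 1, na.rm = TRUE))
  occ4 <- occurrence_set("a", 0.5, 3.5)
  expect_error(suppressWarnings(make_background(regions, occ4)), "no occurrence")
})

test_that("buffer backgrounds follow the haversine radius and are monotone", {
  g <- grid_spec(3, 3, 1, 0, -1.5)   # 1-degree cells straddling the equator
  # point at the center cell's center (0.5+1, hmm) -> use exact center (1.5, 0)
  occ <- occurrence_set("a", 1.5, 0)
  # neighbouring cell centers are ~111.2 km away: radius 100 gives 1 cell
  expect_equal(sum(buffer_background(occ, 100, g)$included), 1)
  # radius 112 reaches the 4 rook neighbours
  expect_equal(sum(buffer_background(occ, 112, g)$included), 5)
  # radius 0 keeps exactly the occupied cell even off-center
  off <- occurrence_set("a", 1.2, 0.3)
  expect_equal(sum(buffer_background(off, 0, g)$included), 1)
  # doubling the radius never shrinks the mask
  for (r in c(0, 50, 100, 150)) {
    small <- buffer_background(occ, r, g)$included
    big <- buffer_background(occ, 2 * r, g)$included
    expect_true(all(big[small]))
  }
})

test_that("matched presence and background means give a near-uniform map", {
  st <- toy_landscape(seed = 11)
  cells <- which(st$mask)
  bg <- stack_env(st, cells)
  # presences = the whole background: feature means match exactly
  m <- fit_suitability(bg, bg, reg = 0.1)
  expect_lt(max(abs(m$beta)), 1e-6)
  map <- project_suitability(m, st, background_mask(st$grid, st$mask),
                             link = "raw")
  expect_lt(diff(range(map$values)), 1e-6 / length(cells))
})

test_that("suitability increases with the niche variable in 1-D", {
  g <- grid_spec(10, 10, 1, 0, 0)
  v <- env_raster("x", matrix(seq(0, 1, length.out = 100), 10, 10), g)
  st <- raster_stack(list(v))
  # presences concentrated at high x
  pres <- matrix(c(0.9, 0.95, 0.85, 0.8, 0.99), ncol = 1,
                 dimnames = list(NULL, "x"))
  bgm <- stack_env(st, which(st$mask))
  m <- fit_suitability(pres, bgm, reg = 0.01)
  map <- project_suitability(m, st, background_mask(st$grid, st$mask),
                             link = "raw")
  x <- stack_env(st, map$cells)[, "x"]
  expect_gte(cor(x, map$values, method = "spearman"), 0.99)
})

test_that("fitting is deterministic and shrinks with regularization", {
  st <- toy_landscape(seed = 13)
  cells <- which(st$mask)
  pres <- stack_env(st, with_seed_test(2, sample(cells, 25)))
  bg <- stack_env(st, cells)
  m1 <- fit_suitability(pres, bg, reg = 0.05, seed = 4)
  m2 <- fit_suitability(pres, bg, reg = 0.05, seed = 4)
  expect_identical(m1$beta, m2$beta)
  norms <- vapply(c(0.01, 0.05, 0.2, 1), function(r)
    sum(abs(fit_suitability(pres, bg, reg = r)$beta)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("projection links behave as documented", {
  st <- toy_landscape(seed = 19)
  mask <- background_mask(st$grid, st$mask)
  cells <- which(st$mask)
  pres <- stack_env(st, with_seed_test(3, sample(cells, 20)))
  m <- fit_suitability(pres, stack_env(st, cells))
  raw <- project_suitability(m, st, mask, link = "raw")
  expect_equal(sum(raw$values), 1)
  expect_true(all(raw$values >= 0))
  # zero-coefficient model: uniform raw, constant logistic at tau
  m0 <- m; m0$beta[] <- 0
  raw0 <- project_suitability(m0, st, mask, link = "raw")
  expect_equal(raw0$values, rep(1 / length(cells), length(cells)))
  log0 <- project_suitability(m0, st, mask, link = "logistic", tau = 0.5)
  expect_equal(log0$values, rep(0.5, length(cells)))
})

test_that("AUC is the tie-corrected rank probability", {
  expect_equal(enm_auc(c(0.9, 0.8), c(0.7, 0.85, 0.1)), 5 / 6)
  expect_equal(enm_auc(rep(0.3, 4), rep(0.3, 6)), 0.5)
  expect_equal(enm_auc(c(5, 6), c(1, 2)), 1)
  expect_error(enm_auc(numeric(), 1), "empty")
})

test_that("a narrow-niche virtual species is modelled with AUC above 0.9", {
  st <- gen_raster_stack(31, n_vars = 4, n_rows = 32, n_cols = 32,
                         smoothness = 3, inter_layer_corr = 0.3)
  cells <- which(st$mask)
  mu <- setNames(drop(stack_env(st, cells[200])), names(st$layers))
  vs <- gen_virtual_species(st, mu, 0.3^2, 40, seed = 8, species_id = "v")
  et <- extract_env(vs$occurrences, st)
  m <- fit_suitability(as.matrix(et), stack_env(st, cells))
  map <- project_suitability(m, st, background_mask(st$grid, st$mask))
  pres <- map$values[match(attr(et, "cells"), map$cells)]
  expect_gt(enm_auc(pres, map$values), 0.9)
})
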
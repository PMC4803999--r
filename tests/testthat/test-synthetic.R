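test_that("raster generation is a pure function of seed and parameters", {
  a <- gen_raster_stack(5, n_vars = 3, n_rows = 16, n_cols = 20, smoothness = 2)
  b <- gen_raster_stack(5, n_vars = 3, n_rows = 16, n_cols = 20, smoothness = 2)
  expect_identical(a$layers[[2]]$values, b$layers[[2]]$values)
  expect_equal(a$grid$n_rows, 16L)
  expect_equal(a$grid$n_cols, 20L)
  expect_named(a$layers, c("bio1", "bio2", "bio3"))
  c_ <- gen_raster_stack(6, n_vars = 3, n_rows = 16, n_cols = 20, smoothness = 2)
  expect_false(identical(a$layers[[1]]$values, c_$layers[[1]]$values))
})

test_that("high target correlation produces r2 above the filter threshold", {
  st <- gen_raster_stack(9, n_vars = 2, n_rows = 64, n_cols = 64,
                         smoothness = 3, inter_layer_corr = 0.95)
  r <- cor(st$layers[[1]]$values[st$mask], st$layers[[2]]$values[st$mask])
  expect_gt(r^2, 0.75)
  expect_error(gen_raster_stack(1, n_vars = 3, inter_layer_corr = -0.5),
               "infeasible")
  expect_error(gen_raster_stack(1, n_vars = 2, inter_layer_corr = 1.2),
               "< 1")
})

test_that("virtual species peak where the environment matches the centroid", {
  st <- gen_raster_stack(3, n_vars = 2, n_rows = 24, n_cols = 24, smoothness = 2)
  cells <- which(st$mask)
  target <- cells[300]
  mu <- setNames(drop(stack_env(st, target)), names(st$layers))
  vs <- gen_virtual_species(st, mu, 0.4^2, 10, seed = 1, species_id = "v")
  expect_equal(vs$suitability$cells[which.max(vs$suitability$values)], target)
  expect_equal(max(vs$suitability$values), 1)   # exp(0) at the centroid cell
  # occurrences land on cell centers and are reproducible
  vs2 <- gen_virtual_species(st, mu, 0.4^2, 10, seed = 1, species_id = "v")
  expect_identical(vs$occurrences$points, vs2$occurrences$points)
})

test_that("occurrence sampling frequencies track the suitability surface", {
  st <- gen_raster_stack(17, n_vars = 2, n_rows = 12, n_cols = 12, smoothness = 1)
  cells <- which(st$mask)
  mu <- setNames(drop(stack_env(st, cells[40])), names(st$layers))
  vs <- gen_virtual_species(st, mu, 1, 10000, seed = 77, species_id = "v")
  p <- vs$suitability$values / sum(vs$suitability$values)
  idx <- cell_index(st$grid, vs$occurrences$points[, 1], vs$occurrences$points[, 2])
  obs <- tabulate(match(idx, vs$suitability$cells), nbins = length(cells))
  keep <- p * 10000 >= 5          # chi-square validity
  chi <- sum((obs[keep] - 10000 * p[keep])^2 / (10000 * p[keep]))
  expect_gt(stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("trait simulation honours the model covariance", {
  tr <- gen_tree(8, 13)
  expect_equal(unname(sim_traits(tr, "BM", list(z0 = 3, sigma2 = 0), seed = 1)[, 1]),
               rep(3, 8))
  # Monte-Carlo covariance of BM draws approaches sigma2 * C
  C <- vcv_from_tree(tr)
  X <- sim_traits(tr, "BM", list(z0 = 0, sigma2 = 1), n_traits = 2000, seed = 5)
  Chat <- tcrossprod(X) / 2000
  expect_lt(max(abs(Chat - C)), 5 * max(diag(C)) / sqrt(2000) * 3)
  # white draws are distributionally independent of tree shape
  trB <- gen_tree(8, 99)
  a <- as.vector(sim_traits(tr, "white", n_traits = 400, seed = 6))
  b <- as.vector(sim_traits(trB, "white", n_traits = 400, seed = 7))
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("planted couplings are recovered by the PLS", {
  # zero noise, one factor: rank-1 covariation with perfect correlation
  b0 <- gen_covarying_blocks(8, c(1, -0.5, 2), c(0.7, 1.2), noise = 0, seed = 3)
  res0 <- two_block_pls(b0$climate, b0$traits, scale = "covariance")
  expect_equal(res0$proportion[1], 1, tolerance = 1e-10)
  expect_equal(abs(res0$correlation[1]), 1, tolerance = 1e-10)
  # high signal: dimension-1 loading direction close to the planted one
  lc <- c(2, 1, -1, 0.5)
  bh <- gen_covarying_blocks(40, lc, c(1, 1, 1), noise = 0.2, seed = 8)
  rh <- two_block_pls(bh$climate, bh$traits, scale = "covariance")
  cos_sim <- abs(sum(rh$left_loadings[, 1] * lc / sqrt(sum(lc^2))))
  expect_gt(cos_sim, 0.9)
  expect_error(gen_covarying_blocks(8, c(0, 0), c(1, 1)), "degenerate")
})

test_that("pure-birth trees are ultrametric and seed-reproducible", {
  tr <- gen_tree(11, 4)
  expect_equal(ape::Ntip(tr), 11)
  d <- ape::node.depth.edgelength(tr)[1:11]
  expect_lt(diff(range(d)), 1e-9)
  expect_identical(ape::write.tree(gen_tree(11, 4)), ape::write.tree(tr))
  expect_error(gen_tree(1, 1), ">= 2")
})
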
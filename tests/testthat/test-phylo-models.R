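three_taxon_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

test_that("the phylogenetic VCV holds shared root-to-MRCA path lengths", {
  C <- vcv_from_tree(three_taxon_tree())
  expect_equal(C[c("A", "B", "C"), c("A", "B", "C")],
               matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(unname(vcv_from_tree(star)), diag(3))
  # ultrametric trees have a constant diagonal
  tr <- gen_tree(12, 5)
  expect_equal(diff(range(diag(vcv_from_tree(tr)))), 0, tolerance = 1e-9)
})

test_that("depth rescaling multiplies branches to the target depth", {
  tr <- three_taxon_tree()
  r <- rescale_depth(tr, 100)
  expect_equal(max(ape::node.depth.edgelength(r)), 100)
  expect_equal(r$edge.length, tr$edge.length * 50)
  expect_equal(rescale_depth(tr, 2)$edge.length, tr$edge.length)
  expect_equal(rescale_depth(rescale_depth(tr, 100), 1)$edge.length,
               rescale_depth(tr, 1)$edge.length)
})

test_that("the lambda transform scales only the off-diagonal", {
  C <- vcv_from_tree(three_taxon_tree())
  expect_equal(lambda_transform(C, 1), C)
  C0 <- lambda_transform(C, 0)
  expect_equal(C0[lower.tri(C0)], rep(0, 3))
  expect_equal(diag(C0), diag(C))
  expect_equal(lambda_transform(C, 0.5)["A", "B"], 0.5)
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("white-noise fits match the iid closed form", {
  tr <- three_taxon_tree()
  z <- c(A = 1, B = 2, C = 3)
  f <- fit_trait_model(z, tr, "white")
  expect_equal(f$z0, 2)
  expect_equal(f$sigma2, 2 / 3)
  expect_equal(f$logLik, -(3 / 2) * (log(2 * pi * 2 / 3) + 1),
               tolerance = 1e-10)
  expect_equal(f$logLik, -3.6486, tolerance = 1e-4)
})

test_that("BM log-likelihood matches a brute-force grid search", {
  tr <- three_taxon_tree()
  z <- c(A = 0.3, B = 1.1, C = -0.7)
  f <- fit_trait_model(z, tr, "BM")
  C <- vcv_from_tree(tr)[names(z), names(z)]
  ll <- function(z0, s2) {
    S <- s2 * C
    -0.5 * (3 * log(2 * pi) + determinant(S)$modulus[1] +
              t(z - z0) %*% solve(S, z - z0))
  }
  grid <- expand.grid(z0 = seq(-2, 2, length.out = 201),
                      s2 = seq(0.01, 3, length.out = 300))
  best <- max(mapply(ll, grid$z0, grid$s2))
  expect_equal(f$logLik, best, tolerance = 1e-4, ignore_attr = TRUE)
  expect_gte(f$logLik, best - 1e-8)
})

test_that("lambda endpoints recover the white and BM likelihoods", {
  tr <- gen_tree(16, 11)
  z <- setNames(sim_traits(tr, "BM", seed = 4)[, 1], tr$tip.label)
  C <- vcv_from_tree(tr)
  w <- fit_trait_model(z, tr, "white")
  b <- fit_trait_model(z, tr, "BM")
  l0 <- fit_trait_model(z, tr, "lambda", bounds = c(0, 1e-12))
  l1 <- fit_trait_model(z, tr, "lambda", bounds = c(1 - 1e-12, 1))
  # on an ultrametric tree lambda = 0 is the white model
  expect_equal(l0$logLik, w$logLik, tolerance = 1e-8)
  expect_equal(l1$logLik, b$logLik, tolerance = 1e-8)
})

test_that("log-likelihood is invariant to tip reordering", {
  tr <- gen_tree(10, 3)
  z <- setNames(sim_traits(tr, "BM", seed = 9)[, 1], tr$tip.label)
  f1 <- fit_trait_model(z, tr, "OU")
  f2 <- fit_trait_model(z[rev(names(z))], tr, "OU")
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-8)
})

test_that("every model family fits and AICc follows its formula", {
  tr <- gen_tree(12, 21)
  z <- setNames(sim_traits(tr, "BM", seed = 2)[, 1], tr$tip.label)
  fits <- lapply(c("white", "BM", "lambda", "OU", "EB", "delta", "kappa"),
                 function(m) fit_trait_model(z, tr, m))
  for (f in fits) {
    expect_true(is.finite(f$logLik))
    expect_gte(f$sigma2, 0)
    expect_equal(f$AICc,
                 -2 * f$logLik + 2 * f$k + 2 * f$k * (f$k + 1) / (f$n - f$k - 1))
  }
  tab <- model_select(fits)
  expect_equal(sum(tab$weight), 1)
  expect_true(all(diff(tab$AICc) >= 0))
})

test_that("AICc arithmetic and the small-sample guard are exact", {
  f <- structure(list(model = "BM", z0 = 0, sigma2 = 1, theta = NA,
                      logLik = -10, k = 2L, n = 11, AICc = NA), class = "model_fit")
  f$AICc <- -2 * f$logLik + 2 * f$k + 2 * f$k * (f$k + 1) / (f$n - f$k - 1)
  expect_equal(f$AICc, 25.5)
  small <- fit_trait_model(c(A = 1, B = 2, C = 3.5), three_taxon_tree(), "BM")
  expect_error(model_select(list(small)), "n <= k \\+ 1")
})
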
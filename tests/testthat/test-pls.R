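test_that("self-covariation gives unit latent correlations and proportions", {
  set.seed(7)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6), paste0("x", 1:4)))
  res <- two_block_pls(X, X)
  pos <- res$singular_values > 1e-10
  expect_equal(res$correlation[pos], rep(1, sum(pos)))
  expect_equal(sum(res$proportion), 1)
  expect_equal(res$rv, 1, tolerance = 1e-12)
})

test_that("singular values match a brute-force characteristic-polynomial oracle", {
  set.seed(12)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), c("x1", "x2")))
  Y <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), c("y1", "y2")))
  res <- two_block_pls(X, Y, scale = "correlation")
  # oracle: eigenvalues of R'R by the 2x2 characteristic polynomial
  Xs <- scale(X); Ys <- scale(Y)
  R <- t(Xs) %*% Ys / 5
  M <- t(R) %*% R
  tr <- M[1, 1] + M[2, 2]
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  lam <- sort((tr + c(1, -1) * sqrt(tr^2 - 4 * dt)) / 2, decreasing = TRUE)
  expect_equal(res$singular_values, sqrt(lam), tolerance = 1e-8)
  # singular values are non-increasing, loadings orthonormal
  expect_true(all(diff(res$singular_values) <= 1e-12))
  expect_equal(crossprod(res$left_loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the proportion identity rescales a reference dimension exactly", {
  set.seed(3)
  X <- matrix(rnorm(33), 11, 3, dimnames = list(paste0("s", 1:11), NULL))
  Y <- matrix(rnorm(33), 11, 3, dimnames = list(paste0("s", 1:11), NULL))
  res <- two_block_pls(X, Y)
  s <- res$singular_values
  expect_equal(pls_scaled_proportion(res$proportion[1], s[1], s[2]),
               res$proportion[2], tolerance = 1e-12)
})

test_that("Rv matches direct trace arithmetic and its boundary cases", {
  set.seed(21)
  X <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  Y <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  Xs <- scale(X); Ys <- scale(Y)
  S11 <- t(Xs) %*% Xs / 3; S22 <- t(Ys) %*% Ys / 3
  S12 <- t(Xs) %*% Ys / 3
  oracle <- sum(diag(S12 %*% t(S12))) /
    sqrt(sum(diag(S11 %*% S11)) * sum(diag(S22 %*% S22)))
  expect_equal(rv_coefficient(X, Y), oracle, tolerance = 1e-10)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  # residual blocks built orthogonal to X have zero cross-covariance
  A <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
  B0 <- scale(matrix(rnorm(12), 6, 2), scale = FALSE)
  B <- B0 - A %*% solve(crossprod(A), crossprod(A, B0))
  rownames(A) <- rownames(B) <- paste0("s", 1:6)
  expect_equal(rv_coefficient(A, B, scale = "covariance"), 0,
               tolerance = 1e-12)
})

test_that("row permutations give valid one-tailed p-values", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  Y <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  p <- pls_permutation(X, Y, nperm = 19, seed = 2)
  expect_true(all(p$p_rv >= 1 / 20 & p$p_rv <= 1))
  expect_true(all(p$p_singular >= 1 / 20 & p$p_singular <= 1))
  # a strongly planted shared factor drives p to the floor
  blocks <- gen_covarying_blocks(12, rep(1, 4), rep(1, 4), noise = 0.05,
                                 seed = 31)
  res <- two_block_pls(blocks$climate, blocks$traits, nperm = 99, seed = 3)
  expect_equal(res$p_singular[1], 1 / 100)
  expect_equal(res$p_rv, 1 / 100)
})

test_that("results are invariant to column order and bit-reproducible", {
  set.seed(9)
  X <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), paste0("x", 1:5)))
  Y <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("s", 1:8), paste0("y", 1:3)))
  a <- two_block_pls(X, Y)
  b <- two_block_pls(X[, c(3, 1, 5, 2, 4)], Y)
  expect_equal(a$singular_values, b$singular_values, tolerance = 1e-12)
  c_ <- two_block_pls(X, Y)
  expect_identical(a$left_loadings, c_$left_loadings)
  # sign convention: largest-magnitude loading entry positive per dimension
  for (d in seq_along(a$singular_values)) {
    w <- c(a$left_loadings[, d], a$right_loadings[, d])
    expect_gt(w[which.max(abs(w))], 0)
  }
})

test_that("dimension-1 loadings maximize cross-block covariance", {
  set.seed(44)
  X <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  Y <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("s", 1:12), NULL))
  res <- two_block_pls(X, Y)
  Xs <- scale(X); Ys <- scale(Y)
  R <- t(Xs) %*% Ys / 11
  for (k in 1:200) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    expect_lte(abs(t(u) %*% R %*% v), res$singular_values[1] + 1e-10)
  }
})

test_that("label mismatches and zero-variance columns are named errors", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  Y <- X; rownames(Y) <- paste0("t", 1:4)
  expect_error(two_block_pls(X, Y), "labels")
  Y2 <- X; Y2[, 2] <- 7; rownames(Y2) <- rownames(X)
  expect_error(two_block_pls(X, Y2), "zero-variance")
})
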
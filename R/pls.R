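# column-center (and scale, in correlation mode) a block
standardize_block <- function(X, scale_mode) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- if (scale_mode == "correlation") apply(X, 2, stats::sd) else
    rep(1, ncol(X))
  if (any(scl == 0))
    stop("two_block_pls: zero-variance column: ",
         paste(colnames(X)[scl == 0], collapse = ", "))
  sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
}

# deterministic sign convention: for each paired loading column, the
# largest-magnitude element of the concatenated [u; v] vector is made
# positive (ties broken by lowest index); u and v flip together so the
# decomposition is preserved.
fix_signs <- function(U, V) {
  for (d in seq_len(ncol(U))) {
    w <- c(U[, d], V[, d])
    j <- which.max(abs(w))
    if (w[j] < 0) { U[, d] <- -U[, d]; V[, d] <- -V[, d] }
  }
  list(U = U, V = V)
}

pls_core <- function(Xs, Ys) {
  n <- nrow(Xs)
  R <- crossprod(Xs, Ys) / (n - 1)
  sv <- svd(R)
  s <- fix_signs(sv$u, sv$v)
  scores_x <- Xs %*% s$U
  scores_y <- Ys %*% s$V
  r_d <- vapply(seq_along(sv$d), function(d) {
    if (stats::sd(scores_x[, d]) == 0 || stats::sd(scores_y[, d]) == 0)
      NA_real_
    else stats::cor(scores_x[, d], scores_y[, d])
  }, numeric(1))
  list(d = sv$d, U = s$U, V = s$V,
       scores_x = scores_x, scores_y = scores_y, r = r_d,
       proportion = sv$d^2 / sum(sv$d^2))
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-block covariance (or, by
#' default, correlation) matrix between two blocks of variables measured
#' on the same units, yielding paired latent dimensions that maximize
#' cross-block covariance.  Per dimension it reports the singular value,
#' the proportion of total squared singular values, and the Pearson
#' correlation of the paired latent scores; the Rv coefficient summarizes
#' overall covariation.  With `nperm > 0`, row-permutation p-values
#' (one-tailed upper) are attached for Rv, each singular value and each
#' latent correlation.
#'
#' @param X,Y numeric matrices with identical rownames in identical order
#'   (>= 3 rows); e.g. species-level climate means and morphology.
#' @param scale `"correlation"` (default: columns standardized to unit
#'   variance) or `"covariance"` (centered only).
#' @param nperm permutations for significance (0 = none; 1000 resolves
#'   p-values near 0.01 comfortably).
#' @param seed permutation seed.
#' @return Object of class `two_block_pls`: `singular_values`, `proportion`,
#'   `correlation`, `left_loadings`, `right_loadings`, `scores_x`,
#'   `scores_y`, `rv`, `n`, `scale`, and with permutations `p_rv`,
#'   `p_singular`, `p_correlation`, `nperm`, `seed`.
#' @export
two_block_pls <- function(X, Y, scale = c("correlation", "covariance"),
                          nperm = 0L, seed = 1L) {
  scale <- match.arg(scale)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y) || !identical(rownames(X), rownames(Y)))
    stop("two_block_pls: row labels of X and Y must match in order")
  if (nrow(X) < 3) stop("two_block_pls: need >= 3 rows")
  Xs <- standardize_block(X, scale)
  Ys <- standardize_block(Y, scale)
  core <- pls_core(Xs, Ys)
  out <- list(singular_values = core$d, proportion = core$proportion,
              correlation = core$r,
              left_loadings = structure(core$U, dimnames = list(colnames(X), NULL)),
              right_loadings = structure(core$V, dimnames = list(colnames(Y), NULL)),
              scores_x = structure(core$scores_x, dimnames = list(rownames(X), NULL)),
              scores_y = structure(core$scores_y, dimnames = list(rownames(Y), NULL)),
              rv = rv_coefficient(X, Y, scale = scale),
              n = nrow(X), scale = scale)
  if (nperm > 0) {
    p <- pls_permutation(X, Y, scale = scale, nperm = nperm, seed = seed)
    out <- c(out, p)
  }
  structure(out, class = "two_block_pls")
}

#' Rv coefficient of two blocks
#'
#' `Rv = tr(S12 S21) / sqrt(tr(S11 S11) tr(S22 S22))` over the centered
#' (or standardized) cross-product blocks: a multivariate generalization
#' of r-squared in `[0, 1]` summarizing how much of one block's
#' covariance structure is shared with the other.
#'
#' @inheritParams two_block_pls
#' @return Rv in `[0, 1]`.
#' @export
rv_coefficient <- function(X, Y, scale = c("correlation", "covariance")) {
  scale <- match.arg(scale)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("rv_coefficient: row counts differ")
  Xs <- standardize_block(X, scale)
  Ys <- standardize_block(Y, scale)
  n <- nrow(Xs)
  S11 <- crossprod(Xs) / (n - 1)
  S22 <- crossprod(Ys) / (n - 1)
  S12 <- crossprod(Xs, Ys) / (n - 1)
  denom <- sqrt(sum(S11 * S11) * sum(S22 * S22))
  if (denom == 0) stop("rv_coefficient: zero within-block trace")
  sum(S12^2) / denom   # tr(S12 S21) = sum of squared cross-covariances
}

#' Row-permutation significance for 2B-PLS statistics
#'
#' Permutes the rows of `Y` (`X` fixed; permutation `b` seeded
#' `seed + b`), recomputes Rv, the singular values and the latent
#' correlations, and returns one-tailed upper p-values
#' `(1 + #{perm >= observed}) / (nperm + 1)`.
#'
#' @inheritParams two_block_pls
#' @return list with `p_rv`, `p_singular`, `p_correlation`, `nperm`, `seed`.
#' @export
pls_permutation <- function(X, Y, scale = c("correlation", "covariance"),
                            nperm = 1000L, seed = 1L) {
  scale <- match.arg(scale)
  if (nperm < 1) stop("pls_permutation: nperm must be >= 1")
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xs <- standardize_block(X, scale)
  Ys <- standardize_block(Y, scale)
  obs <- pls_core(Xs, Ys)
  n <- nrow(Xs)
  rv_den <- sqrt(sum((crossprod(Xs) / (n - 1))^2) *
                 sum((crossprod(Ys) / (n - 1))^2))
  rv_of <- function(Yp) sum((crossprod(Xs, Yp) / (n - 1))^2) / rv_den
  obs_rv <- rv_of(Ys)
  cnt_rv <- 0L
  cnt_s <- integer(length(obs$d))
  cnt_r <- integer(length(obs$r))
  for (b in seq_len(nperm)) {
    Yp <- Ys[with_seed(seed + b, sample.int(n)), , drop = FALSE]
    perm <- pls_core(Xs, Yp)
    cnt_rv <- cnt_rv + (rv_of(Yp) >= obs_rv)
    cnt_s <- cnt_s + (perm$d >= obs$d)
    cnt_r <- cnt_r + ifelse(is.na(perm$r) | is.na(obs$r), 0L,
                            perm$r >= obs$r)
  }
  list(p_rv = (1 + cnt_rv) / (nperm + 1),
       p_singular = (1 + cnt_s) / (nperm + 1),
       p_correlation = (1 + cnt_r) / (nperm + 1),
       nperm = as.integer(nperm), seed = as.integer(seed))
}

#' Scale a covariance proportion from one dimension to another
#'
#' The per-dimension proportions of a 2B-PLS are `s_d^2 / sum_j s_j^2`,
#' so any two dimensions satisfy
#' `proportion_d = proportion_ref * (s_d / s_ref)^2` — a consistency
#' identity useful for checking reported tables that print only some
#' singular values.
#'
#' @param proportion_ref proportion of the reference dimension.
#' @param s_ref,s_d singular values of the reference and target dimensions.
#' @return implied proportion of the target dimension.
#' @export
pls_scaled_proportion <- function(proportion_ref, s_ref, s_d) {
  proportion_ref * (s_d / s_ref)^2
}
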
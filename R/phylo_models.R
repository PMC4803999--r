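#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @return symmetric labelled matrix.
#' @export
vcv_from_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("vcv_from_tree: tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("vcv_from_tree: negative branch length")
  ape::vcv.phylo(tree)
}

tree_depth <- function(tree) max(ape::node.depth.edgelength(tree))

#' Rescale a tree to a target root-to-tip depth
#'
#' Multiplies every branch by `target_depth / depth(tree)` (e.g. the
#' common convention of rescaling a dated tree to depth 100 before model
#' fitting).
#'
#' @param tree a `phylo`.
#' @param target_depth new maximum root-to-tip depth, > 0.
#' @return rescaled `phylo`.
#' @export
rescale_depth <- function(tree, target_depth) {
  d <- tree_depth(tree)
  if (d <= 0) stop("rescale_depth: tree depth is zero")
  if (target_depth <= 0) stop("rescale_depth: target depth must be > 0")
  tree$edge.length <- tree$edge.length * target_depth / d
  tree
}

#' Pagel's lambda transform of a phylogenetic VCV
#'
#' Multiplies off-diagonal entries by `lam` in `[0, 1]`, leaving the
#' diagonal unchanged: `lam = 1` is Brownian motion, `lam = 0` removes
#' all phylogenetic covariance.
#'
#' @param C phylogenetic VCV matrix.
#' @param lam lambda in `[0, 1]`.
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.finite(lam) || lam < 0 || lam > 1)
    stop("lambda_transform: lambda must be in [0, 1]")
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}

# C(theta) per evolutionary model; `tree` needed only for kappa.
transform_vcv <- function(C, model, theta, tree = NULL) {
  switch(model,
    white = diag(nrow(C)),
    BM = C,
    lambda = lambda_transform(C, theta),
    OU = {
      a <- theta
      Td <- max(diag(C))
      exp(-2 * a * (Td - C)) * (1 - exp(-2 * a * C)) / (2 * a)
    },
    EB = {
      if (theta >= 0) stop("transform_vcv: EB rate must be negative")
      (exp(theta * C) - 1) / theta
    },
    delta = {
      if (theta <= 0) stop("transform_vcv: delta must be > 0")
      C^theta
    },
    kappa = {
      if (theta < 0 || theta > 1) stop("transform_vcv: kappa must be in [0, 1]")
      tk <- tree
      tk$edge.length <- tk$edge.length^theta
      ape::vcv.phylo(tk)[rownames(C), colnames(C)]
    },
    stop("transform_vcv: unknown model ", model))
}

# ML multivariate-normal fit with mean z0*1 and covariance sigma2*Cmat;
# z0 (GLS mean) and sigma2 profiled in closed form.
gls_profile <- function(Cmat, z) {
  R <- tryCatch(chol(Cmat), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  n <- length(z)
  logdet <- 2 * sum(log(diag(R)))
  Ci <- chol2inv(R)
  one <- rep(1, n)
  z0 <- sum(Ci %*% z) / sum(Ci)
  r <- z - z0
  sigma2 <- drop(t(r) %*% Ci %*% r) / n
  if (sigma2 <= 0) sigma2 <- .Machine$double.eps
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  list(z0 = z0, sigma2 = sigma2, logLik = ll)
}

model_theta_bounds <- function(model, depth) {
  switch(model,
    lambda = c(0, 1),
    OU = c(1e-8 / depth, 50 / depth),
    EB = c(-10 / depth, -1e-8 / depth),
    delta = c(1e-6, 3),
    kappa = c(0, 1),
    NULL)
}

#' Fit a continuous-trait evolutionary model by maximum likelihood
#'
#' Models: `white` (iid species values, no phylogenetic covariance),
#' `BM` (Brownian motion), `lambda` (Pagel's lambda), `OU`
#' (Ornstein-Uhlenbeck, ultrametric trees), `EB` (early burst), `delta`
#' and `kappa`.  The ancestral mean `z0` and rate `sigma2` are profiled
#' in closed form (GLS); the single extra parameter, where present, is
#' optimized by bounded one-dimensional search (tolerance 1e-8) with the
#' domain endpoints also evaluated.  The likelihood is computed through a
#' Cholesky factorization and fails (rather than silently repairing) on
#' non-positive-definite covariances.
#'
#' @param trait named numeric vector; names must equal the tip labels.
#' @param tree rooted `phylo` with branch lengths; >= 3 tips (>= 4 for
#'   finite AICc of one-extra-parameter models).
#' @param model one of `"white"`, `"BM"`, `"lambda"`, `"OU"`, `"EB"`,
#'   `"delta"`, `"kappa"`.
#' @param bounds optional length-2 override of the parameter search
#'   interval.
#' @return Object of class `model_fit`: `model`, `z0`, `sigma2`, `theta`
#'   (NA for white/BM), `logLik`, `k`, `n`, `AICc`, `converged`.
#' @export
fit_trait_model <- function(trait, tree,
                            model = c("white", "BM", "lambda", "OU", "EB",
                                      "delta", "kappa"),
                            bounds = NULL) {
  model <- match.arg(model)
  if (is.null(names(trait)) || !setequal(names(trait), tree$tip.label))
    stop("fit_trait_model: trait names must match tip labels")
  z <- trait[tree$tip.label]
  n <- length(z)
  if (n < 3) stop("fit_trait_model: need >= 3 tips")
  C <- vcv_from_tree(tree)
  depth <- max(diag(C))
  if (model == "OU" &&
      diff(range(diag(C))) > 1e-6 * depth)
    stop("fit_trait_model: OU requires an ultrametric tree ",
         "(rescale or date the tree first)")
  k <- if (model %in% c("white", "BM")) 2L else 3L
  theta <- NA_real_
  converged <- TRUE
  if (model %in% c("white", "BM")) {
    Cm <- transform_vcv(C, model, NA, tree)
    fit <- gls_profile(Cm, z)
    if (is.null(fit)) stop("fit_trait_model: covariance not positive definite")
  } else {
    b <- bounds %||% model_theta_bounds(model, depth)
    obj <- function(th) {
      f <- tryCatch(gls_profile(transform_vcv(C, model, th, tree), z),
                    error = function(e) NULL)
      if (is.null(f)) -Inf else f$logLik
    }
    opt <- stats::optimize(obj, interval = b, maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, b)
    vals <- c(opt$objective, obj(b[1]), obj(b[2]))
    if (all(!is.finite(vals)))
      stop("fit_trait_model: covariance not positive definite over the ",
           model, " parameter domain")
    theta <- cand[which.max(vals)]
    fit <- gls_profile(transform_vcv(C, model, theta, tree), z)
  }
  aicc <- if (n - k - 1 > 0)
    -2 * fit$logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1) else Inf
  structure(list(model = model, z0 = fit$z0, sigma2 = fit$sigma2,
                 theta = theta, logLik = fit$logLik, k = k, n = n,
                 AICc = aicc, converged = converged),
            class = "model_fit")
}

#' Rank model fits by AICc with Akaike weights
#'
#' @param fits list of [fit_trait_model()] results on the same trait and
#'   tree.
#' @return data frame sorted by AICc ascending with columns `model`,
#'   `z0`, `sigma2`, `theta`, `logLik`, `k`, `AICc`, `delta_AICc`,
#'   `weight` (weights normalized to 1).
#' @export
model_select <- function(fits) {
  if (!length(fits)) stop("model_select: no fits")
  n <- unique(vapply(fits, function(f) f$n, numeric(1)))
  if (length(n) != 1) stop("model_select: fits are not on the same data")
  bad <- vapply(fits, function(f) f$n <= f$k + 1, logical(1))
  if (any(bad))
    stop("model_select: AICc undefined (n <= k + 1) for model ",
         paste(vapply(fits[bad], function(f) f$model, character(1)),
               collapse = ", "))
  df <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    z0 = vapply(fits, function(f) f$z0, numeric(1)),
    sigma2 = vapply(fits, function(f) f$sigma2, numeric(1)),
    theta = vapply(fits, function(f) f$theta, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    AICc = vapply(fits, function(f) f$AICc, numeric(1)),
    stringsAsFactors = FALSE)
  df$delta_AICc <- df$AICc - min(df$AICc)
  w <- exp(-0.5 * df$delta_AICc)
  df$weight <- w / sum(w)
  df[order(df$AICc), , drop = FALSE]
}
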
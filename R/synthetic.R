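# truncated moving-average smoothing of a matrix (box kernel of radius r
# applied along rows then columns; edges use the truncated window)
ma2d <- function(m, r) {
  if (r <= 0) return(m)
  smooth1 <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - r, 1)
    hi <- pmin(seq_len(n) + r, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Generate a stack of smooth, correlated environmental rasters
#'
#' Each layer is spatially smoothed seeded Gaussian noise standardized to
#' zero mean and unit variance over cells; layers are mixed with a shared
#' field so every pair approximates the target correlation
#' (`equicorrelation`; negative targets are feasible only for two
#' layers).
#'
#' @param seed RNG seed (the generator is a pure function of seed and
#'   parameters).
#' @param n_vars number of layers (named `bio1`, `bio2`, ...).
#' @param n_rows,n_cols grid dimensions (>= 8).
#' @param smoothness box-kernel radius in cells (>= 0).
#' @param inter_layer_corr target pairwise correlation, |r| < 1.
#' @param cell_size,origin_west,origin_south grid geometry (defaults give
#'   a plausible 0.05-degree grid).
#' @return A [raster_stack()].
#' @export
gen_raster_stack <- function(seed, n_vars = 6L, n_rows = 64L, n_cols = 64L,
                             smoothness = 3L, inter_layer_corr = 0.6,
                             cell_size = 0.05, origin_west = -105,
                             origin_south = 20) {
  if (n_rows < 8 || n_cols < 8) stop("gen_raster_stack: grid must be >= 8 x 8")
  if (smoothness < 0) stop("gen_raster_stack: smoothness must be >= 0")
  rho <- inter_layer_corr
  if (abs(rho) >= 1) stop("gen_raster_stack: |inter_layer_corr| must be < 1")
  if (rho < 0 && n_vars > 2)
    stop("gen_raster_stack: negative equicorrelation infeasible for > 2 layers")
  g <- grid_spec(n_rows, n_cols, cell_size, origin_west, origin_south)
  field <- function() {
    f <- ma2d(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols), smoothness)
    (f - mean(f)) / stats::sd(f)
  }
  layers <- with_seed(seed, {
    shared <- field()
    lapply(seq_len(n_vars), function(k) {
      own <- field()
      v <- if (rho >= 0) sqrt(rho) * shared + sqrt(1 - rho) * own
           else if (k == 1) shared else rho * shared + sqrt(1 - rho^2) * own
      v <- (v - mean(v)) / stats::sd(v)
      env_raster(paste0("bio", k), v, g)
    })
  })
  raster_stack(layers)
}

#' Generate a block-structured region-label raster
#'
#' Divides the grid into `blocks x blocks` rectangular regions labelled
#' 1..blocks^2 — a stand-in for an ecoregion map.
#'
#' @param grid a [grid_spec()].
#' @param blocks regions per side.
#' @return An [env_raster()] of integer labels named `region`.
#' @export
gen_region_raster <- function(grid, blocks = 3L) {
  ri <- ceiling(seq_len(grid$n_rows) / (grid$n_rows / blocks))
  ci <- ceiling(seq_len(grid$n_cols) / (grid$n_cols / blocks))
  env_raster("region", outer(ri, ci, function(a, b) (a - 1) * blocks + b), grid)
}

#' Generate a virtual species with a Gaussian response niche
#'
#' True suitability per cell is
#' `exp(-0.5 * (e - mu)' breadth^{-1} (e - mu))` of the cell environment
#' `e`; occurrences are drawn (with replacement) from valid cells with
#' probability proportional to suitability and placed at cell centers.
#'
#' @param stack a [raster_stack()].
#' @param mu niche centroid, named by (a subset of) stack layers.
#' @param breadth symmetric positive-definite niche breadth matrix (or a
#'   single variance reused for all variables).
#' @param n_occ number of occurrence points (>= 1).
#' @param seed RNG seed.
#' @param species_id label for the occurrence set.
#' @return Object of class `virtual_species`: `mu`, `breadth`,
#'   `suitability` (a raw-link `suitability_map` over valid cells),
#'   `occurrences`, `seed`.
#' @export
gen_virtual_species <- function(stack, mu, breadth, n_occ, seed,
                                species_id = "vsp") {
  if (n_occ < 1) stop("gen_virtual_species: n_occ must be >= 1")
  vars <- names(mu) %||% names(stack$layers)[seq_along(mu)]
  if (length(breadth) == 1) breadth <- diag(as.numeric(breadth), length(mu))
  ev <- eigen(breadth, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("gen_virtual_species: breadth must be positive definite")
  cells <- which(stack$mask)
  E <- stack_env(stack, cells, vars)
  d2 <- stats::mahalanobis(E, as.numeric(mu), breadth)
  suit <- exp(-0.5 * d2)
  if (sum(suit) == 0)
    stop("gen_virtual_species: suitability underflows to zero everywhere")
  draw <- with_seed(seed, sample(cells, n_occ, replace = TRUE,
                                 prob = suit / sum(suit)))
  ctr <- cell_centers(stack$grid, draw)
  occ <- occurrence_set(species_id, ctr[, "longitude"], ctr[, "latitude"])
  smap <- structure(list(grid = stack$grid, cells = cells, values = suit,
                         link = "true", species = species_id),
                    class = "suitability_map")
  structure(list(mu = mu, breadth = breadth, suitability = smap,
                 occurrences = occ, seed = as.integer(seed)),
            class = "virtual_species")
}

#' Simulate continuous traits on a tree
#'
#' One multivariate-normal draw per trait with mean `z0` and covariance
#' `sigma2 * C(theta)` under the chosen evolutionary model.
#'
#' @param tree a `phylo`.
#' @param model `"white"`, `"BM"`, `"lambda"` or `"OU"`.
#' @param params list with `z0`, `sigma2` and, for lambda/OU, `theta`.
#' @param n_traits number of independent traits.
#' @param seed RNG seed.
#' @return species x trait matrix (rownames = tip labels).
#' @export
sim_traits <- function(tree, model = c("white", "BM", "lambda", "OU"),
                       params = list(z0 = 0, sigma2 = 1, theta = NULL),
                       n_traits = 1L, seed = 1L) {
  model <- match.arg(model)
  z0 <- params$z0 %||% 0
  sigma2 <- params$sigma2 %||% 1
  if (!is.finite(sigma2) || sigma2 < 0) stop("sim_traits: sigma2 must be >= 0")
  C <- vcv_from_tree(tree)
  Cm <- transform_vcv(C, model, params$theta, tree)
  n <- nrow(Cm)
  out <- if (sigma2 == 0) {
    matrix(z0, n, n_traits)
  } else {
    L <- chol(sigma2 * Cm)
    z0 + t(L) %*% with_seed(seed, matrix(stats::rnorm(n * n_traits), n, n_traits))
  }
  dimnames(out) <- list(tree$tip.label, paste0("trait", seq_len(n_traits)))
  out
}

#' Generate paired climate/trait blocks with a planted shared factor
#'
#' `climate = latent %*% t(climate_loadings) + noise`, likewise for
#' traits: at zero noise the cross-block correlation matrix has rank
#' equal to the number of planted factors.
#'
#' @param n number of species (>= 4).
#' @param climate_loadings,trait_loadings loading matrices (variables x
#'   factors) or vectors (one factor); must not be all zero.
#' @param noise noise standard deviation added to both blocks.
#' @param seed RNG seed.
#' @return list with `climate`, `traits` (matrices with rownames
#'   `sp1..spn`), `latent`, `seed`.
#' @export
gen_covarying_blocks <- function(n, climate_loadings, trait_loadings,
                                 noise = 0.5, seed = 1L) {
  if (n < 4) stop("gen_covarying_blocks: need n >= 4")
  Lc <- as.matrix(climate_loadings)
  Lt <- as.matrix(trait_loadings)
  if (all(Lc == 0) || all(Lt == 0))
    stop("gen_covarying_blocks: degenerate (all-zero) loadings")
  if (ncol(Lc) != ncol(Lt))
    stop("gen_covarying_blocks: blocks must share the number of factors")
  k <- ncol(Lc)
  out <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * k), n, k)
    list(latent = Z,
         climate = Z %*% t(Lc) + noise * matrix(stats::rnorm(n * nrow(Lc)), n),
         traits = Z %*% t(Lt) + noise * matrix(stats::rnorm(n * nrow(Lt)), n))
  })
  sp <- paste0("sp", seq_len(n))
  rownames(out$climate) <- rownames(out$traits) <- sp
  colnames(out$climate) <- paste0("clim", seq_len(nrow(Lc)))
  colnames(out$traits) <- paste0("trait", seq_len(nrow(Lt)))
  c(out, list(seed = as.integer(seed)))
}

#' Generate a pure-birth ultrametric tree
#'
#' Unit speciation rate, no extinction; ultrametric by construction and
#' a pure function of its seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed RNG seed.
#' @return a `phylo`.
#' @export
gen_tree <- function(n_tips, seed) {
  if (n_tips < 2) stop("gen_tree: need >= 2 tips")
  with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
}
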
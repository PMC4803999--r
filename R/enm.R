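#' Background mask over a grid
#'
#' @param grid a [grid_spec()].
#' @param included logical matrix of included cells.
#' @return Object of class `background_mask`.
#' @export
background_mask <- function(grid, included) {
  if (!any(included)) stop("background_mask: no included cell")
  structure(list(grid = grid, included = included), class = "background_mask")
}

#' Background from occupied regions
#'
#' The available environment of a species is taken as the union of all
#' region cells whose integer label is occupied by at least one of its
#' localities (the ecoregion-based background design).  Points on
#' unlabelled (nodata) cells are ignored with a warning; it is an error
#' if no point falls in any labelled region.
#'
#' @param region_raster [env_raster()] of integer region labels.
#' @param occ an [occurrence_set()].
#' @return A [background_mask()].
#' @export
make_background <- function(region_raster, occ) {
  idx <- cell_index(region_raster$grid,
                    occ$points[, "longitude"], occ$points[, "latitude"])
  ok <- !is.na(idx) & region_raster$mask[pmax(idx, 1L)]
  ok[is.na(idx)] <- FALSE
  if (any(!ok))
    warning("make_background: ", sum(!ok),
            " point(s) outside labelled regions ignored (", occ$species_id, ")")
  if (!any(ok))
    stop("make_background: no occurrence of '", occ$species_id,
         "' falls inside a labelled region")
  labs <- unique(region_raster$values[idx[ok]])
  included <- region_raster$mask & matrix(region_raster$values %in% labs,
                                          nrow = region_raster$grid$n_rows)
  background_mask(region_raster$grid, included)
}

# great-circle distance in km (haversine, Earth radius 6371 km)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dphi <- (lat2 - lat1) * r / 2
  dlam <- (lon2 - lon1) * r / 2
  a <- sin(dphi)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlam)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Background as a great-circle buffer around localities
#'
#' Includes every cell whose center lies within `radius_km` of at least
#' one locality (haversine distance, Earth radius 6371 km), plus the
#' cells containing the localities themselves (so a zero radius yields
#' exactly the occupied cells).
#'
#' @param occ an [occurrence_set()].
#' @param radius_km buffer radius, km, >= 0 (the ecoregion-free design
#'   uses 100 km).
#' @param grid a [grid_spec()].
#' @param valid optional logical matrix; the mask is intersected with it.
#' @return A [background_mask()].
#' @export
buffer_background <- function(occ, radius_km, grid, valid = NULL) {
  if (!is.finite(radius_km) || radius_km < 0)
    stop("buffer_background: radius_km must be >= 0")
  ctr <- cell_centers(grid, seq_len(grid$n_rows * grid$n_cols))
  inc <- rep(FALSE, nrow(ctr))
  for (i in seq_len(nrow(occ$points))) {
    d <- haversine_km(occ$points[i, 1], occ$points[i, 2], ctr[, 1], ctr[, 2])
    inc <- inc | d <= radius_km
  }
  own <- cell_index(grid, occ$points[, "longitude"], occ$points[, "latitude"])
  inc[own[!is.na(own)]] <- TRUE
  included <- matrix(inc, nrow = grid$n_rows)
  if (!is.null(valid)) included <- included & valid
  if (!any(included)) stop("buffer_background: empty mask")
  background_mask(grid, included)
}

# --- maximum-entropy suitability model -------------------------------------

# linear + quadratic features of standardized variables
model_features <- function(env, center, scale) {
  Z <- sweep(sweep(as.matrix(env), 2, center, "-"), 2, scale, "/")
  F <- cbind(Z, Z^2)
  colnames(F) <- c(paste0(names(center), ".lin"), paste0(names(center), ".sq"))
  F
}

#' Fit a presence/background maximum-entropy suitability model
#'
#' A documented maximum-entropy model over background cells: linear and
#' quadratic features of variables standardized by background mean and
#' standard deviation, an L1 coefficient penalty, and a convex fit by
#' FISTA with backtracking.  The fitted raw output is an exponential
#' (Gibbs) probability distribution over the background whose feature
#' expectations are pulled toward the presence feature means.
#'
#' @param presence_env matrix of environmental values at presences
#'   (>= 2 rows).
#' @param background_env matrix of values at background cells (>= presence
#'   rows; same columns).
#' @param reg L1 regularization weight, >= 0; default `1/sqrt(n_presence)`
#'   (heavier shrinkage for sparse samples).
#' @param seed seed used only if the background exceeds `max_background`
#'   cells and is subsampled.
#' @param max_background background cells kept without subsampling
#'   (default 10000).
#' @param max_iter,tol convergence control: relative objective change
#'   below `tol` (default 1e-8) within `max_iter` (default 500)
#'   iterations, else an error carrying the final gradient norm.
#' @return Object of class `suitability_model`: `variables`, `center`,
#'   `scale`, `beta`, `reg`, `objective`, `iterations`.
#' @export
fit_suitability <- function(presence_env, background_env, reg = NULL,
                            seed = 1L, max_background = 10000L,
                            max_iter = 500L, tol = 1e-8) {
  P <- as.matrix(presence_env)
  B <- as.matrix(background_env)
  if (nrow(P) < 2) stop("fit_suitability: need >= 2 presence rows")
  if (nrow(B) < nrow(P))
    stop("fit_suitability: background must have at least as many rows as presences")
  if (is.null(colnames(P)) || !identical(colnames(P), colnames(B)))
    stop("fit_suitability: presence/background columns must match")
  if (nrow(B) > max_background) {
    keep <- with_seed(seed, sample.int(nrow(B), max_background))
    B <- B[keep, , drop = FALSE]
  }
  center <- colMeans(B)
  scale <- apply(B, 2, stats::sd)
  if (any(scale <= 0))
    stop("fit_suitability: zero background variance in: ",
         paste(colnames(B)[scale <= 0], collapse = ", "))
  reg <- reg %||% (1 / sqrt(nrow(P)))
  Fbg <- model_features(B, center, scale)
  tpr <- colMeans(model_features(P, center, scale))
  m <- ncol(Fbg)

  fsm <- function(b) {                        # smooth part: logZ - t'b
    eta <- drop(Fbg %*% b)
    mx <- max(eta)
    log(sum(exp(eta - mx))) + mx - sum(tpr * b)
  }
  gsm <- function(b) {
    eta <- drop(Fbg %*% b)
    w <- exp(eta - max(eta))
    drop(crossprod(Fbg, w / sum(w))) - tpr
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

  beta <- numeric(m); y <- beta; tk <- 1; L <- 1
  obj <- fsm(beta)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    g <- gsm(y); fy <- fsm(y)
    repeat {
      bnew <- soft(y - g / L, reg / L)
      d <- bnew - y
      if (fsm(bnew) <= fy + sum(g * d) + 0.5 * L * sum(d^2) + 1e-12) break
      L <- 2 * L
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- bnew + ((tk - 1) / tk1) * (bnew - beta)
    beta <- bnew; tk <- tk1
    obj_new <- fsm(beta) + reg * sum(abs(beta))
    if (abs(obj - obj_new) <= tol * max(1, abs(obj))) { converged <- TRUE; break }
    obj <- obj_new
  }
  if (!converged)
    stop(sprintf(
      "fit_suitability: no convergence after %d iterations (gradient norm %.3g)",
      max_iter, sqrt(sum(gsm(beta)^2))))
  structure(list(variables = colnames(B), center = center, scale = scale,
                 beta = stats::setNames(beta, colnames(Fbg)), reg = reg,
                 objective = obj, iterations = it),
            class = "suitability_model")
}

#' Project a suitability model onto a raster grid
#'
#' Raw link: the exponential of the linear predictor normalized to sum to
#' one over the background cells (a probability surface).  Logistic link:
#' the prevalence-`tau` transform `tau*s/(tau*s + 1 - tau)` of the
#' relative suitability `s` (raw value times the number of background
#' cells), which equals `tau` everywhere for a zero-coefficient model.
#'
#' @param model a [fit_suitability()] model.
#' @param stack a [raster_stack()] containing the model's variables.
#' @param mask a [background_mask()] on the same grid.
#' @param link `"raw"` or `"logistic"`.
#' @param tau logistic prevalence (default 0.5).
#' @param species optional species label carried on the map.
#' @return Object of class `suitability_map`: `grid`, `cells` (linear
#'   indices), `values`, `link`, `species`.
#' @export
project_suitability <- function(model, stack, mask,
                                link = c("logistic", "raw"), tau = 0.5,
                                species = NA_character_) {
  link <- match.arg(link)
  if (!grid_equal(stack$grid, mask$grid))
    stop("project_suitability: mask/stack grid mismatch")
  cells <- which(mask$included & stack$mask)
  if (!length(cells)) stop("project_suitability: empty projection extent")
  E <- stack_env(stack, cells, model$variables)
  F <- model_features(E, model$center, model$scale)
  eta <- drop(F %*% model$beta)
  q <- exp(eta - max(eta)); q <- q / sum(q)
  vals <- if (link == "raw") q else {
    s <- q * length(cells)
    tau * s / (tau * s + 1 - tau)
  }
  structure(list(grid = stack$grid, cells = cells, values = vals,
                 link = link, species = species),
            class = "suitability_map")
}

#' Rank-based AUC of presence versus background scores
#'
#' The probability that a random presence outscores a random background
#' point, ties counted one half (the Mann-Whitney statistic).
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
enm_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("enm_auc: empty score vector")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}
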
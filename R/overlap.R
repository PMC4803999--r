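#' Standardize a suitability surface to sum to one
#'
#' Suitability scores (e.g. logistic outputs) are divided by their total
#' over the analysis extent, giving a probability surface comparable
#' across species.
#'
#' @param x a `suitability_map` or numeric vector of cell values.
#' @return Same type as the input, with values summing to 1.
#' @export
standardize_surface <- function(x) {
  v <- if (inherits(x, "suitability_map")) x$values else x
  s <- sum(v)
  if (!is.finite(s) || s <= 0) stop("standardize_surface: surface sums to zero")
  if (inherits(x, "suitability_map")) {
    x$values <- v / s
    x$link <- paste0(x$link, "+standardized")
    x
  } else v / s
}

# values of two surfaces on a verified common cell set, each summing to 1
paired_surface_values <- function(p, q, tol = 1e-8) {
  if (inherits(p, "suitability_map") && inherits(q, "suitability_map")) {
    if (!grid_equal(p$grid, q$grid) || !identical(p$cells, q$cells))
      stop("overlap: surfaces are not on a common cell set")
    p <- p$values; q <- q$values
  } else {
    p <- as.numeric(if (inherits(p, "suitability_map")) p$values else p)
    q <- as.numeric(if (inherits(q, "suitability_map")) q$values else q)
    if (length(p) != length(q))
      stop("overlap: surfaces are not on a common cell set")
  }
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol)
    stop("overlap: surfaces must be standardized to sum to 1")
  list(p = p, q = q)
}

#' Hellinger distance between two probability surfaces
#'
#' `H = sqrt(sum((sqrt(p) - sqrt(q))^2))`, in `[0, sqrt(2)]`.
#'
#' @param p,q standardized surfaces on a common cell set.
#' @return H.
#' @export
hellinger_distance <- function(p, q) {
  v <- paired_surface_values(p, q)
  sqrt(sum((sqrt(v$p) - sqrt(v$q))^2))
}

#' Warren's I niche-overlap statistic
#'
#' `I = 1 - H^2/2`, ranging 0 (disjoint) to 1 (identical).
#' @inheritParams hellinger_distance
#' @export
warren_I <- function(p, q) 1 - hellinger_distance(p, q)^2 / 2

#' Schoener's D niche-overlap statistic
#'
#' `D = 1 - 0.5 * sum(|p - q|)`.
#' @inheritParams hellinger_distance
#' @export
schoener_D <- function(p, q) {
  v <- paired_surface_values(p, q)
  1 - 0.5 * sum(abs(v$p - v$q))
}

#' All three overlap statistics at once
#' @inheritParams hellinger_distance
#' @return list with `D`, `I`, `H`.
#' @export
overlap_stats <- function(p, q) {
  H <- hellinger_distance(p, q)
  list(D = schoener_D(p, q), I = 1 - H^2 / 2, H = H)
}

#' Classify a directed overlap comparison
#'
#' Two-tailed randomization call at level `alpha`: `divergent` when the
#' observed overlap sits in the lower `alpha/2` tail of the null
#' (overlap lower than expected given the available environment),
#' `conserved` in the upper tail, else `non_significant`.  Empirical
#' p-values use the add-one rule and can never be zero; when `nreps` is
#' too small for `1/(nreps+1)` to reach `alpha/2` the call is always
#' `non_significant` (an explicit power floor).
#'
#' @param observed observed overlap statistic.
#' @param null numeric vector of null replicates (nonempty).
#' @param alpha two-tailed level (default 0.05).
#' @return `"divergent"`, `"conserved"` or `"non_significant"`.
#' @export
classify_overlap <- function(observed, null, alpha = 0.05) {
  if (!length(null)) stop("classify_overlap: empty null")
  n <- length(null)
  p_low <- (1 + sum(null <= observed)) / (n + 1)
  p_high <- (1 + sum(null >= observed)) / (n + 1)
  if (p_low <= alpha / 2) "divergent"
  else if (p_high <= alpha / 2) "conserved"
  else "non_significant"
}

#' Background randomization test of niche similarity
#'
#' Fits and projects suitability models for a focal and a background
#' species, standardizes both over the union of their backgrounds, and
#' compares the observed Warren's I to a null built by refitting the
#' background species' model from points drawn uniformly from its own
#' background mask (`nreps` replicates, replicate `r` seeded `seed + r`).
#' Detects overlap significantly lower (divergence) or higher
#' (conservatism) than expected given the available environment.
#'
#' @param occ_focal,occ_other [occurrence_set()]s.
#' @param mask_focal,mask_other [background_mask()]s.
#' @param stack a [raster_stack()].
#' @param nreps null replicates (default 100).
#' @param alpha two-tailed level (default 0.05).
#' @param seed master seed.
#' @param link projection link fed to the overlap ("logistic" default,
#'   then re-standardized; "raw" supported).
#' @param reg optional L1 weight passed to [fit_suitability()].
#' @return Object of class `background_test_result`: `focal_species`,
#'   `background_species`, `observed_I`, `null_I`, `p_low`, `p_high`,
#'   `alpha`, `classification`, `seed`, `n_failed`.
#' @export
background_test <- function(occ_focal, mask_focal, occ_other, mask_other,
                            stack, nreps = 100L, alpha = 0.05, seed = 1L,
                            link = "logistic", reg = NULL) {
  if (nreps < 1) stop("background_test: nreps must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("background_test: alpha must be in (0, 1)")
  union_mask <- background_mask(stack$grid, mask_focal$included | mask_other$included)
  bg_focal <- stack_env(stack, which(mask_focal$included & stack$mask))
  bg_other_cells <- which(mask_other$included & stack$mask)
  bg_other <- stack_env(stack, bg_other_cells)

  fit_project <- function(env_presence, env_background) {
    m <- fit_suitability(env_presence, env_background, reg = reg, seed = seed)
    standardize_surface(project_suitability(m, stack, union_mask, link = link))
  }
  surf_focal <- fit_project(as.matrix(extract_env(occ_focal, stack)), bg_focal)
  surf_other <- fit_project(as.matrix(extract_env(occ_other, stack)), bg_other)
  observed <- warren_I(surf_focal, surf_other)

  n_other <- nrow(occ_other$points)
  null_I <- rep(NA_real_, nreps)
  for (r in seq_len(nreps)) {
    cells <- with_seed(seed + r,
                       sample(bg_other_cells, n_other, replace = TRUE))
    null_I[r] <- tryCatch(
      warren_I(surf_focal, fit_project(stack_env(stack, cells), bg_other)),
      error = function(e) NA_real_)
  }
  failed <- sum(is.na(null_I))
  if (failed > 0.2 * nreps)
    stop("background_test: degenerate model fits in ", failed, " of ", nreps,
         " null replicates")
  null_I <- null_I[!is.na(null_I)]
  n <- length(null_I)
  p_low <- (1 + sum(null_I <= observed)) / (n + 1)
  p_high <- (1 + sum(null_I >= observed)) / (n + 1)
  structure(list(focal_species = occ_focal$species_id,
                 background_species = occ_other$species_id,
                 observed_I = observed, null_I = null_I,
                 p_low = p_low, p_high = p_high, alpha = alpha,
                 classification = classify_overlap(observed, null_I, alpha),
                 seed = as.integer(seed), n_failed = failed),
            class = "background_test_result")
}

#' Directed classification matrix and per-species counts
#'
#' Assembles background-test results for all ordered species pairs
#' (`n` species give `n*(n-1)` directed comparisons) into a matrix of
#' calls (rows = focal species, columns = background species, entries
#' `D`/`C`/`NS`) plus per-species counts over the `2*(n-1)` directed
#' comparisons each species takes part in.
#'
#' @param results list of `background_test_result` objects covering every
#'   ordered pair.
#' @param species optional species order; default: order of first
#'   appearance as focal species.
#' @return list with `matrix` (character), `counts` (data frame with
#'   columns species, conserved, divergent, non_significant) and
#'   `n_comparisons`.
#' @export
overlap_matrix <- function(results, species = NULL) {
  foc <- vapply(results, function(r) r$focal_species, character(1))
  bgs <- vapply(results, function(r) r$background_species, character(1))
  cls <- vapply(results, function(r) r$classification, character(1))
  species <- species %||% unique(foc)
  n <- length(species)
  m <- matrix(NA_character_, n, n, dimnames = list(focal = species,
                                                   background = species))
  code <- c(divergent = "D", conserved = "C", non_significant = "NS")
  for (k in seq_along(results)) m[foc[k], bgs[k]] <- code[[cls[k]]]
  need <- which(is.na(m) & diag(n) != 1, arr.ind = TRUE)
  if (nrow(need))
    stop("overlap_matrix: missing result for pair ",
         species[need[1, 1]], " vs ", species[need[1, 2]])
  counts <- data.frame(species = species,
                       conserved = 0L, divergent = 0L, non_significant = 0L,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    inv <- c(m[i, -i], m[-i, i])
    counts$conserved[i] <- sum(inv == "C")
    counts$divergent[i] <- sum(inv == "D")
    counts$non_significant[i] <- sum(inv == "NS")
  }
  list(matrix = m, counts = counts, n_comparisons = n * (n - 1L))
}
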
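#' Euclidean distances between species in trait space
#'
#' @param traits species x trait numeric matrix with rownames; no
#'   missing values.
#' @param standardize standardize columns to unit variance first.
#' @return symmetric labelled distance matrix (class `matrix`).
#' @export
euclidean_distances <- function(traits, standardize = FALSE) {
  X <- as.matrix(traits)
  if (nrow(X) < 2) stop("euclidean_distances: need >= 2 species")
  if (anyNA(X)) stop("euclidean_distances: missing trait values")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("euclidean_distances: zero-variance column under standardization")
    X <- scale(X)
  }
  as.matrix(stats::dist(X))
}

#' Pairwise Hellinger distances between standardized suitability surfaces
#'
#' @param maps named list of standardized `suitability_map`s (or numeric
#'   vectors) on one common cell set.
#' @return symmetric labelled distance matrix; entries in `[0, sqrt(2)]`.
#' @export
hellinger_distances <- function(maps) {
  n <- length(maps)
  if (n < 2) stop("hellinger_distances: need >= 2 surfaces")
  labs <- names(maps) %||% vapply(maps, function(m)
    if (inherits(m, "suitability_map")) m$species else NA_character_,
    character(1))
  if (anyNA(labs)) stop("hellinger_distances: surfaces must be named")
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- hellinger_distance(maps[[i]], maps[[j]])
  D
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the strict lower-triangle entries, with
#' significance from jointly permuting the rows and columns of the
#' second matrix.  The first matrix can be log-transformed (the usual
#' axis for Hellinger niche distances); the default tail is upper (the
#' hypothesis of positive association between niche and morphological
#' divergence).
#'
#' @param d1,d2 symmetric labelled distance matrices over the same
#'   labels (`d2` is reordered to `d1`'s labels and is the permuted one).
#' @param nperm permutations (default 999).
#' @param tail `"upper"` (default) or `"lower"`.
#' @param transform `"raw"` or `"log"` (applied to `d1`'s off-diagonal
#'   entries, which must then be positive).
#' @param seed permutation seed (permutation `b` uses `seed + b`).
#' @param exhaustive enumerate all `n!` relabelings instead of sampling
#'   (n <= 8); p is then the exact tail fraction including the identity.
#' @return Object of class `mantel_result`: `r`, `r_squared`, `p`,
#'   `nperm`, `tail`, `transform`, `seed`.
#' @export
mantel_test <- function(d1, d2, nperm = 999L, tail = c("upper", "lower"),
                        transform = c("raw", "log"), seed = 1L,
                        exhaustive = FALSE) {
  tail <- match.arg(tail)
  transform <- match.arg(transform)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  labs <- rownames(d1)
  if (is.null(labs) || !setequal(labs, rownames(d2)))
    stop("mantel_test: matrices must share row labels")
  d2 <- d2[labs, labs]
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (transform == "log") {
    if (any(v1 <= 0))
      stop("mantel_test: log transform requires positive off-diagonal distances")
    v1 <- log(v1)
  }
  v2 <- d2[lt]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("mantel_test: zero variance in a distance triangle")
  r_obs <- stats::cor(v1, v2)
  hit <- function(r_perm)
    if (tail == "upper") r_perm >= r_obs else r_perm <= r_obs
  if (exhaustive) {
    if (n > 8) stop("mantel_test: exhaustive enumeration limited to n <= 8")
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(p) stats::cor(v1, d2[p, p][lt]))
    p_val <- mean(hit(r_all))
    nperm <- nrow(perms) - 1L
  } else {
    if (nperm < 1) stop("mantel_test: nperm must be >= 1")
    cnt <- 0L
    for (b in seq_len(nperm)) {
      p <- with_seed(seed + b, sample.int(n))
      cnt <- cnt + hit(stats::cor(v1, d2[p, p][lt]))
    }
    p_val <- (1 + cnt) / (nperm + 1)
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p = p_val,
                 nperm = as.integer(nperm), tail = tail,
                 transform = transform, seed = as.integer(seed)),
            class = "mantel_result")
}
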
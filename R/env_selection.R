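#' Extract environmental values at occurrence points
#'
#' Nearest-cell (point-in-cell) lookup, no interpolation.  Points outside
#' the grid bounding box are dropped with a warning; rows falling on a
#' nodata cell of any layer are dropped and recorded in the table's
#' provenance attributes.
#'
#' @param occ an [occurrence_set()].
#' @param stack a [raster_stack()].
#' @return A data frame (class `env_table`) with one column per layer and
#'   attributes `species_id`, `dropped_out_of_bounds`, `dropped_nodata`
#'   (original point indices) and `cells` (linear cell index per retained
#'   row).
#' @export
extract_env <- function(occ, stack) {
  idx <- cell_index(stack$grid, occ$points[, "longitude"], occ$points[, "latitude"])
  oob <- which(is.na(idx))
  if (length(oob))
    warning("extract_env: ", length(oob), " point(s) outside the grid dropped (",
            occ$species_id, ")")
  inb <- setdiff(seq_along(idx), oob)
  nodata <- inb[!stack$mask[idx[inb]]]
  keep <- setdiff(inb, nodata)
  if (!length(keep))
    stop("extract_env: no occurrence of '", occ$species_id,
         "' falls on a valid cell")
  env <- stack_env(stack, idx[keep])
  out <- as.data.frame(env)
  attr(out, "species_id") <- occ$species_id
  attr(out, "dropped_out_of_bounds") <- oob
  attr(out, "dropped_nodata") <- nodata
  attr(out, "cells") <- idx[keep]
  class(out) <- c("env_table", class(out))
  out
}

#' Reduce collinear variables by a pairwise r-squared rule
#'
#' Builds a graph with an edge wherever the pairwise Pearson r^2 exceeds
#' `threshold_r2`, takes connected components as clusters of redundant
#' variables, and retains the highest-priority member of each cluster.
#' The retained set then has all pairwise r^2 at or below the threshold.
#'
#' @param table data frame or matrix of environmental values (rows =
#'   observations, >= 3).
#' @param threshold_r2 r-squared threshold in (0, 1); default 0.75.
#' @param priority character vector ranking variables from most to least
#'   preferred representative; defaults to input column order.  Mirrors
#'   an expert's choice of which correlated variable to keep.
#' @return Object of class `variable_selection`: `retained` (in input
#'   column order), `clusters`, `threshold_r2`, `priority`.
#' @export
correlation_filter <- function(table, threshold_r2 = 0.75, priority = NULL) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("correlation_filter: table must be numeric")
  if (nrow(X) < 3) stop("correlation_filter: need at least 3 rows")
  if (!is.finite(threshold_r2) || threshold_r2 <= 0 || threshold_r2 >= 1)
    stop("correlation_filter: threshold_r2 must be in (0, 1)")
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("correlation_filter: zero-variance column: ",
         paste(vars[sds == 0], collapse = ", "))
  priority <- priority %||% vars
  if (!all(vars %in% priority))
    stop("correlation_filter: priority ranking must cover all variables")
  r2 <- stats::cor(X)^2
  adj <- r2 > threshold_r2
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(vars, comp)
  retained <- vapply(clusters, function(cl) cl[which.min(match(cl, priority))],
                     character(1))
  retained <- vars[vars %in% retained]    # input column order
  structure(list(retained = retained, clusters = unname(clusters),
                 threshold_r2 = threshold_r2, priority = priority),
            class = "variable_selection")
}

#' Species-level means of environmental variables
#'
#' @param tables named list of `env_table` objects (one per species).
#' @param variables variable names to average; default: columns of the
#'   first table.  Every variable must be present for every species.
#' @return species x variable numeric matrix, rows in input species order.
#' @export
species_env_means <- function(tables, variables = NULL) {
  if (!length(tables)) stop("species_env_means: no tables given")
  variables <- variables %||% colnames(tables[[1]])
  sp <- names(tables) %||% vapply(tables, function(t) attr(t, "species_id"),
                                  character(1))
  out <- matrix(NA_real_, nrow = length(tables), ncol = length(variables),
                dimnames = list(sp, variables))
  for (i in seq_along(tables)) {
    t <- tables[[i]]
    if (!nrow(t)) stop("species_env_means: empty table for species ", sp[i])
    miss <- setdiff(variables, colnames(t))
    if (length(miss))
      stop("species_env_means: variable(s) absent for species ", sp[i], ": ",
           paste(miss, collapse = ", "))
    out[i, ] <- colMeans(as.matrix(t[, variables, drop = FALSE]))
  }
  out
}

#' Read a species-by-trait table from CSV
#'
#' First column = species labels (must be unique); remaining columns are
#' numeric traits.  Missing values are a load-time error unless
#' `impute_mean = TRUE`, in which case missing cells are replaced by the
#' per-column mean (with a warning).
#'
#' @param path CSV file path.
#' @param impute_mean impute missing cells with column means.
#' @return numeric matrix with species rownames.
#' @export
read_traits <- function(path, impute_mean = FALSE) {
  if (!file.exists(path)) stop("read_traits: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_traits: need species column plus >= 1 trait")
  sp <- as.character(df[[1]])
  if (anyDuplicated(sp)) stop("read_traits: duplicate species label(s)")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- sp
  if (anyNA(X)) {
    if (!impute_mean)
      stop("read_traits: missing trait value(s); set impute_mean = TRUE ",
           "to impute per-column means")
    warning("read_traits: imputing ", sum(is.na(X)), " missing cell(s) ",
            "with column means")
    for (j in seq_len(ncol(X)))
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
  }
  X
}
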
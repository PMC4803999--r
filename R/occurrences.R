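#' Locality records for one species
#'
#' @param species_id species label.
#' @param longitude,latitude numeric vectors, decimal degrees.
#' @return Object of class `occurrence_set` with `species_id` and a
#'   two-column `points` matrix.  Duplicate points are permitted but
#'   counted in the `n_duplicated` field.
#' @export
occurrence_set <- function(species_id, longitude, latitude) {
  if (length(longitude) != length(latitude))
    stop("occurrence_set: longitude and latitude lengths differ")
  if (!length(longitude)) stop("occurrence_set: at least one point required")
  bad <- which(!is.finite(longitude) | longitude < -180 | longitude > 180)
  if (length(bad))
    stop("occurrence_set: longitude out of [-180, 180] at point ", bad[1])
  bad <- which(!is.finite(latitude) | latitude < -90 | latitude > 90)
  if (length(bad))
    stop("occurrence_set: latitude out of [-90, 90] at point ", bad[1])
  pts <- cbind(longitude = as.numeric(longitude), latitude = as.numeric(latitude))
  structure(list(species_id = as.character(species_id), points = pts,
                 n_duplicated = sum(duplicated(pts))),
            class = "occurrence_set")
}

#' Read occurrence records from CSV
#'
#' Expects a header with columns `species`, `longitude`, `latitude`.
#' Returns one [occurrence_set()] per distinct species, in order of first
#' appearance, with row order preserved within species.  Out-of-range
#' coordinates are a load-time error naming the offending data row;
#' duplicated rows are kept with a warning.
#'
#' @param path CSV file path.
#' @return Named list of `occurrence_set` objects.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("read_occurrences: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_occurrences: missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("read_occurrences: file contains no records")
  lon <- suppressWarnings(as.numeric(df$longitude))
  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(!is.finite(lon) | lon < -180 | lon > 180)
  if (length(bad))
    stop("read_occurrences: longitude out of [-180, 180] at row ", bad[1])
  bad <- which(!is.finite(lat) | lat < -90 | lat > 90)
  if (length(bad))
    stop("read_occurrences: latitude out of [-90, 90] at row ", bad[1])
  ndup <- sum(duplicated(df[need]))
  if (ndup > 0)
    warning("read_occurrences: ", ndup, " duplicated record(s) kept")
  species <- unique(df$species)
  out <- lapply(species, function(sp) {
    sel <- df$species == sp
    occurrence_set(sp, lon[sel], lat[sel])
  })
  names(out) <- species
  out
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin, validating wrapper over [ape::read.tree()].  Requires a single
#' tree with a branch length on every edge (error names the first
#' offending node), nonnegative lengths, and unique tip labels;
#' polytomies are preserved.
#'
#' @param path Newick file path.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("read_newick: file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("read_newick: parse failure: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("read_newick: no tree could be parsed")
  if (inherits(tr, "multiPhylo")) stop("read_newick: expected a single tree")
  if (is.null(tr$edge.length))
    stop("read_newick: tree has no branch lengths")
  bad <- which(!is.finite(tr$edge.length))
  if (length(bad)) {
    child <- tr$edge[bad[1], 2]
    lab <- if (child <= length(tr$tip.label)) tr$tip.label[child]
           else paste("internal node", child)
    stop("read_newick: missing branch length above ", lab)
  }
  if (any(tr$edge.length < 0))
    stop("read_newick: negative branch length")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup))
    stop("read_newick: duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  tr
}
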
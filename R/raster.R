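#' Grid geometry for a gridded environmental layer
#'
#' Cell values are cell-centered; `origin_west`/`origin_south` give the
#' outer corner of the south-west cell (the ESRI ASCII `xllcorner`
#' convention).  Row 1 of the value matrix is the northernmost row.
#'
#' @param n_rows,n_cols positive integers.
#' @param cell_size cell edge, decimal degrees, > 0.
#' @param origin_west,origin_south outer south-west corner, degrees.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, origin_west, origin_south) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L) stop("grid_spec: n_rows must be a positive integer")
  if (is.na(n_cols) || n_cols < 1L) stop("grid_spec: n_cols must be a positive integer")
  if (!is.finite(cell_size) || cell_size <= 0) stop("grid_spec: cell_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 cell_size = as.numeric(cell_size),
                 origin_west = as.numeric(origin_west),
                 origin_south = as.numeric(origin_south),
                 crs = "EPSG:4326"),
            class = "grid_spec")
}

#' Compare two grid specifications
#'
#' @param a,b `grid_spec` objects.
#' @param tol degree tolerance for the real-valued fields.
#' @return `TRUE` iff dimensions match and all real fields agree within `tol`.
#' @export
grid_equal <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    abs(a$origin_west - b$origin_west) <= tol &&
    abs(a$origin_south - b$origin_south) <= tol
}

#' A single named environmental raster layer
#'
#' @param name layer name.
#' @param values numeric matrix (`n_rows` x `n_cols`, row 1 = north);
#'   `NA` marks nodata cells.
#' @param grid a [grid_spec()].
#' @return Object of class `env_raster` with fields `name`, `grid`,
#'   `values` and logical `mask` (TRUE on valid cells).
#' @export
env_raster <- function(name, values, grid) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("env_raster: value matrix shape does not match grid (",
         grid$n_rows, "x", grid$n_cols, ")")
  mask <- is.finite(values)
  if (!any(mask)) stop("env_raster: layer '", name, "' has no valid cell")
  structure(list(name = as.character(name), grid = grid,
                 values = values, mask = mask),
            class = "env_raster")
}

# --- ESRI ASCII grid reader/writer -----------------------------------------

parse_ascii_header <- function(lines) {
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  known <- c(req, "nodata_value", "xllcenter", "yllcenter")
  hdr <- list(nodata_value = -9999)
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) != 2L || !tolower(tok[1]) %in% known) break
    key <- tolower(tok[1])
    if (key %in% c("xllcenter", "yllcenter"))
      stop("read_raster: header field '", key,
           "' (center registration) is not supported; use corner registration")
    val <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(val))
      stop("read_raster: malformed header field '", key, "': ", tok[2])
    hdr[[key]] <- val
    n_hdr <- n_hdr + 1L
  }
  missing <- setdiff(req, names(hdr))
  if (length(missing))
    stop("read_raster: missing header field(s): ", paste(missing, collapse = ", "))
  for (key in c("ncols", "nrows"))
    if (hdr[[key]] < 1 || hdr[[key]] != round(hdr[[key]]))
      stop("read_raster: malformed header field '", key, "': ", hdr[[key]])
  if (hdr$cellsize <= 0)
    stop("read_raster: malformed header field 'cellsize': ", hdr$cellsize)
  hdr$n_header_lines <- n_hdr
  hdr
}

#' Read a gridded raster layer
#'
#' Supported dialect: ESRI ASCII grid (`.asc`), corner-registered, with an
#' optional `NODATA_value` (default -9999).  GeoTIFF is recognised as a
#' dialect name but not implemented; inputs should be converted to ESRI
#' ASCII (e.g. `gdal_translate -of AAIGrid`).
#'
#' @param path file path.
#' @param dialect `"esri_ascii"` (default) or `"geotiff"` (errors).
#' @param name layer name; defaults to the file name without extension.
#' @return An [env_raster()].
#' @export
read_raster <- function(path, dialect = c("esri_ascii", "geotiff"), name = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "geotiff")
    stop("read_raster: the GeoTIFF dialect is not implemented in this build; ",
         "convert the layer to an ESRI ASCII grid")
  if (!file.exists(path)) stop("read_raster: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- parse_ascii_header(lines)
  vals <- suppressWarnings(as.numeric(scan(
    text = paste(lines[-seq_len(hdr$n_header_lines)], collapse = "\n"),
    what = numeric(), quiet = TRUE)))
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("read_raster: expected ", hdr$nrows * hdr$ncols, " values, found ",
         length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  if (all(is.na(m))) stop("read_raster: layer is entirely nodata")
  g <- grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
  env_raster(name %||% sub("\\.[^.]*$", "", basename(path)), m, g)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Values are formatted with `%.15g` so that a read-write-read cycle is
#' value-identical and a write-read-write cycle is byte-identical.
#'
#' @param layer an [env_raster()].
#' @param path output file.
#' @param nodata sentinel written for invalid cells.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  v <- layer$values
  v[!layer$mask] <- nodata
  hdr <- c(paste("ncols", g$n_cols), paste("nrows", g$n_rows),
           paste("xllcorner", sprintf("%.15g", g$origin_west)),
           paste("yllcorner", sprintf("%.15g", g$origin_south)),
           paste("cellsize", sprintf("%.15g", g$cell_size)),
           paste("NODATA_value", sprintf("%.15g", nodata)))
  rows <- apply(v, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Bundle co-registered layers into a stack
#'
#' All layers must share one grid (within 1e-9 degrees) and carry unique
#' names.  The stack's shared mask is the intersection of layer masks.
#'
#' @param layers list of [env_raster()] objects.
#' @return Object of class `raster_stack` with fields `layers` (named
#'   list), `grid`, `mask`.
#' @export
raster_stack <- function(layers) {
  if (!length(layers)) stop("raster_stack: no layers given")
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms))
    stop("raster_stack: duplicate layer name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  g <- layers[[1]]$grid
  for (l in layers[-1])
    if (!grid_equal(g, l$grid))
      stop("raster_stack: grid mismatch between layers '", layers[[1]]$name,
           "' and '", l$name, "'")
  mask <- Reduce(`&`, lapply(layers, function(l) l$mask))
  if (!any(mask)) stop("raster_stack: shared valid mask is empty")
  names(layers) <- nms
  structure(list(layers = layers, grid = g, mask = mask),
            class = "raster_stack")
}

# --- cell addressing --------------------------------------------------------

#' Linear cell index of lon/lat points
#'
#' Column-major (R matrix) linear index of the cell containing each
#' point; `NA` for points outside the grid bounding box.  Points exactly
#' on a cell edge belong to the cell to the north-west (floor
#' convention), so extraction is deterministic.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat coordinate vectors, degrees.
#' @return integer vector of linear cell indices.
#' @export
cell_index <- function(grid, lon, lat) {
  u <- (lon - grid$origin_west) / grid$cell_size
  ytop <- grid$origin_south + grid$n_rows * grid$cell_size
  v <- (ytop - lat) / grid$cell_size
  col0 <- floor(u)
  on_edge <- u == col0 & u > 0
  col0[on_edge] <- col0[on_edge] - 1       # edge -> west cell
  row0 <- floor(v)
  on_edge <- v == row0 & v > 0
  row0[on_edge] <- row0[on_edge] - 1       # edge -> north cell
  out <- row0 + 1 + col0 * grid$n_rows
  out[col0 < 0 | col0 >= grid$n_cols | row0 < 0 | row0 >= grid$n_rows |
        !is.finite(u) | !is.finite(v)] <- NA_integer_
  as.integer(out)
}

#' Cell-center coordinates of linear cell indices
#'
#' @param grid a [grid_spec()].
#' @param cells integer linear indices.
#' @return two-column matrix (`longitude`, `latitude`).
#' @export
cell_centers <- function(grid, cells) {
  row0 <- (cells - 1L) %% grid$n_rows
  col0 <- (cells - 1L) %/% grid$n_rows
  ytop <- grid$origin_south + grid$n_rows * grid$cell_size
  cbind(longitude = grid$origin_west + (col0 + 0.5) * grid$cell_size,
        latitude = ytop - (row0 + 0.5) * grid$cell_size)
}

#' Stack values at cells
#'
#' @param stack a [raster_stack()].
#' @param cells integer linear cell indices.
#' @param variables layer subset; default all layers.
#' @return cells x layers numeric matrix.
#' @export
stack_env <- function(stack, cells, variables = NULL) {
  variables <- variables %||% names(stack$layers)
  miss <- setdiff(variables, names(stack$layers))
  if (length(miss))
    stop("stack_env: variable(s) absent from stack: ", paste(miss, collapse = ", "))
  out <- vapply(variables, function(v) stack$layers[[v]]$values[cells],
                numeric(length(cells)))
  if (length(cells) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, variables))
  out
}
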
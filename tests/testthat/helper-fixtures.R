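# Small fixtures built in code, shared across test files.

# 3x3 one-degree grid anchored at the origin
toy_grid <- function(n_rows = 3L, n_cols = 3L, cell_size = 1, xll = 0, yll = 0) {
  grid_spec(n_rows, n_cols, cell_size, xll, yll)
}

toy_layer <- function(values = matrix(1:9, 3, 3, byrow = TRUE),
                      name = "bio1", grid = toy_grid()) {
  env_raster(name, values, grid)
}

# write an ESRI ASCII grid from a matrix, return the path
write_ascii_fixture <- function(values, path = tempfile(fileext = ".asc"),
                                cell_size = 1, xll = 0, yll = 0,
                                nodata = -9999) {
  hdr <- c(paste("ncols", ncol(values)), paste("nrows", nrow(values)),
           paste("xllcorner", xll), paste("yllcorner", yll),
           paste("cellsize", cell_size), paste("NODATA_value", nodata))
  rows <- apply(values, 1, paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  path
}

# occurrence CSV fixture
write_occ_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# small two-species virtual landscape used by ENM/overlap tests
toy_landscape <- function(seed = 7, n_rows = 20L, n_cols = 20L, n_vars = 2L,
                          smoothness = 2L, corr = 0.3) {
  gen_raster_stack(seed, n_vars = n_vars, n_rows = n_rows, n_cols = n_cols,
                   smoothness = smoothness, inter_layer_corr = corr)
}

# standardized random probability surface on k cells
random_surface <- function(k, seed) {
  standardize_surface(with_seed_test(seed, stats::runif(k)))
}

# seeded evaluation that does not disturb other tests' RNG
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
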
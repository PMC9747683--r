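# Grid / raster / stack containers. Values are stored as plain matrices
# (row 1 = northernmost row) with NA as the nodata mask; a grid_spec pins
# the matrix to WGS84 geographic coordinates.

#' Define a geographic grid
#'
#' A `grid_spec` anchors a rectangular array of cells to WGS84. Cells are
#' indexed from the north-west corner (row 1 = northernmost). Each cell
#' covers the half-open interval `[west + (c-1)*d, west + c*d)` in longitude
#' and `(north - r*d, north - (r-1)*d]` in latitude, where `d` is the cell
#' size in degrees; a point lying exactly on an east or south cell boundary
#' belongs to the next cell. Cell values refer to the whole cell and
#' coordinates are reported at cell centers.
#'
#' @param west Western edge of the grid (decimal degrees, WGS84).
#' @param north Northern edge of the grid (decimal degrees, WGS84).
#' @param cell_size Cell size in arc-minutes (2.5 is the conventional
#'   analysis resolution for regional bioclim stacks).
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(west, north, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1,
            n_rows == as.integer(n_rows), n_cols == as.integer(n_cols))
  structure(list(west = as.numeric(west), north = as.numeric(north),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, %.4g' cells, origin (%.6g W, %.6g N)\n",
              x$n_rows, x$n_cols, x$cell_size, x$west, x$north))
  invisible(x)
}

# cell size in decimal degrees
grid_deg <- function(grid) grid$cell_size / 60

grid_equal <- function(a, b, tol = 1e-9) {
  abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$cell_size - b$cell_size) < tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Map coordinates to grid cells
#'
#' Returns 1-based row/column indices for points, using the half-open cell
#' convention (east/south boundary points fall in the next cell). Points
#' outside the grid get NA indices.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors (decimal degrees).
#' @return A data.frame with columns `row`, `col`, and `cell` (linear index,
#'   column-major as used by R matrices).
#' @export
cell_index <- function(grid, lon, lat) {
  d <- grid_deg(grid)
  col <- floor((lon - grid$west) / d) + 1L
  row <- floor((grid$north - lat) / d) + 1L
  # a point exactly on the northern edge belongs to row 1
  row[lat == grid$north] <- 1L
  bad <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1L) * grid$n_rows + row))
}

#' Cell-center coordinates
#'
#' @param grid A [grid_spec()].
#' @param row,col Cell indices (1-based, row 1 northernmost).
#' @return data.frame with `lon`, `lat` of the cell centers.
#' @export
cell_center <- function(grid, row, col) {
  d <- grid_deg(grid)
  data.frame(lon = grid$west + (col - 0.5) * d,
             lat = grid$north - (row - 0.5) * d)
}

#' Create a raster
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix (`n_rows` x `n_cols`) or a single value to
#'   fill with; NA marks nodata cells.
#' @return An object of class `env_raster`.
#' @export
env_raster <- function(grid, values) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values must be an n_rows x n_cols matrix")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "env_raster")
}

#' @export
print.env_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("env_raster: %d x %d, %d valid cells, range [%.4g, %.4g]\n",
              x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Create an environmental stack
#'
#' A named set of grid-aligned layers for one period / climate model (GCM) /
#' scenario combination; the covariate space of the suitability model.
#'
#' @param grid Shared [grid_spec()].
#' @param layers Named list of value matrices (or `env_raster`s) sharing the
#'   grid; names like `Bio1`...`Bio19`, `elevation`.
#' @param period,gcm,scenario Optional labels.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, period = "current", gcm = "none",
                      scenario = "none") {
  stopifnot(inherits(grid, "grid_spec"), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique non-empty names")
  layers <- lapply(layers, function(l) {
    if (inherits(l, "env_raster")) {
      if (!grid_equal(l$grid, grid)) stop("all layers must share one grid")
      l <- l$values
    }
    l <- as.matrix(l)
    if (!all(dim(l) == c(grid$n_rows, grid$n_cols)))
      stop("layer dimensions do not match grid")
    storage.mode(l) <- "double"
    l
  })
  structure(list(grid = grid, layers = layers, period = period,
                 gcm = gcm, scenario = scenario), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack [%s/%s/%s]: %d layers (%s) on %d x %d grid\n",
              x$period, x$gcm, x$scenario, length(x$layers),
              paste(utils::head(names(x$layers), 6), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Extract one layer of a stack as a raster
#' @param stack An [env_stack()].
#' @param name Layer name.
#' @return An `env_raster`.
#' @export
stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) stop("no layer named '", name, "'")
  env_raster(stack$grid, stack$layers[[name]])
}

#' Extract covariate values at cells
#'
#' @param stack An [env_stack()].
#' @param cells Linear cell indices (column-major), e.g. from [cell_index()].
#' @param vars Layer names to extract (default all).
#' @return Numeric matrix, one row per cell, one column per layer.
#' @export
extract_env <- function(stack, cells, vars = names(stack$layers)) {
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss)) stop("missing layer(s): ", paste(miss, collapse = ", "))
  out <- vapply(vars, function(v) stack$layers[[v]][cells], numeric(length(cells)))
  out <- matrix(out, nrow = length(cells),
                dimnames = list(NULL, vars))
  out
}

#' Linear indices of cells valid in every layer
#' @param stack An [env_stack()].
#' @return Integer vector of column-major cell indices.
#' @export
valid_cells <- function(stack) {
  ok <- !is.na(stack$layers[[1]])
  for (l in stack$layers[-1]) ok <- ok & !is.na(l)
  which(ok)
}

## ---- ESRI ASCII grid I/O ----------------------------------------------

#' Write a raster as an ESRI ASCII grid (.asc)
#'
#' @param raster An [env_raster()].
#' @param path Output file path.
#' @param nodata Sentinel written for NA cells (default -9999).
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  d <- grid_deg(g)
  hdr <- c(sprintf("NCOLS %d", g$n_cols),
           sprintf("NROWS %d", g$n_rows),
           sprintf("XLLCORNER %.10g", g$west),
           sprintf("YLLCORNER %.10g", g$north - g$n_rows * d),
           sprintf("CELLSIZE %.10g", d),
           sprintf("NODATA_VALUE %.10g", nodata))
  v <- raster$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 9, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path File path.
#' @return An [env_raster()]; the nodata value becomes NA.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list(); i <- 1L
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) break
    key <- toupper(parts[1])
    if (!key %in% c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER",
                    "CELLSIZE", "NODATA_VALUE")) break
    hdr[[key]] <- as.numeric(parts[2]); i <- i + 1L
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields in ", path)
  nr <- as.integer(hdr$NROWS); nc <- as.integer(hdr$NCOLS)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, got ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$NODATA_VALUE)) m[m == hdr$NODATA_VALUE] <- NA_real_
  g <- grid_spec(west = hdr$XLLCORNER,
                 north = hdr$YLLCORNER + nr * hdr$CELLSIZE,
                 cell_size = hdr$CELLSIZE * 60, n_rows = nr, n_cols = nc)
  env_raster(g, m)
}

#' Write every layer of a stack as .asc files
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_stack_asc <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_asc(stack_layer(stack, nm), p)
    p
  }, character(1))
  paths
}

#' Read a directory of .asc files as a stack
#' @param dir Directory holding one .asc per layer (file name = layer name).
#' @param period,gcm,scenario Labels for the stack.
#' @return An [env_stack()].
#' @export
read_stack_asc <- function(dir, period = "current", gcm = "none",
                           scenario = "none") {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc files in ", dir)
  rasters <- lapply(files, read_asc)
  g <- rasters[[1]]$grid
  layers <- lapply(rasters, function(r) {
    if (!grid_equal(r$grid, g)) stop("layers in ", dir, " have mismatched grids")
    r$values
  })
  names(layers) <- sub("\\.asc$", "", basename(files))
  env_stack(g, layers, period = period, gcm = gcm, scenario = scenario)
}
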
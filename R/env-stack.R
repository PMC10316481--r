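#' Define a regular geographic grid
#'
#' A `grid_spec` describes a regular lon/lat raster grid in WGS84 degrees.
#' Cells are addressed row-major with cell `(1, 1)` at the north-west corner;
#' `origin_lon`/`origin_lat` give the outer (north-west) corner of that cell.
#' A point maps to the cell whose half-open interval
#' `[west, east) x (south, north]`... more precisely `[origin + (j-1)*size,
#' origin + j*size)` in longitude and the mirrored half-open interval in
#' latitude, contains it.
#'
#' @param n_rows,n_cols Cell counts (rows run north to south).
#' @param origin_lon,origin_lat North-west corner of the grid, degrees.
#' @param cell_size_deg Cell edge length in degrees.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_lon = 0, origin_lat = 0,
                      cell_size_deg = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_deg > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size_deg = cell_size_deg),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g deg, NW corner (%.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size_deg, x$origin_lon, x$origin_lat))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Map coordinates to grid cells
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors in degrees.
#' @return A tibble with columns `row`, `col`, `cell` (row-major index);
#'   `NA` for points outside the grid extent.
#' @export
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin_lon) / grid$cell_size_deg) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size_deg) + 1
  # points exactly on the southern/eastern outer edge belong to the last cell
  col[lon == grid$origin_lon + grid$n_cols * grid$cell_size_deg] <- grid$n_cols
  row[lat == grid$origin_lat - grid$n_rows * grid$cell_size_deg] <- grid$n_rows
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows |
    is.na(lon) | is.na(lat)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer((row - 1L) * grid$n_cols + col))
}

#' Cell centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param cells Optional integer cell indices; default all cells.
#' @return A tibble with `cell`, `row`, `col`, `lon`, `lat`.
#' @export
cell_centres <- function(grid, cells = seq_len(n_cells(grid))) {
  row <- (cells - 1L) %/% grid$n_cols + 1L
  col <- (cells - 1L) %% grid$n_cols + 1L
  tibble::tibble(
    cell = as.integer(cells), row = as.integer(row), col = as.integer(col),
    lon = grid$origin_lon + (col - 0.5) * grid$cell_size_deg,
    lat = grid$origin_lat - (row - 0.5) * grid$cell_size_deg)
}

#' Per-row cell area in square kilometres
#'
#' Cell area on the geographic grid with cosine-latitude weighting:
#' `(cell_size_deg * 111.3195)^2 * cos(latitude of the cell centre)`.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_rows * n_cols` (row-major).
#' @export
cell_area_km2 <- function(grid) {
  km_per_deg <- 111.3195
  lat <- cell_centres(grid)$lat
  (grid$cell_size_deg * km_per_deg)^2 * cos(lat * pi / 180)
}

#' Multi-layer environmental grid
#'
#' Bundles aligned raster layers sharing one [grid_spec()] and one nodata
#' mask. Values are stored as a cells-by-layers matrix in row-major cell
#' order.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix, `n_cells x n_layers`, or a named list of
#'   `n_rows x n_cols` matrices.
#' @param layer_names Unique layer labels (taken from `values` if named).
#' @param nodata_mask Logical vector, `TRUE` where no data (e.g. ocean).
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, values, layer_names = NULL, nodata_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.list(values)) {
    if (is.null(layer_names)) layer_names <- names(values)
    values <- vapply(values, function(m) as.vector(t(m)), numeric(n_cells(grid)))
  }
  values <- as.matrix(values)
  if (is.null(layer_names)) layer_names <- colnames(values)
  if (is.null(layer_names)) layer_names <- paste0("layer", seq_len(ncol(values)))
  if (anyDuplicated(layer_names)) stop("layer names must be unique")
  if (nrow(values) != n_cells(grid))
    stop("values must have one row per grid cell")
  colnames(values) <- layer_names
  if (is.null(nodata_mask)) nodata_mask <- rowSums(is.na(values)) > 0
  stopifnot(length(nodata_mask) == n_cells(grid))
  structure(list(grid = grid, values = values,
                 layer_names = layer_names,
                 nodata_mask = as.logical(nodata_mask)),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) [%s] on %d x %d grid, %d nodata cells\n",
              length(x$layer_names),
              paste(utils::head(x$layer_names, 5), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$nodata_mask)))
  invisible(x)
}

#' Extract one layer as a matrix
#'
#' @param env An [env_stack()].
#' @param layer Layer name or index.
#' @return An `n_rows x n_cols` numeric matrix (NA on nodata cells).
#' @export
layer_matrix <- function(env, layer = 1) {
  v <- env$values[, layer]
  v[env$nodata_mask] <- NA_real_
  matrix(v, env$grid$n_rows, env$grid$n_cols, byrow = TRUE)
}

#' @describeIn env_stack Long-format tibble of cell values.
#' @param x An `env_stack`.
#' @param ... Unused.
#' @method as_tibble env_stack
#' @export
as_tibble.env_stack <- function(x, ...) {
  cc <- cell_centres(x$grid)
  out <- dplyr::bind_cols(cc, tibble::as_tibble(x$values))
  out$nodata <- x$nodata_mask
  out
}

check_same_grid <- function(a, b) {
  ga <- if (inherits(a, "env_stack")) a$grid else a
  gb <- if (inherits(b, "env_stack")) b$grid else b
  if (!isTRUE(all.equal(unclass(ga), unclass(gb))))
    stop("grids are not aligned; all layers must share an identical grid_spec")
  invisible(TRUE)
}

# ---- ESRI ASCII grid I/O (plain-text raster interchange) --------------------

#' Write an environmental stack as ESRI ASCII grids
#'
#' One `.asc` file per layer, plus the shared header. ESRI ASCII is the
#' plain-text raster format understood by standard GIS tooling.
#'
#' @param env An [env_stack()].
#' @param dir Output directory (created if needed).
#' @param nodata_value Sentinel written for nodata cells.
#' @return Invisibly, the written file paths.
#' @export
write_env_stack <- function(env, dir, nodata_value = -9999) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- env$grid
  paths <- purrr::map_chr(env$layer_names, function(nm) {
    path <- file.path(dir, paste0(nm, ".asc"))
    v <- env$values[, nm]
    v[env$nodata_mask | is.na(v)] <- nodata_value
    m <- matrix(v, g$n_rows, g$n_cols, byrow = TRUE)
    hdr <- c(
      sprintf("ncols %d", g$n_cols),
      sprintf("nrows %d", g$n_rows),
      sprintf("xllcorner %.10g", g$origin_lon),
      sprintf("yllcorner %.10g", g$origin_lat - g$n_rows * g$cell_size_deg),
      sprintf("cellsize %.10g", g$cell_size_deg),
      sprintf("NODATA_value %.10g", nodata_value))
    writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
    path
  })
  invisible(paths)
}

read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else NA_real_
  m <- matrix(scan(path, skip = sum(keys %in% c(need, "nodata_value")),
                   quiet = TRUE),
              vals[["nrows"]], vals[["ncols"]], byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  list(matrix = m,
       grid = grid_spec(vals[["nrows"]], vals[["ncols"]],
                        origin_lon = vals[["xllcorner"]],
                        origin_lat = vals[["yllcorner"]] +
                          vals[["nrows"]] * vals[["cellsize"]],
                        cell_size_deg = vals[["cellsize"]]))
}

#' Read aligned ESRI ASCII grids into an environmental stack
#'
#' All files must share an identical grid (no on-the-fly resampling; a
#' mismatch is an error). The union of the per-layer nodata cells becomes the
#' stack's nodata mask.
#'
#' @param paths Character vector of `.asc` files, or a directory containing
#'   them.
#' @return An [env_stack()].
#' @export
read_env_stack <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.asc$", full.names = TRUE)
  if (length(paths) == 0) stop("no .asc files to read")
  layers <- purrr::map(paths, read_asc)
  grid <- layers[[1]]$grid
  purrr::walk(layers[-1], function(l) check_same_grid(grid, l$grid))
  vals <- vapply(layers, function(l) as.vector(t(l$matrix)),
                 numeric(n_cells(grid)))
  colnames(vals) <- sub("\\.asc$", "", basename(paths))
  env_stack(grid, vals, nodata_mask = rowSums(is.na(vals)) > 0)
}

# ---- collinearity pruning ---------------------------------------------------

#' Drop highly correlated layers
#'
#' Greedy single pass in priority order: a layer is kept unless its absolute
#' Pearson correlation with any already-kept layer (over cells with data)
#' exceeds `r_max`. Constant layers are dropped with a warning, correlation
#' being undefined for them.
#'
#' @param env An [env_stack()].
#' @param r_max Correlation threshold (default 0.80).
#' @param priority Layer names in decreasing priority; default input order.
#' @return The pruned `env_stack`; the decision log is in
#'   `attr(, "collinearity_log")`.
#' @export
drop_correlated <- function(env, r_max = 0.80, priority = NULL) {
  stopifnot(inherits(env, "env_stack"), length(env$layer_names) >= 2)
  if (is.null(priority)) priority <- env$layer_names
  stopifnot(setequal(priority, env$layer_names))
  v <- env$values[!env$nodata_mask, , drop = FALSE]
  sds <- apply(v, 2, stats::sd)
  log <- character()
  kept <- character()
  for (nm in priority) {
    if (is.na(sds[nm]) || sds[nm] == 0) {
      warning("layer '", nm, "' is constant; dropped (correlation undefined)")
      log <- c(log, sprintf("dropped %s: zero variance", nm))
      next
    }
    rs <- if (length(kept)) abs(stats::cor(v[, nm], v[, kept, drop = FALSE]))
          else numeric()
    if (length(rs) && any(rs > r_max)) {
      culprit <- kept[which.max(rs)]
      log <- c(log, sprintf("dropped %s: |r| = %.3f with %s > %.2f",
                            nm, max(rs), culprit, r_max))
    } else {
      kept <- c(kept, nm)
      log <- c(log, sprintf("kept %s", nm))
    }
  }
  if (length(kept) == 0) stop("all layers dropped; lower r_max or check data")
  kept <- env$layer_names[env$layer_names %in% kept]  # stable input order
  out <- env_stack(env$grid, env$values[, kept, drop = FALSE],
                   layer_names = kept, nodata_mask = env$nodata_mask)
  attr(out, "collinearity_log") <- log
  out
}

# ---- point extraction -------------------------------------------------------

#' Extract environmental values at occurrence points
#'
#' Containing-cell extraction: each record receives the values of the grid
#' cell containing it. Records falling outside the grid or on nodata cells
#' are dropped and logged.
#'
#' @param env An [env_stack()].
#' @param occ An occurrence table with `lon`/`lat` columns (e.g. an
#'   [occ_set]).
#' @return A tibble with the occurrence columns followed by one column per
#'   layer; the provenance log (if any) is carried in `attr(, "provenance")`.
#' @export
extract_env <- function(env, occ) {
  stopifnot(inherits(env, "env_stack"))
  idx <- cell_of(env$grid, occ$lon, occ$lat)
  outside <- is.na(idx$cell)
  nodata <- !outside & env$nodata_mask[idx$cell]
  keep <- !outside & !nodata
  if (!any(keep)) stop("no occurrence falls on a data cell")
  vals <- env$values[idx$cell[keep], , drop = FALSE]
  out <- dplyr::bind_cols(tibble::as_tibble(occ)[keep, ],
                          tibble::as_tibble(vals))
  prov <- c(attr(occ, "provenance"),
            sprintf("extract_env: %d outside grid dropped, %d on nodata dropped, %d retained",
                    sum(outside), sum(nodata), sum(keep)))
  attr(out, "provenance") <- prov
  out
}

#' Environment values of the data cells of a stack
#'
#' Convenience accessor used for backgrounds and MESS targets: the
#' cells-by-layers value matrix restricted to cells with data.
#'
#' @param env An [env_stack()].
#' @return A tibble of layer values, one row per non-nodata cell, with the
#'   cell index in `attr(, "cell")`.
#' @export
env_values <- function(env) {
  keep <- !env$nodata_mask
  out <- tibble::as_tibble(env$values[keep, , drop = FALSE])
  attr(out, "cell") <- which(keep)
  out
}
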
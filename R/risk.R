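#' Accumulated cost distance from occupied cells
#'
#' Least-cost-path distance from the nearest source cell over an
#' 8-neighbour lattice. Each cell's conductance is its habitat suitability
#' floored at `epsilon`; the cost of traversing the edge between neighbours
#' `i` and `j` is the reciprocal-mean `0.5 * (1/c_i + 1/c_j) * d`, with
#' `d = 1` for orthogonal and `sqrt(2)` for diagonal moves (cell units) --
#' the accumulated-cost semantics of transition-based GIS tooling. Nodata
#' cells, and cells whose floored conductance is not positive (possible only
#' with `epsilon = 0`, e.g. hard barriers), are untraversable; unreachable
#' cells get `Inf`.
#'
#' @param suitability A one-layer [env_stack()] or an `n_rows x n_cols`
#'   matrix (NA = nodata).
#' @param sources Source (occurrence) cells: integer cell indices, or a
#'   data frame with `lon`/`lat` when `suitability` is a stack.
#' @param epsilon Conductance floor (default 1e-3).
#' @return Numeric vector of accumulated costs, one per cell (row-major),
#'   with the grid in `attr(, "grid")` when available.
#' @export
accumulated_cost <- function(suitability, sources, epsilon = 1e-3) {
  parsed <- parse_layer(suitability)
  suit <- parsed$values; grid <- parsed$grid
  nr <- parsed$n_rows; ncl <- parsed$n_cols
  nc <- nr * ncl
  if (is.data.frame(sources)) {
    if (is.null(grid)) stop("lon/lat sources need an env_stack with a grid")
    sources <- cell_of(grid, sources$lon, sources$lat)$cell
  }
  sources <- unique(sources[!is.na(sources)])
  cond <- pmax(suit, epsilon)
  traversable <- !is.na(suit) & cond > 0
  if (!any(traversable[sources])) stop("no traversable source cell")
  sources <- sources[traversable[sources]]

  inv <- ifelse(traversable, 1 / cond, NA_real_)
  # undirected edges for the three unique forward shifts within rows/cols
  edge <- function(di, dj, d) {
    ri <- seq_len(nr); ci <- seq_len(ncl)
    ri_ok <- ri[ri + di <= nr & ri + di >= 1]
    ci_ok <- ci[ci + dj <= ncl & ci + dj >= 1]
    from <- as.vector(outer((ri_ok - 1) * ncl, ci_ok, `+`))
    to <- from + di * ncl + dj
    ok <- traversable[from] & traversable[to]
    cbind(from = from[ok], to = to[ok],
          w = 0.5 * (inv[from[ok]] + inv[to[ok]]) * d)
  }
  edges <- rbind(edge(0, 1, 1), edge(1, 0, 1),
                 edge(1, 1, sqrt(2)), edge(1, -1, sqrt(2)))
  super <- nc + 1L
  g <- igraph::make_empty_graph(n = super, directed = FALSE)
  g <- igraph::add_edges(g,
    t(cbind(rbind(edges[, 1:2], cbind(super, sources)))),
    weight = c(edges[, 3], rep(0, length(sources))))
  cost <- as.vector(igraph::distances(g, v = super, weights = igraph::E(g)$weight))[seq_len(nc)]
  cost[!traversable] <- Inf
  attr(cost, "grid") <- grid
  attr(cost, "dim_rc") <- c(nr, ncl)
  cost
}

parse_layer <- function(x) {
  if (inherits(x, "env_stack")) {
    v <- x$values[, 1]
    v[x$nodata_mask] <- NA_real_
    list(values = v, grid = x$grid, n_rows = x$grid$n_rows,
         n_cols = x$grid$n_cols)
  } else if (is.matrix(x)) {
    list(values = as.vector(t(x)), grid = NULL, n_rows = nrow(x),
         n_cols = ncol(x))
  } else stop("expected an env_stack or a matrix")
}

#' Invasion-risk surface from suitability and accumulated cost
#'
#' Accumulated cost is min-max rescaled to `[0, 1]` over the reachable data
#' cells; risk is `suitability * (1 - rescaled cost)`, itself min-max
#' rescaled to `[0, 1]`, so cells far away and hard to reach carry small
#' risk even when highly suitable, and the most invasible cell scores 1.
#' Unreachable cells get risk 0. Cells inside the presently occupied range
#' are kept in `risk` but blanked (NA) in `risk_future`, the future-spread
#' surface.
#'
#' @param suitability One-layer [env_stack()] or matrix.
#' @param cost Output of [accumulated_cost()] (or a conforming vector).
#' @param occupied_mask Optional logical per-cell mask of the presently
#'   occupied range (e.g. rasterized from [alpha_hull_range()]).
#' @return An object of class `risk_map` with per-cell `risk`, `risk_future`,
#'   `cost`, the mask, and the grid (if any).
#' @export
risk_map <- function(suitability, cost, occupied_mask = NULL) {
  parsed <- parse_layer(suitability)
  suit <- parsed$values
  stopifnot(length(cost) == length(suit))
  reachable <- is.finite(cost) & !is.na(suit)
  if (!any(reachable)) stop("no reachable cell")
  cr <- cost[reachable]
  scaled <- if (diff(range(cr)) == 0) rep(0, length(cr))
            else (cr - min(cr)) / diff(range(cr))
  risk <- rep(0, length(suit))
  risk[reachable] <- suit[reachable] * (1 - scaled)
  rr <- risk[reachable]
  if (diff(range(rr)) > 0)
    risk[reachable] <- (rr - min(rr)) / diff(range(rr))
  risk[is.na(suit)] <- NA_real_
  risk_future <- risk
  if (!is.null(occupied_mask)) {
    stopifnot(length(occupied_mask) == length(risk))
    risk_future[which(occupied_mask)] <- NA_real_
  }
  structure(list(risk = risk, risk_future = risk_future, cost = cost,
                 occupied_mask = occupied_mask, grid = parsed$grid,
                 n_rows = parsed$n_rows, n_cols = parsed$n_cols),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  r <- x$risk[!is.na(x$risk)]
  cat(sprintf("<risk_map> %d cells, risk in [%.3f, %.3f], %d occupied\n",
              length(r), min(r), max(r),
              if (is.null(x$occupied_mask)) 0L else sum(x$occupied_mask, na.rm = TRUE)))
  invisible(x)
}

#' @describeIn risk_map Long-format tibble of a risk surface.
#' @param x A `risk_map`.
#' @param ... Unused.
#' @method as_tibble risk_map
#' @export
as_tibble.risk_map <- function(x, ...) {
  base <- if (!is.null(x$grid)) cell_centres(x$grid)
          else tibble::tibble(cell = seq_along(x$risk))
  dplyr::bind_cols(base,
    tibble::tibble(risk = x$risk, risk_future = x$risk_future,
                   cost = as.vector(x$cost),
                   occupied = x$occupied_mask %||% rep(NA, length(x$risk))))
}

# ---- alpha hull -------------------------------------------------------------

km_per_deg <- 111.3195

# Equirectangular projection at a reference latitude; areas from it carry
# the cosine-latitude correction.
project_km <- function(lon, lat, lat_ref) {
  cbind(x = lon * km_per_deg * cos(lat_ref * pi / 180), y = lat * km_per_deg)
}

tri_area <- function(p1, p2, p3) {
  abs((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

#' Alpha-hull estimate of an occupied range
#'
#' Builds the Delaunay triangulation of the occurrence points and prunes it
#' by the `alpha` parameter. The default `"mean_edge"` dialect removes every
#' triangle having an edge longer than `alpha` times the mean Delaunay edge
#' length (the multiplier reading of the alpha-hull); the `"circumradius"`
#' dialect retains triangles whose circumradius is at most `alpha` (in
#' degrees), the alpha-shape reading used by some software. As `alpha` grows
#' the hull approaches the convex hull. Area is computed in km2 on a
#' cosine-latitude-corrected planar projection at the points' mean latitude.
#'
#' @param points Data frame with `lon`/`lat` (e.g. an [occ_set()]), or a
#'   two-column matrix.
#' @param alpha Pruning parameter (> 0); `Inf` gives the convex hull.
#' @param dialect `"mean_edge"` or `"circumradius"`.
#' @return An object of class `range_polygon`: the retained triangles
#'   (vertex indices into the deduplicated points), the points, `area_km2`,
#'   `alpha`, and `dialect`.
#' @export
alpha_hull_range <- function(points, alpha = 1.5,
                             dialect = c("mean_edge", "circumradius")) {
  dialect <- match.arg(dialect)
  stopifnot(alpha > 0)
  pts <- if (is.matrix(points)) tibble::tibble(lon = points[, 1],
                                               lat = points[, 2])
         else tibble::as_tibble(points)[, c("lon", "lat")]
  pts <- dplyr::distinct(pts)
  if (nrow(pts) < 3) stop("need at least 3 distinct points")
  tri <- tryCatch({
    dxy <- suppressMessages(deldir::deldir(pts$lon, pts$lat))
    deldir::triMat(dxy)
  }, error = function(e) NULL)
  if (!is.null(tri)) tri <- rbind(tri)   # a single triangle comes back bare
  if (is.null(tri) || nrow(tri) == 0)
    stop("no triangulation (points may be collinear)")
  elen <- function(i, j) sqrt((pts$lon[i] - pts$lon[j])^2 +
                              (pts$lat[i] - pts$lat[j])^2)
  e1 <- elen(tri[, 1], tri[, 2]); e2 <- elen(tri[, 2], tri[, 3])
  e3 <- elen(tri[, 3], tri[, 1])
  keep <- if (dialect == "mean_edge") {
    edges <- unique(rbind(t(apply(cbind(tri[, 1], tri[, 2]), 1, sort)),
                          t(apply(cbind(tri[, 2], tri[, 3]), 1, sort)),
                          t(apply(cbind(tri[, 3], tri[, 1]), 1, sort))))
    mean_edge <- mean(elen(edges[, 1], edges[, 2]))
    pmax(e1, e2, e3) <= alpha * mean_edge
  } else {
    # circumradius = abc / (4 * area), in degrees
    area_deg <- tri_area(cbind(pts$lon[tri[, 1]], pts$lat[tri[, 1]]),
                         cbind(pts$lon[tri[, 2]], pts$lat[tri[, 2]]),
                         cbind(pts$lon[tri[, 3]], pts$lat[tri[, 3]]))
    circum <- ifelse(area_deg > 0, e1 * e2 * e3 / (4 * area_deg), Inf)
    circum <= alpha
  }
  if (!any(keep))
    stop("alpha hull is empty after pruning; raise alpha")
  tri <- tri[keep, , drop = FALSE]
  lat_ref <- mean(pts$lat[unique(as.vector(tri))])
  pk <- project_km(pts$lon, pts$lat, lat_ref)
  area <- sum(tri_area(pk[tri[, 1], , drop = FALSE],
                       pk[tri[, 2], , drop = FALSE],
                       pk[tri[, 3], , drop = FALSE]))
  structure(list(triangles = tri, points = pts, area_km2 = area,
                 alpha = alpha, dialect = dialect, lat_ref = lat_ref),
            class = "range_polygon")
}

#' @export
print.range_polygon <- function(x, ...) {
  cat(sprintf("<range_polygon> alpha = %g (%s): %d triangles over %d points, %.0f km2\n",
              x$alpha, x$dialect, nrow(x$triangles), nrow(x$points),
              x$area_km2))
  invisible(x)
}

#' Rasterize a range polygon onto a grid
#'
#' Marks every cell whose centre lies inside (or on the boundary of) one of
#' the polygon's triangles.
#'
#' @param polygon A [alpha_hull_range()] result.
#' @param grid A [grid_spec()].
#' @return Logical vector, one element per cell (row-major).
#' @export
rasterize_range <- function(polygon, grid) {
  cc <- cell_centres(grid)
  inside <- rep(FALSE, nrow(cc))
  eps <- 1e-12
  for (t in seq_len(nrow(polygon$triangles))) {
    v <- polygon$triangles[t, ]
    x1 <- polygon$points$lon[v[1]]; y1 <- polygon$points$lat[v[1]]
    x2 <- polygon$points$lon[v[2]]; y2 <- polygon$points$lat[v[2]]
    x3 <- polygon$points$lon[v[3]]; y3 <- polygon$points$lat[v[3]]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < eps) next
    cand <- which(!inside &
                    cc$lon >= min(x1, x2, x3) - eps &
                    cc$lon <= max(x1, x2, x3) + eps &
                    cc$lat >= min(y1, y2, y3) - eps &
                    cc$lat <= max(y1, y2, y3) + eps)
    if (!length(cand)) next
    a <- ((y2 - y3) * (cc$lon[cand] - x3) + (x3 - x2) * (cc$lat[cand] - y3)) / det
    b <- ((y3 - y1) * (cc$lon[cand] - x3) + (x1 - x3) * (cc$lat[cand] - y3)) / det
    g <- 1 - a - b
    inside[cand[a >= -eps & b >= -eps & g >= -eps]] <- TRUE
  }
  inside
}

#' Write a range polygon as GeoJSON
#'
#' The retained triangles are written as a MultiPolygon (an exact, if
#' undissolved, representation of the hull).
#'
#' @param polygon A [alpha_hull_range()] result.
#' @param path Output `.geojson` path.
#' @return Invisibly, `path`.
#' @export
write_range_geojson <- function(polygon, path) {
  rings <- purrr::map(seq_len(nrow(polygon$triangles)), function(t) {
    v <- c(polygon$triangles[t, ], polygon$triangles[t, 1])
    list(purrr::map(v, function(i) c(polygon$points$lon[i],
                                     polygon$points$lat[i])))
  })
  gj <- list(type = "Feature",
             properties = list(alpha = polygon$alpha,
                               dialect = polygon$dialect,
                               area_km2 = polygon$area_km2),
             geometry = list(type = "MultiPolygon", coordinates = rings))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- area accounting --------------------------------------------------------

#' Percent difference between uninvaded and occupied areas
#'
#' `round(100 * uninvaded / occupied)`, the percentage that the not-yet-
#' invaded suitable habitat represents of the presently occupied range.
#' Undefined (NA) when the occupied area is zero.
#'
#' @param occupied_km2,uninvaded_km2 Areas in km2.
#' @return Integer-valued percentage (NA if `occupied_km2` is 0).
#' @export
pct_difference <- function(occupied_km2, uninvaded_km2) {
  ifelse(occupied_km2 > 0, round(100 * uninvaded_km2 / occupied_km2),
         NA_real_)
}

#' Present-range and uninvaded-habitat area summary
#'
#' The presently occupied area is the alpha-hull polygon's area; the
#' uninvaded area sums the cosine-latitude-corrected cell areas of suitable
#' cells outside the rasterized polygon. The percent difference is
#' `100 * uninvaded / occupied`, rounded to the nearest integer.
#'
#' @param present A [alpha_hull_range()] polygon of the present range.
#' @param suitable_mask Logical per-cell suitable-habitat mask (e.g. from
#'   [threshold_cumulative()]); NA treated as unsuitable.
#' @param grid The [grid_spec()] of `suitable_mask`.
#' @return A one-row tibble: `occupied_km2`, `uninvaded_km2`,
#'   `pct_difference`.
#' @export
range_area_summary <- function(present, suitable_mask, grid) {
  stopifnot(inherits(present, "range_polygon"), inherits(grid, "grid_spec"))
  stopifnot(length(suitable_mask) == n_cells(grid))
  occupied_cells <- rasterize_range(present, grid)
  areas <- cell_area_km2(grid)
  suitable <- !is.na(suitable_mask) & suitable_mask
  uninvaded <- sum(areas[suitable & !occupied_cells])
  occ <- present$area_km2
  if (occ == 0) message("zero occupied area; percent difference undefined")
  tibble::tibble(occupied_km2 = occ, uninvaded_km2 = uninvaded,
                 pct_difference = pct_difference(occ, uninvaded))
}

#' Published range-area accounting for Australia's six wild deer species
#'
#' Reported total areas (km2) presently occupied and of suitable but not yet
#' invaded habitat for the six deer species with established wild
#' populations in Australia (chital, fallow, hog, red, rusa, sambar), with
#' the percent difference the uninvaded habitat represents of the present
#' range. Bundled as reference input for the area-accounting arithmetic.
#'
#' @format A tibble with 6 rows: `species`, `present_km2`, `uninvaded_km2`,
#'   `pct_difference`.
#' @export
deer_range_areas <- tibble::tibble(
  species = c("chital", "fallow", "hog", "red", "rusa", "sambar"),
  present_km2 = c(10667, 654193, 6916, 262287, 25657, 101957),
  uninvaded_km2 = c(510957, 123655, 99806, 5188, 18668, 15953),
  pct_difference = c(4790, 19, 1443, 2, 73, 16))
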
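#' Occurrence sets with provenance
#'
#' An `occ_set` is a tibble of georeferenced presence records (columns
#' `species_id`, `lon`, `lat`, `uncertainty_m`, `source`) carrying a
#' provenance log: an ordered character vector of the filters applied and the
#' record counts they produced. Filtering verbs in this package keep record
#' order stable and never invent records.
#'
#' @param records A data frame with at least `lon` and `lat`.
#' @param provenance Character vector of log lines.
#' @return An object of classes `occ_set` and `tbl_df`.
#' @export
occ_set <- function(records, provenance = character()) {
  records <- tibble::as_tibble(records)
  for (col in c("species_id", "source"))
    if (!col %in% names(records)) records[[col]] <- NA_character_
  if (!"uncertainty_m" %in% names(records))
    records$uncertainty_m <- NA_real_
  stopifnot(all(c("lon", "lat") %in% names(records)))
  structure(records, provenance = provenance,
            class = c("occ_set", class(tibble::tibble())))
}

#' @export
print.occ_set <- function(x, ...) {
  cat(sprintf("<occ_set> %d records (%s)\n", nrow(x),
              paste(unique(stats::na.omit(x$species_id)), collapse = ", ")))
  NextMethod()
}

#' Provenance log of an occurrence set
#' @param x An [occ_set()] (or a tibble produced from one).
#' @return Character vector of log lines.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character()

occ_log <- function(x, ...) {
  attr(x, "provenance") <- c(provenance(x), sprintf(...))
  x
}

reoccset <- function(records, template, ...) {
  out <- occ_set(records, provenance = provenance(template))
  occ_log(out, ...)
}

#' Read occurrence records from CSV
#'
#' Column names are configurable and default to the Darwin-Core-style headers
#' used by the large open biodiversity databases. Rows whose coordinates do
#' not parse or fall outside valid lon/lat bounds are dropped and counted in
#' the provenance log.
#'
#' @param path CSV file path.
#' @param species_id Optional label overriding the species column.
#' @param col_map Named character vector mapping the fields `species`, `lon`,
#'   `lat`, `uncertainty`, `source` to CSV headers.
#' @return An [occ_set()].
#' @export
read_occurrences <- function(path, species_id = NULL,
                             col_map = c(species = "species",
                                         lon = "decimalLongitude",
                                         lat = "decimalLatitude",
                                         uncertainty = "coordinateUncertaintyInMeters",
                                         source = "source")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!all(col_map[c("lon", "lat")] %in% names(raw)))
    stop("missing coordinate columns: expected '", col_map[["lon"]],
         "' and '", col_map[["lat"]], "' in ", path)
  pick <- function(field, default = NA_character_) {
    nm <- col_map[[field]]
    if (!is.null(nm) && !is.na(nm) && nm %in% names(raw)) raw[[nm]]
    else rep(default, nrow(raw))
  }
  rec <- tibble::tibble(
    species_id = if (!is.null(species_id)) species_id else pick("species"),
    lon = suppressWarnings(as.numeric(pick("lon"))),
    lat = suppressWarnings(as.numeric(pick("lat"))),
    uncertainty_m = suppressWarnings(as.numeric(pick("uncertainty"))),
    source = pick("source"))
  bad <- is.na(rec$lon) | is.na(rec$lat) |
    rec$lon < -180 | rec$lon > 180 | rec$lat < -90 | rec$lat > 90
  neg_unc <- !is.na(rec$uncertainty_m) & rec$uncertainty_m < 0
  rec$uncertainty_m[neg_unc] <- NA_real_
  rec <- rec[!bad, ]
  if (nrow(rec) == 0) stop("no parseable occurrence rows in ", path)
  occ <- occ_set(rec)
  occ_log(occ, "read_occurrences: %d rows read, %d with invalid coordinates dropped, %d retained",
          nrow(raw), sum(bad), nrow(rec))
}

#' Filter imprecise records with a retention guard
#'
#' Removes records whose coordinate uncertainty exceeds
#' `max_uncertainty_m` (default 1 km). If the filter would leave less than
#' `min_retained_fraction` of the input or fewer than `min_n` records, it is
#' rolled back entirely (the imprecise records are kept) and the event is
#' logged -- a small-sample guard, not an error. Records with missing
#' uncertainty are kept either way.
#'
#' @param occ An [occ_set()].
#' @param max_uncertainty_m Uncertainty cutoff in metres.
#' @param min_retained_fraction,min_n Retention guard: the filter must keep
#'   at least this fraction of records and at least this many.
#' @return An [occ_set()].
#' @export
filter_records <- function(occ, max_uncertainty_m = 1000,
                           min_retained_fraction = 0.5, min_n = 20) {
  stopifnot(nrow(occ) > 0)
  n_missing <- sum(is.na(occ$uncertainty_m))
  keep <- is.na(occ$uncertainty_m) | occ$uncertainty_m <= max_uncertainty_m
  n_in <- nrow(occ); n_keep <- sum(keep)
  if (n_keep / n_in < min_retained_fraction || n_keep < min_n) {
    out <- occ_log(occ,
      "filter_records: uncertainty filter (> %g m) would keep %d/%d records, below guard (>= %d%% and >= %d); rolled back, imprecise records kept",
      max_uncertainty_m, n_keep, n_in,
      round(100 * min_retained_fraction), min_n)
    return(out)
  }
  out <- reoccset(occ[keep, ], occ,
    "filter_records: removed %d records with uncertainty > %g m, %d retained",
    n_in - n_keep, max_uncertainty_m, n_keep)
  if (n_missing > 0)
    out <- occ_log(out,
      "filter_records: %d records with missing uncertainty kept", n_missing)
  out
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Keeps the first record (stable input order) in each occupied cell.
#' Records outside the grid extent are dropped and logged.
#'
#' @param occ An [occ_set()].
#' @param grid A [grid_spec()], typically the ~1 km analysis grid.
#' @return An [occ_set()].
#' @export
thin_to_grid <- function(occ, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  idx <- cell_of(grid, occ$lon, occ$lat)
  outside <- is.na(idx$cell)
  keep <- !outside & !duplicated(idx$cell)
  reoccset(occ[keep, ], occ,
    "thin_to_grid: %d outside grid dropped, %d duplicates within cells removed, %d retained",
    sum(outside), sum(!outside) - sum(keep), sum(keep))
}
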
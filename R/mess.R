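#' Multivariate environmental similarity surface (MESS)
#'
#' Compares every target cell with a reference sample of environments
#' (conventionally, the environments at the known occurrences of the
#' reference range). For each variable, with `f` the percentage of reference
#' values below the cell value (ties counted half):
#' `f = 0` gives `100 * (v - min) / (max - min)`; `0 < f <= 50` gives `2f`;
#' `50 < f < 100` gives `2(100 - f)`; `f = 100` gives
#' `100 * (max - v) / (max - min)`. The cell's MESS value is the minimum
#' over variables, and the minimizing (most dissimilar) variable is
#' recorded. Values are positive only strictly inside the reference range on
#' every variable, 100 at the reference median of all variables, and
#' unbounded below outside the range.
#'
#' Non-numeric (categorical) reference variables are excluded with a
#' warning; the formula is defined for continuous variables only. A
#' zero-range variable (all reference values equal) contributes 0 at the
#' reference value and a negative value scaled by `max(1, |v0|)` outside,
#' with a warning.
#'
#' @param reference Point-by-variable reference sample (data frame/matrix,
#'   >= 2 rows).
#' @param target An [env_stack()] whose layers are all reference variables,
#'   or a point-by-variable matrix/data frame.
#' @return For a stack, an object of class `mess_result` (`similarity` and
#'   `most_dissimilar` per cell plus the grid); otherwise a tibble with
#'   columns `similarity` and `most_dissimilar`.
#' @export
mess_map <- function(reference, target) {
  ref <- tibble::as_tibble(reference)
  numeric_vars <- names(ref)[vapply(ref, is.numeric, logical(1))]
  if (length(numeric_vars) < length(ref))
    warning("excluding non-numeric reference variable(s): ",
            paste(setdiff(names(ref), numeric_vars), collapse = ", "))
  ref <- ref[numeric_vars]
  if (nrow(ref) < 2) stop("need at least 2 reference points")
  is_stack <- inherits(target, "env_stack")
  tg <- if (is_stack) tibble::as_tibble(env_values(target))
        else tibble::as_tibble(target)
  vars <- names(tg)
  if (!all(vars %in% names(ref)))
    stop("target variable(s) missing from reference: ",
         paste(setdiff(vars, names(ref)), collapse = ", "))
  sims <- vapply(vars, function(v) mess_variable(ref[[v]], tg[[v]]),
                 numeric(nrow(tg)))
  if (!is.matrix(sims)) sims <- matrix(sims, nrow = 1, dimnames = list(NULL, vars))
  mdv_idx <- apply(sims, 1, which.min)
  out <- tibble::tibble(similarity = sims[cbind(seq_len(nrow(sims)), mdv_idx)],
                        most_dissimilar = vars[mdv_idx])
  if (!is_stack) return(out)
  nc <- n_cells(target$grid)
  sim_full <- rep(NA_real_, nc); mdv_full <- rep(NA_character_, nc)
  keep <- which(!target$nodata_mask)
  sim_full[keep] <- out$similarity; mdv_full[keep] <- out$most_dissimilar
  structure(list(grid = target$grid, similarity = sim_full,
                 most_dissimilar = mdv_full,
                 nodata_mask = target$nodata_mask, variables = vars),
            class = "mess_result")
}

# Per-variable similarity for a vector of cell values against one reference
# sample.
mess_variable <- function(ref, v) {
  n <- length(ref)
  s <- sort(ref)
  mn <- s[1]; mx <- s[n]; rng <- mx - mn
  out <- numeric(length(v))
  if (rng == 0) {
    warning("zero reference range for a variable; degenerate similarity used")
    off <- v != mn
    out[off] <- -100 * abs(v[off] - mn) / max(1, abs(mn))
    return(out)
  }
  below <- v <= mn
  above <- v >= mx
  mid <- !below & !above
  out[below] <- 100 * (v[below] - mn) / rng
  out[above] <- 100 * (mx - v[above]) / rng
  if (any(mid)) {
    n_le <- findInterval(v[mid], s)
    n_lt <- findInterval(v[mid], s, left.open = TRUE)
    f <- 100 * (n_lt + 0.5 * (n_le - n_lt)) / n
    out[mid] <- ifelse(f <= 50, 2 * f, 2 * (100 - f))
  }
  out
}

#' @export
print.mess_result <- function(x, ...) {
  v <- x$similarity[!is.na(x$similarity)]
  cat(sprintf("<mess_result> %d cells; similarity %.1f to %.1f, %.1f%% negative (non-analogue)\n",
              length(v), min(v), max(v), 100 * mean(v < 0)))
  invisible(x)
}

#' @describeIn mess_map Long-format tibble of a MESS surface.
#' @param x A `mess_result`.
#' @param ... Unused.
#' @method as_tibble mess_result
#' @export
as_tibble.mess_result <- function(x, ...) {
  dplyr::bind_cols(cell_centres(x$grid),
                   tibble::tibble(similarity = x$similarity,
                                  most_dissimilar = x$most_dissimilar))
}
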
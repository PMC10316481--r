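#' Simulate a spatially autocorrelated environmental landscape
#'
#' Generates `k_layers` Gaussian random fields by circular (FFT)
#' convolution of white noise with a Gaussian kernel of scale
#' `autocorr_range_cells`, each standardized to zero mean and unit variance
#' over the grid. An optional target Pearson correlation can be imposed
#' between the first two layers by linear mixing. Deterministic under
#' `seed`.
#'
#' @param seed Integer seed.
#' @param n_rows,n_cols Grid size.
#' @param k_layers Number of layers.
#' @param autocorr_range_cells Gaussian smoothing scale in cells (>= 1).
#' @param pairwise_corr Optional target correlation between layers 1 and 2.
#' @param origin_lon,origin_lat,cell_size_deg Geographic placement of the
#'   grid (defaults put it in north-eastern Australia at ~1 km cells).
#' @param nodata_fraction Fraction of cells masked as nodata (seeded).
#' @return An [env_stack()].
#' @export
make_landscape <- function(seed, n_rows = 120, n_cols = 120, k_layers = 2,
                           autocorr_range_cells = 6, pairwise_corr = NULL,
                           origin_lon = 144, origin_lat = -16,
                           cell_size_deg = 0.01, nodata_fraction = 0) {
  stopifnot(autocorr_range_cells >= 1, n_rows >= 4, n_cols >= 4,
            k_layers >= 1)
  set.seed(seed)
  # Gaussian kernel on the torus, in the frequency domain
  di <- pmin(0:(n_rows - 1), n_rows - 0:(n_rows - 1))
  dj <- pmin(0:(n_cols - 1), n_cols - 0:(n_cols - 1))
  kern <- exp(-outer(di^2, dj^2, `+`) / (2 * autocorr_range_cells^2))
  fk <- stats::fft(kern / sum(kern))
  field <- function() {
    w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
    f <- Re(stats::fft(stats::fft(w) * fk, inverse = TRUE)) / (n_rows * n_cols)
    as.vector(t((f - mean(f)) / stats::sd(f)))  # row-major cell order
  }
  vals <- vapply(seq_len(k_layers), function(i) field(),
                 numeric(n_rows * n_cols))
  if (!is.null(pairwise_corr) && k_layers >= 2) {
    stopifnot(abs(pairwise_corr) <= 1)
    mixed <- pairwise_corr * vals[, 1] +
      sqrt(1 - pairwise_corr^2) * vals[, 2]
    vals[, 2] <- (mixed - mean(mixed)) / stats::sd(mixed)
  }
  colnames(vals) <- paste0("env", seq_len(k_layers))
  nodata <- rep(FALSE, n_rows * n_cols)
  if (nodata_fraction > 0)
    nodata[sample.int(length(nodata), round(nodata_fraction * length(nodata)))] <- TRUE
  env_stack(grid_spec(n_rows, n_cols, origin_lon, origin_lat, cell_size_deg),
            vals, nodata_mask = nodata)
}

#' Define a virtual species with a Gaussian niche
#'
#' Suitability is a product of Gaussian responses,
#' `max_prob * exp(-0.5 * sum(((e - centroid) / widths)^2))`, the simplest
#' unimodal niche with a closed-form density.
#'
#' @param centroid Niche optimum per variable (named or positional).
#' @param widths Niche breadth (Gaussian sd) per variable, > 0.
#' @param max_prob Suitability at the optimum, in `(0, 1]`.
#' @return An object of class `virtual_species` whose `$suitability` maps a
#'   point-by-variable matrix to `[0, 1]` suitabilities.
#' @export
virtual_species <- function(centroid, widths = 1, max_prob = 1) {
  widths <- rep_len(widths, length(centroid))
  stopifnot(all(widths > 0), max_prob > 0, max_prob <= 1)
  suitability <- function(env_values) {
    x <- as.matrix(env_values)[, seq_along(centroid), drop = FALSE]
    d2 <- sweep(sweep(x, 2, centroid), 2, widths, "/")^2
    max_prob * exp(-0.5 * rowSums(d2))
  }
  structure(list(centroid = centroid, widths = widths, max_prob = max_prob,
                 suitability = suitability),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat(sprintf("<virtual_species> centroid (%s), widths (%s), max %.2f\n",
              paste(signif(x$centroid, 3), collapse = ", "),
              paste(signif(x$widths, 3), collapse = ", "), x$max_prob))
  invisible(x)
}

#' Sample occurrence records proportional to suitability
#'
#' Cells are drawn with probability proportional to suitability times the
#' optional sampling-bias field; coordinates are jittered uniformly within
#' the cell (so records stay in their cell under thinning). Deterministic
#' under `seed`.
#'
#' @param env An [env_stack()].
#' @param species A [virtual_species()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @param bias_field Optional per-cell non-negative sampling bias.
#' @param one_per_cell Sample cells without replacement.
#' @param species_id Label for the records.
#' @return An [occ_set()].
#' @export
sample_occurrences <- function(env, species, n, seed = NULL,
                               bias_field = NULL, one_per_cell = FALSE,
                               species_id = "virtual") {
  stopifnot(inherits(env, "env_stack"), inherits(species, "virtual_species"))
  if (!is.null(seed)) set.seed(seed)
  p <- species$suitability(env$values)
  p[env$nodata_mask] <- 0
  if (!is.null(bias_field)) {
    stopifnot(length(bias_field) == length(p), all(bias_field >= 0, na.rm = TRUE))
    p <- p * ifelse(is.na(bias_field), 0, bias_field)
  }
  if (all(p == 0)) stop("suitability is zero everywhere; nothing to sample")
  if (one_per_cell) n <- min(n, sum(p > 0))
  cells <- sample.int(length(p), n, replace = !one_per_cell, prob = p)
  cc <- cell_centres(env$grid, cells)
  half <- env$grid$cell_size_deg / 2
  occ <- occ_set(tibble::tibble(
    species_id = species_id,
    lon = cc$lon + stats::runif(n, -half, half) * 0.999,
    lat = cc$lat + stats::runif(n, -half, half) * 0.999,
    uncertainty_m = 0, source = "synthetic"))
  occ_log(occ, "sample_occurrences: %d records drawn proportional to suitability%s",
          n, if (is.null(bias_field)) "" else " x bias")
}

#' Paired-range niche-shift scenario with known truth
#'
#' Builds the full inputs for one species' two-range comparison: a
#' "reference" (international) landscape and an "introduced" landscape with
#' the same layer statistics, a Gaussian-niche species whose introduced
#' centroid is shifted by `delta` standardized environmental units (the
#' shift is split equally across the layers, as real climatic displacements
#' load many correlated variables at once -- this is what lets the leading
#' PCA axis align with the shift), and presence samples from both.
#' `env_shift_frac` moves the introduced landscape's layer means along the
#' same direction by `delta * env_shift_frac`: 0 keeps the available
#' environments identical (a niche shift within shared conditions), 1 makes
#' the introduced range's environment as novel as the niche shift itself
#' (the fully non-analogue case that produces complete niche expansion).
#'
#' Truth indices (D, expansion, stability, unfilled) are computed by numeric
#' integration of the two suitability-weighted occupancy densities --
#' availability (standard normal per standardized layer, mean-shifted for
#' the introduced range) times the Gaussian suitability -- on a
#' `truth_res^2` lattice over the first two environmental variables. The
#' occupied envelope used for the truth expansion/unfilled masks is the
#' region carrying density above `support_floor` of the peak.
#'
#' @param seed Integer seed; sub-seeds are derived for each stochastic step.
#' @param delta Total niche centroid shift, standardized units (>= 0).
#' @param n_per_range Presences sampled per range.
#' @param env_shift_frac Fraction of `delta` applied to the introduced
#'   landscape's layer-1 mean (0-1).
#' @param widths Niche breadth per variable.
#' @param k_layers,n_rows,n_cols,autocorr_range_cells Landscape parameters.
#' @param n_background Background points subsampled per range.
#' @param truth_res Truth-integration lattice resolution per axis.
#' @param support_floor Relative density floor defining the occupied
#'   envelope in the truth integration.
#' @return An object of class `shift_scenario`: `native` and `invaded`
#'   sub-lists (`env`, `occ`, `species`), background environment tibbles,
#'   and the `truth` tibble.
#' @export
make_shift_scenario <- function(seed, delta = 2, n_per_range = 500,
                                env_shift_frac = 0, widths = 1,
                                k_layers = 2, n_rows = 120, n_cols = 120,
                                autocorr_range_cells = 6,
                                n_background = 3000, truth_res = 400,
                                support_floor = 1e-5) {
  stopifnot(delta >= 0, env_shift_frac >= 0, env_shift_frac <= 1,
            k_layers == 2)
  widths <- rep_len(widths, k_layers)
  mu_niche <- delta / sqrt(k_layers)       # per-layer niche centroid shift
  mu_avail <- mu_niche * env_shift_frac    # per-layer availability shift
  env_n <- make_landscape(seed, n_rows, n_cols, k_layers,
                          autocorr_range_cells)
  env_i <- make_landscape(seed + 1000003L, n_rows, n_cols, k_layers,
                          autocorr_range_cells, origin_lon = 110)
  env_i$values <- env_i$values + mu_avail
  sp_n <- virtual_species(rep(0, k_layers), widths)
  sp_i <- virtual_species(rep(mu_niche, k_layers), widths)
  occ_n <- sample_occurrences(env_n, sp_n, n_per_range, seed = seed + 11L,
                              species_id = "native")
  occ_i <- sample_occurrences(env_i, sp_i, n_per_range, seed = seed + 22L,
                              species_id = "invaded")
  pick_bkg <- function(env, s) {
    set.seed(s)
    v <- env_values(env)
    v[sample.int(nrow(v), min(n_background, nrow(v))), ]
  }
  bkg_n <- pick_bkg(env_n, seed + 33L)
  bkg_i <- pick_bkg(env_i, seed + 44L)

  # truth by numeric integration over the two environmental axes
  e1 <- seq(-6, mu_niche + 6, length.out = truth_res)
  e2 <- e1
  zdens <- function(avail_mu, niche_mu) {
    z <- outer(stats::dnorm(e1, avail_mu) *
                 stats::dnorm(e1, niche_mu, widths[1]),
               stats::dnorm(e2, avail_mu) *
                 stats::dnorm(e2, niche_mu, widths[2]))
    z / sum(z)
  }
  zn <- zdens(0, 0)
  zi <- zdens(mu_avail, mu_niche)
  supp_n <- zn > support_floor * max(zn)
  supp_i <- zi > support_floor * max(zi)
  truth <- tibble::tibble(
    D = 1 - 0.5 * sum(abs(zn - zi)),
    expansion = sum(zi[!supp_n]),
    stability = 1 - sum(zi[!supp_n]),
    unfilled = sum(zn[!supp_i]))
  structure(list(
    native = list(env = env_n, occ = occ_n, species = sp_n),
    invaded = list(env = env_i, occ = occ_i, species = sp_i),
    bkg_native = bkg_n, bkg_invaded = bkg_i,
    truth = truth, delta = delta, env_shift_frac = env_shift_frac,
    widths = widths, seed = seed),
    class = "shift_scenario")
}

#' @export
print.shift_scenario <- function(x, ...) {
  cat(sprintf("<shift_scenario> delta = %g (env shift %g), %d presences/range; truth D = %.3f, expansion = %.3f\n",
              x$delta, x$delta * x$env_shift_frac, nrow(x$native$occ),
              x$truth$D, x$truth$expansion))
  invisible(x)
}

#' Run the niche-overlap analysis on a scenario
#'
#' Convenience wrapper: extracts the environments at each range's
#' occurrences and calls [niche_overlap()] with the scenario backgrounds.
#'
#' @param scenario A [make_shift_scenario()] result.
#' @param ... Passed to [niche_overlap()].
#' @return A [niche_overlap()] object.
#' @export
scenario_overlap <- function(scenario, ...) {
  stopifnot(inherits(scenario, "shift_scenario"))
  vars <- scenario$native$env$layer_names
  en <- extract_env(scenario$native$env, scenario$native$occ)[vars]
  ei <- extract_env(scenario$invaded$env, scenario$invaded$occ)[vars]
  niche_overlap(en, ei, scenario$bkg_native, scenario$bkg_invaded, ...)
}
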
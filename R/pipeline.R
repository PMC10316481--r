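#' Default analysis configuration
#'
#' Returns the full configuration skeleton with the conventional defaults:
#' 1 km (1000 m) coordinate-uncertainty cutoff with the 50%/20-record
#' retention guard, Pearson r > 0.80 collinearity pruning, 100 x 100 niche
#' grid, 1000 similarity randomizations, 10-fold cross-validation, 1%
#' permutation-importance cutoff, fixed cumulative threshold 10, alpha-hull
#' alpha 1.5, and conductance floor 1e-3.
#'
#' @return A nested list; fill in `env`, `species`, and `output_dir`.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    env = list(international = NULL, australian = NULL),
    species = list(),
    background = NULL,
    profile_vars = NULL,
    thresholds = list(
      max_uncertainty_m = 1000, min_retained_fraction = 0.5, min_n = 20,
      r_max = 0.80, niche_grid_R = 100, n_rand = 1000,
      cumulative = 10, importance_pct = 1, k_folds = 10,
      alpha = 1.5, epsilon = 1e-3,
      n_background = 10000, n_background_env = 3000))
}

#' Read an analysis configuration from YAML
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(default_config(), yaml::read_yaml(path))
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
                      nm == "thresholds")
      utils::modifyList(base[[nm]], user[[nm]])
    else user[[nm]]
  }
  base
}

validate_config <- function(config) {
  errs <- character()
  th <- config$thresholds
  for (nm in names(th))
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0)
      errs <- c(errs, sprintf("thresholds$%s must be a positive number", nm))
  for (rng in c("international", "australian")) {
    p <- config$env[[rng]]
    if (is.null(p)) errs <- c(errs, sprintf("env$%s is required", rng))
    else if (!all(file.exists(unlist(p))))
      errs <- c(errs, sprintf("env$%s path does not exist: %s", rng,
                              paste(unlist(p)[!file.exists(unlist(p))],
                                    collapse = ", ")))
  }
  if (length(config$species) == 0) errs <- c(errs, "species list is empty")
  for (sp in config$species) {
    if (is.null(sp$id)) errs <- c(errs, "every species needs an id")
    for (rng in c("international", "australian")) {
      if (is.null(sp[[rng]]))
        errs <- c(errs, sprintf("species %s: %s occurrences required",
                                sp$id %||% "?", rng))
      else if (!file.exists(sp[[rng]]))
        errs <- c(errs, sprintf("species %s: missing file %s",
                                sp$id %||% "?", sp[[rng]]))
    }
  }
  if (!is.null(config$background) &&
      !all(file.exists(unlist(config$background))))
    errs <- c(errs, sprintf("background path does not exist: %s",
                            paste(unlist(config$background)[
                              !file.exists(unlist(config$background))],
                              collapse = ", ")))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full niche-shift and invasion-risk pipeline
#'
#' Executes, per species: record filtering and thinning; collinearity
#' pruning; the PCA niche-space overlap analysis with the randomization
#' similarity test; maximum-entropy suitability modeling with target-group
#' (or whole-landscape) background, cross-validation and
#' permutation-importance variable selection; fixed-cumulative
#' thresholding; MESS dissimilarity against the reference-range occurrence
#' environments; the accumulated-cost invasion-risk surface; and alpha-hull
#' range-area accounting. All randomness derives from `config$seed`.
#'
#' @param config A configuration list (see [default_config()]) or a YAML
#'   path.
#' @return An object of class `run_report`: the three report tables
#'   (`overlap`, `profiles`, `areas`), model `evaluation`, per-species
#'   result objects, provenance logs, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- merge_config(default_config(), config)
  validate_config(config)
  th <- config$thresholds
  env_int <- stage("load-env", read_env_stack(unlist(config$env$international)))
  env_aus <- stage("load-env", read_env_stack(unlist(config$env$australian)))
  if (!setequal(env_int$layer_names, env_aus$layer_names))
    stop("stage 'load-env' failed: ranges have different layer sets")

  # collinearity pruning (applied to the niche-overlap stage only; the
  # suitability models keep the full variable set)
  env_int_nc <- stage("collinearity", drop_correlated(env_int, th$r_max))
  overlap_vars <- env_int_nc$layer_names

  bkg_env <- function(env, s) {
    set.seed(s)
    v <- env_values(env)
    v[sample.int(nrow(v), min(th$n_background_env, nrow(v))), ]
  }
  target_bkg <- NULL
  if (!is.null(config$background))
    target_bkg <- stage("background", {
      occs <- purrr::map(unlist(config$background), read_occurrences)
      make_background(occs, env_aus$grid, th$n_background,
                      seed = config$seed + 7L)
    })

  profile_vars <- config$profile_vars %||%
    utils::head(env_int$layer_names, 3)

  species_results <- purrr::map(config$species, function(sp) {
    prep <- function(path, env, id) {
      read_occurrences(path, species_id = id) |>
        filter_records(th$max_uncertainty_m, th$min_retained_fraction,
                       th$min_n) |>
        thin_to_grid(env$grid)
    }
    occ_int <- stage(paste0(sp$id, ":filter"),
                     prep(sp$international, env_int, sp$id))
    occ_aus <- stage(paste0(sp$id, ":filter"),
                     prep(sp$australian, env_aus, sp$id))
    ex_int <- stage(paste0(sp$id, ":extract"), extract_env(env_int, occ_int))
    ex_aus <- stage(paste0(sp$id, ":extract"), extract_env(env_aus, occ_aus))

    ov <- stage(paste0(sp$id, ":niche-overlap"),
      niche_overlap(ex_int[overlap_vars], ex_aus[overlap_vars],
                    bkg_env(env_int, config$seed + 101L),
                    bkg_env(env_aus, config$seed + 102L),
                    R = th$niche_grid_R, n_rand = th$n_rand,
                    seed = config$seed + 103L))
    prof <- stage(paste0(sp$id, ":profile"),
      climate_profile_diff(ex_int[profile_vars], ex_aus[profile_vars]))

    sdm <- stage(paste0(sp$id, ":sdm"), {
      pres <- dplyr::bind_rows(ex_int[env_int$layer_names],
                               ex_aus[env_aus$layer_names])
      bkg <- if (!is.null(target_bkg))
        extract_env(env_aus, target_bkg)[env_aus$layer_names]
      else dplyr::bind_rows(bkg_env(env_int, config$seed + 104L),
                            bkg_env(env_aus, config$seed + 105L))
      sel <- select_variables(pres, bkg,
                              min_importance_pct = th$importance_pct,
                              seed = config$seed + 106L)
      cv <- maxent_cv(pres[sel$selected], bkg[sel$selected],
                      k = th$k_folds, seed = config$seed + 107L)
      suit <- predict(sel$model, env_aus, type = "logistic")
      cum <- predict(sel$model, env_aus, type = "cumulative")
      list(selection = sel, cv = cv, suitability = suit,
           suitable_mask = threshold_cumulative(cum, th$cumulative))
    })

    mess <- stage(paste0(sp$id, ":mess"),
                  mess_map(ex_int[env_int$layer_names], env_aus))

    risk <- stage(paste0(sp$id, ":risk"), {
      hull <- alpha_hull_range(occ_aus, alpha = th$alpha)
      occupied <- rasterize_range(hull, env_aus$grid)
      cost <- accumulated_cost(sdm$suitability, tibble::as_tibble(occ_aus),
                               epsilon = th$epsilon)
      list(hull = hull, occupied = occupied,
           map = risk_map(sdm$suitability, cost, occupied))
    })
    areas <- stage(paste0(sp$id, ":areas"),
      range_area_summary(risk$hull, sdm$suitable_mask, env_aus$grid))

    list(id = sp$id, overlap = ov, profile = prof, sdm = sdm, mess = mess,
         risk = risk, areas = areas,
         provenance = list(international = provenance(occ_int),
                           australian = provenance(occ_aus)))
  })

  ids <- purrr::map_chr(species_results, "id")
  report <- structure(list(
    overlap = purrr::map2_dfr(species_results, ids, function(r, id)
      dplyr::bind_cols(tibble::tibble(species = id), tidy(r$overlap))),
    profiles = purrr::map2_dfr(species_results, ids, function(r, id)
      dplyr::bind_cols(tibble::tibble(species = id), r$profile)),
    areas = purrr::map2_dfr(species_results, ids, function(r, id)
      dplyr::bind_cols(tibble::tibble(species = id), r$areas)),
    evaluation = purrr::map2_dfr(species_results, ids, function(r, id)
      tibble::tibble(species = id, mean_auc = r$sdm$cv$mean_auc,
                     n_selected = length(r$sdm$selection$selected),
                     selected = paste(r$sdm$selection$selected,
                                      collapse = ","))),
    species = stats::setNames(species_results, ids),
    manifest = list(seed = config$seed, thresholds = th,
                    overlap_vars = overlap_vars,
                    profile_vars = profile_vars,
                    package_version = as.character(utils::packageVersion("nicheshift")))),
    class = "run_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d species\n", nrow(x$overlap)))
  print(x$overlap)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes the three report tables as TSV, the manifest as JSON, provenance
#' logs as text, and the per-species suitability/MESS/risk layers as ESRI
#' ASCII grids plus the range polygon as GeoJSON. Output is assembled in a
#' temporary sibling directory and moved into place, so a failed write
#' leaves no partial report.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory.
#' @return Invisibly, `outdir`.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  parent <- dirname(outdir)
  if (!dir.exists(parent)) stop("unwritable directory: ", parent)
  tmp <- tempfile("report", tmpdir = parent)
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  readr::write_tsv(report$overlap, file.path(tmp, "niche_overlap.tsv"))
  readr::write_tsv(report$profiles, file.path(tmp, "climate_profiles.tsv"))
  readr::write_tsv(report$areas, file.path(tmp, "range_areas.tsv"))
  readr::write_tsv(report$evaluation, file.path(tmp, "model_evaluation.tsv"))
  jsonlite::write_json(report$manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (id in names(report$species)) {
    r <- report$species[[id]]
    d <- file.path(tmp, id)
    dir.create(d)
    write_env_stack(r$sdm$suitability, d)
    mess_stack <- env_stack(r$mess$grid,
                            matrix(r$mess$similarity, ncol = 1),
                            layer_names = "mess",
                            nodata_mask = r$mess$nodata_mask)
    write_env_stack(mess_stack, d)
    risk_stack <- env_stack(r$risk$map$grid,
                            matrix(r$risk$map$risk, ncol = 1),
                            layer_names = "risk",
                            nodata_mask = is.na(r$risk$map$risk))
    write_env_stack(risk_stack, d)
    write_range_geojson(r$risk$hull, file.path(d, "present_range.geojson"))
    writeLines(c("# international", r$provenance$international,
                 "# australian", r$provenance$australian),
               file.path(d, "provenance.txt"))
  }
  if (dir.exists(outdir)) unlink(outdir, recursive = TRUE)
  ok <- file.rename(tmp, outdir)
  if (!ok) stop("could not move report into place at ", outdir)
  invisible(outdir)
}

#' Write a self-contained synthetic input bundle
#'
#' Generates a small two-species virtual-species dataset (landscapes as
#' ESRI ASCII grids, occurrences as CSV, truth as JSON, configuration as
#' YAML) so the full pipeline can be exercised from files alone. One species
#' has a mild niche shift, the other a complete shift into novel
#' environments.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_per_range Presences per range and species.
#' @return The path of the written YAML configuration.
#' @export
write_demo_inputs <- function(dir, seed = 1, n_per_range = 150) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scn <- make_shift_scenario(seed, delta = 1, n_per_range = n_per_range)
  write_env_stack(scn$native$env, file.path(dir, "env_international"))
  write_env_stack(scn$invaded$env, file.path(dir, "env_australian"))
  write_occ_csv <- function(occ, sp_label, range_key) {
    occ <- tibble::as_tibble(occ)
    path <- file.path(dir, sprintf("%s_%s.csv", sp_label, range_key))
    readr::write_csv(
      tibble::tibble(species = sp_label,
                     decimalLongitude = occ$lon, decimalLatitude = occ$lat,
                     coordinateUncertaintyInMeters = occ$uncertainty_m,
                     source = occ$source), path)
    path
  }
  species <- list(
    list(id = "mild",
         international = write_occ_csv(scn$native$occ, "mild",
                                       "international"),
         australian = write_occ_csv(scn$invaded$occ, "mild", "australian")),
    list(id = "shifted",
         international = write_occ_csv(
           sample_occurrences(scn$native$env,
                              virtual_species(c(-1.2, 0)), n_per_range,
                              seed = seed + 900L, species_id = "shifted"),
           "shifted", "international"),
         australian = write_occ_csv(
           sample_occurrences(scn$invaded$env,
                              virtual_species(c(1.8, 0)), n_per_range,
                              seed = seed + 901L, species_id = "shifted"),
           "shifted", "australian")))
  jsonlite::write_json(scn$truth, file.path(dir, "mild_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(
    seed = seed,
    env = list(international = file.path(dir, "env_international"),
               australian = file.path(dir, "env_australian")),
    species = species,
    thresholds = list(n_rand = 199, niche_grid_R = 60, k_folds = 5,
                      n_background_env = 1500))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  path
}
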
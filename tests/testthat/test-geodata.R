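test_that("occurrence reading drops unparseable coordinates and logs counts", {
  path <- write_occ_fixture(occ_rows(lon = c(150, 151, 152, 153, 154),
                                     lat = c(-20, -21, -22, -23, -24)))
  occ <- read_occurrences(path)
  expect_s3_class(occ, "occ_set")
  expect_equal(nrow(occ), 5)
  expect_match(provenance(occ), "0 with invalid coordinates", all = FALSE)

  bad <- write_occ_fixture(occ_rows(lon = c(150, 151, 152, 153, 154),
                                    lat = c(-20, 999, -22, -23, -24)))
  occ2 <- read_occurrences(bad)
  expect_equal(nrow(occ2), 4)
  expect_match(provenance(occ2), "1 with invalid coordinates", all = FALSE)

  empty <- write_occ_fixture(occ_rows(lon = numeric(), lat = numeric()))
  expect_error(read_occurrences(empty), "no parseable")

  nocol <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(x = 1, y = 2), nocol)
  expect_error(read_occurrences(nocol), "coordinate columns")
})

test_that("uncertainty filter enforces the retention guard by rolling back", {
  # 10 records, 4 imprecise: filtering to 6 violates min_n = 20 -> rollback
  occ <- occ_set(occ_rows(lon = 150 + 1:10 / 10, lat = rep(-20, 10),
                          unc = c(rep(2000, 4), rep(100, 6))) |>
                   dplyr::rename(lon = decimalLongitude,
                                 lat = decimalLatitude,
                                 uncertainty_m = coordinateUncertaintyInMeters,
                                 species_id = species))
  out <- filter_records(occ)
  expect_equal(nrow(out), 10)
  expect_match(provenance(out), "rolled back", all = FALSE)

  # 40 records, 5 imprecise: 35 retained passes both guard conditions
  occ40 <- occ_set(tibble::tibble(lon = 150 + 1:40 / 10, lat = rep(-20, 40),
                                  uncertainty_m = c(rep(1500, 5), rep(10, 35))))
  out40 <- filter_records(occ40)
  expect_equal(nrow(out40), 35)

  # missing uncertainty is kept, with the policy logged
  occ_na <- occ_set(tibble::tibble(lon = 150 + 1:40 / 10, lat = rep(-20, 40)))
  out_na <- filter_records(occ_na)
  expect_equal(nrow(out_na), 40)
  expect_match(provenance(out_na), "missing uncertainty kept", all = FALSE)
})

test_that("grid thinning keeps the first record per occupied cell", {
  grid <- grid_spec(10, 10, origin_lon = 150, origin_lat = -20,
                    cell_size_deg = 0.1)
  occ <- occ_set(tibble::tibble(
    lon = c(150.01, 150.02, 150.03, 150.51),
    lat = c(-20.01, -20.02, -20.03, -20.51),
    source = c("a", "b", "c", "d")))
  out <- thin_to_grid(occ, grid)
  expect_equal(nrow(out), 2)
  expect_equal(out$source, c("a", "d"))  # stable input order tie-break

  # already-thin data passes through unchanged
  spread <- occ_set(tibble::tibble(lon = 150 + (0:9) / 10 + 0.05,
                                   lat = rep(-20.05, 10)))
  expect_equal(nrow(thin_to_grid(spread, grid)), 10)

  # a record outside the grid is dropped and logged
  outside <- occ_set(tibble::tibble(lon = c(150.05, 10), lat = c(-20.05, 0)))
  thinned <- thin_to_grid(outside, grid)
  expect_equal(nrow(thinned), 1)
  expect_match(provenance(thinned), "1 outside grid", all = FALSE)
})

test_that("thinned count equals the brute-force occupied-cell tally", {
  set.seed(41)
  grid <- grid_spec(10, 10, origin_lon = 0, origin_lat = 10, cell_size_deg = 1)
  lon <- runif(100, 0, 10); lat <- runif(100, 0, 10)
  occ <- occ_set(tibble::tibble(lon = lon, lat = lat))
  # independent tally: integer cell addresses computed from scratch
  ids <- paste(floor(lon), floor(lat))
  expect_equal(nrow(thin_to_grid(occ, grid)), length(unique(ids)))
})

test_that("filtering never grows a dataset and filter-then-thin is idempotent", {
  set.seed(7)
  grid <- grid_spec(12, 12, origin_lon = 0, origin_lat = 12, cell_size_deg = 1)
  occ <- occ_set(tibble::tibble(lon = runif(200, 0, 12),
                                lat = runif(200, 0, 12),
                                uncertainty_m = sample(c(NA, 50, 5000), 200,
                                                       replace = TRUE)))
  step1 <- thin_to_grid(filter_records(occ), grid)
  step2 <- thin_to_grid(filter_records(step1), grid)
  expect_lte(nrow(step1), nrow(occ))
  strip <- function(d) as.data.frame(lapply(tibble::as_tibble(d), unname))
  expect_equal(strip(step2), strip(step1))
})

test_that("collinearity pruning keeps a maximal low-correlation set", {
  set.seed(11)
  grid <- grid_spec(100, 100)
  a <- rnorm(1e4); c <- rnorm(1e4)
  env <- env_stack(grid, cbind(A = a, B = a, C = c))
  kept <- drop_correlated(env, r_max = 0.80)
  expect_equal(kept$layer_names, c("A", "C"))
  expect_match(attr(kept, "collinearity_log"), "dropped B", all = FALSE)

  # two independent white-noise layers both survive
  env2 <- env_stack(grid, cbind(A = a, C = c))
  expect_equal(drop_correlated(env2)$layer_names, c("A", "C"))

  # all pairwise correlations among kept layers respect the threshold
  set.seed(12)
  base <- matrix(rnorm(5e4), ncol = 5)
  mixed <- base %*% matrix(runif(25, -1, 1), 5)
  colnames(mixed) <- paste0("v", 1:5)
  pruned <- drop_correlated(env_stack(grid, mixed), r_max = 0.8)
  cors <- abs(cor(pruned$values))
  expect_true(all(cors[upper.tri(cors)] <= 0.8))

  # a constant layer is dropped with a warning
  env3 <- env_stack(grid, cbind(A = a, K = rep(1, 1e4)))
  expect_warning(out <- drop_correlated(env3), "constant")
  expect_equal(out$layer_names, "A")
})

test_that("point extraction returns containing-cell values and drops nodata", {
  grid <- grid_spec(2, 2, origin_lon = 0, origin_lat = 2, cell_size_deg = 1)
  vals <- cbind(t1 = c(1, 2, 3, 4), t2 = c(10, 20, 30, 40))
  nodata <- c(FALSE, FALSE, FALSE, TRUE)
  env <- env_stack(grid, vals, nodata_mask = nodata)
  occ <- occ_set(tibble::tibble(lon = c(0.5, 1.5, 1.5),
                                lat = c(1.5, 1.5, 0.5)))
  ex <- extract_env(env, occ)
  expect_equal(nrow(ex), 2)  # third point sits on the nodata cell
  expect_equal(ex$t1, c(1, 2))
  expect_equal(ex$t2, c(10, 20))
  expect_match(attr(ex, "provenance"), "1 on nodata", all = FALSE)

  all_bad <- occ_set(tibble::tibble(lon = 1.5, lat = 0.5))
  expect_error(extract_env(env, all_bad), "no occurrence")
})

test_that("ESRI ASCII stacks round-trip through disk", {
  grid <- grid_spec(6, 5, origin_lon = 140, origin_lat = -18,
                    cell_size_deg = 0.5)
  vals <- matrix(rnorm(60), ncol = 2, dimnames = list(NULL, c("a", "b")))
  vals[3, 1] <- NA
  env <- env_stack(grid, vals)
  dir <- withr::local_tempdir()
  write_env_stack(env, dir)
  back <- read_env_stack(dir)
  expect_equal(unclass(back$grid), unclass(grid))
  expect_equal(back$values[!back$nodata_mask, ],
               env$values[!env$nodata_mask, ], tolerance = 1e-9)
  expect_true(back$nodata_mask[3])

  # stacks on different grids refuse to align
  other <- env_stack(grid_spec(6, 5, origin_lon = 0, origin_lat = -18,
                               cell_size_deg = 0.5),
                     matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "c")))
  d2 <- withr::local_tempdir()
  write_env_stack(other, d2)
  expect_error(read_env_stack(c(file.path(dir, "a.asc"),
                                file.path(d2, "c.asc"))), "not aligned")
})
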
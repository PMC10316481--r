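test_that("a single binary feature recovers the closed-form weight", {
  # presence mean 0.8 vs background mean 0.5: the unpenalized moment
  # condition e^l / (e^l + 1) = 0.8 gives l = ln 4
  pres <- data.frame(v = c(rep(1, 8), rep(0, 2)))
  bkg <- data.frame(v = rep(c(1, 0), 50))
  fit <- fit_maxent(pres, bkg, classes = "l", reg_multiplier = 0)
  expect_equal(unname(fit$lambda), log(4), tolerance = 0.01)
  expect_equal(sum(predict(fit, bkg, type = "raw")), 1, tolerance = 1e-9)
})

test_that("presences matching the background give a near-null model", {
  set.seed(3)
  bkg <- data.frame(a = runif(400), b = runif(400))
  fit <- fit_maxent(bkg, bkg, classes = "lq")
  expect_true(all(abs(fit$lambda) < 0.05))
  raw <- predict(fit, bkg, type = "raw")
  expect_lt(max(raw) / min(raw), 1.6)   # close to uniform
})

test_that("the penalized objective trace is monotone and moments match", {
  set.seed(8)
  bkg <- data.frame(a = rnorm(500), b = rnorm(500))
  pres <- data.frame(a = rnorm(80, 0.8), b = rnorm(80, -0.4))
  fit <- fit_maxent(pres, bkg, classes = "lq", reg_multiplier = 0,
                    tol = 1e-10, max_iter = 5000)
  expect_true(all(diff(fit$trace) >= -1e-12))
  # unpenalized optimum: presence feature means = model-expected means
  Fp <- nicheshift:::feature_matrix(fit$features, pres)
  Fb <- nicheshift:::feature_matrix(fit$features, bkg)
  expect_equal(colMeans(Fp), as.vector(crossprod(Fb, fit$q_background)),
               tolerance = 1e-4, ignore_attr = TRUE)
  # features normalized to [0,1] over the background
  expect_true(all(Fb >= 0 & Fb <= 1))
})

test_that("cumulative output follows its definition and nests under thresholds", {
  # engineer four cells with raw mass 0.4, 0.3, 0.2, 0.1: with a single
  # linear feature, eta = log(raw) up to a constant
  cells <- data.frame(v = log(c(0.4, 0.3, 0.2, 0.1)))
  bkg <- cells
  fe <- maxent_features(bkg, n_presence = 100, classes = "l")
  fit <- structure(list(features = fe, lambda = c(v = diff(range(cells$v))),
                        logZ = 0, entropy = 1, vars = "v"),
                   class = "maxent_model")
  raw <- predict(fit, cells, type = "raw")
  expect_equal(raw, c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-9,
               ignore_attr = TRUE)
  cum <- predict(fit, cells, type = "cumulative")
  expect_equal(cum, c(100, 60, 30, 10), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cum[which.max(raw)], 100)
  # cumulative is monotone in raw, and masks nest as the threshold rises
  expect_equal(order(cum), order(raw))
  expect_equal(threshold_cumulative(cum, 10), rep(TRUE, 4))
  expect_equal(sum(threshold_cumulative(cum, 20)), 3)
  m10 <- threshold_cumulative(cum, 10); m20 <- threshold_cumulative(cum, 20)
  expect_true(all(m20[m20] & m10[m20]))
  expect_equal(threshold_cumulative(c(1, 5), 0), c(TRUE, TRUE))
  expect_equal(threshold_cumulative(c(1, 5), 50), c(FALSE, FALSE))
})

test_that("logistic output stays within the unit interval", {
  set.seed(9)
  bkg <- data.frame(a = rnorm(300))
  pres <- data.frame(a = rnorm(40, 1))
  fit <- suppressWarnings(fit_maxent(pres, bkg))
  lg <- predict(fit, data.frame(a = seq(-5, 5, 0.25)), type = "logistic")
  expect_true(all(lg >= 0 & lg <= 1))
})

test_that("prediction over a stack honours nodata and missing layers", {
  grid <- grid_spec(4, 4)
  vals <- cbind(a = rnorm(16), b = rnorm(16))
  env <- env_stack(grid, vals, nodata_mask = c(TRUE, rep(FALSE, 15)))
  pres <- data.frame(a = rnorm(30, 1), b = rnorm(30))
  bkg <- data.frame(a = rnorm(200), b = rnorm(200))
  fit <- fit_maxent(pres, bkg, classes = "l")
  out <- predict(fit, env, type = "raw")
  expect_s3_class(out, "env_stack")
  expect_true(is.na(out$values[1, 1]))
  expect_equal(sum(out$values[, 1], na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(predict(fit, env_stack(grid, vals[, 1, drop = FALSE],
                                      layer_names = "a")),
               "missing layer")
})

test_that("cross-validation separates the separable and floors at chance", {
  set.seed(14)
  # background on an annulus, presences at its centre: a quadratic surface
  # separates them with margin, strictly inside the feature bounds
  th <- runif(500, 0, 2 * pi); r <- runif(500, 2, 3)
  bkg <- data.frame(x = r * cos(th), y = r * sin(th))
  pres <- data.frame(x = runif(50, -0.5, 0.5), y = runif(50, -0.5, 0.5))
  cv <- suppressWarnings(maxent_cv(pres, bkg, k = 5, seed = 1,
                                   classes = "lq"))
  expect_equal(cv$mean_auc, 1, tolerance = 1e-9)
  pres <- pres[1]; bkg <- bkg[1]  # 1-D variant for the remaining checks
  pres$x <- runif(50, 2, 3); bkg$x <- runif(500, 0, 1)

  # labels carrying no signal: AUC sits at the permutation floor
  pool <- data.frame(x = runif(1000))
  cv0 <- maxent_cv(pool[1:200, , drop = FALSE], pool[201:1000, , drop = FALSE],
                   k = 5, seed = 2, classes = "l")
  expect_equal(cv0$mean_auc, 0.5, tolerance = 0.05)

  cv_a <- maxent_cv(pres, bkg, k = 5, seed = 7, classes = "l")
  cv_b <- maxent_cv(pres, bkg, k = 5, seed = 7, classes = "l")
  expect_equal(tidy(cv_a), tidy(cv_b))
  expect_error(maxent_cv(pres[1:4, , drop = FALSE], bkg, k = 10),
               "smaller k")
})

test_that("permutation importance finds the single informative variable", {
  set.seed(25)
  bkg <- data.frame(sig = rnorm(600), n1 = rnorm(600), n2 = rnorm(600))
  pres <- data.frame(sig = rnorm(120, 1.6, 0.5), n1 = rnorm(120),
                     n2 = rnorm(120))
  sel <- suppressWarnings(select_variables(pres, bkg,
                                           min_importance_pct = 1, seed = 5,
                                           classes = "lq"))
  expect_equal(sum(sel$importance$importance_pct), 100, tolerance = 1e-9)
  expect_gt(sel$importance$importance_pct[sel$importance$variable == "sig"],
            90)
  expect_true("sig" %in% sel$selected)
  expect_false(any(c("n1", "n2") %in% sel$selected))
  expect_equal(sel$model$vars, sel$selected)
})

test_that("target-group backgrounds thin, subsample, and warn when short", {
  grid <- grid_spec(20, 20, origin_lon = 0, origin_lat = 20, cell_size_deg = 1)
  set.seed(30)
  occ1 <- occ_set(tibble::tibble(lon = runif(40, 0, 20),
                                 lat = runif(40, 0, 20)))
  expect_warning(bg <- make_background(list(occ1), grid, n_background = 1e4),
                 "available")
  expect_lte(nrow(bg), 40)

  # records sharing one cell collapse to one
  dup <- occ_set(tibble::tibble(lon = c(0.2, 0.3, 5.5), lat = c(19.5, 19.4, 5.5)))
  expect_warning(bgd <- make_background(dup, grid, n_background = 1e4))
  expect_equal(nrow(bgd), 2)

  big <- occ_set(tibble::tibble(lon = runif(800, 0, 20),
                                lat = runif(800, 0, 20)))
  s1 <- make_background(big, grid, n_background = 100, seed = 3)
  s2 <- make_background(big, grid, n_background = 100, seed = 3)
  expect_equal(nrow(s1), 100)
  expect_equal(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_error(make_background(occ_set(tibble::tibble(lon = numeric(),
                                                      lat = numeric())),
                               grid), "empty")
})
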
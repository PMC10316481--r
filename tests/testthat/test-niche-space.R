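test_that("pooled PCA matches a direct eigen-decomposition oracle", {
  x1 <- matrix(c(0, 0, 1, 2, 2, 1), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  x2 <- matrix(c(3, 4, 5, 5, 4, 3), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))
  fit <- calibrate_pca(x1, x2)
  # oracle: standardize pooled data, eigen-solve its covariance directly
  pooled <- scale(rbind(x1, x2))
  eig <- eigen(cov(pooled))
  expect_equal(abs(fit$loadings), abs(eig$vectors), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fit$explained, eig$values / sum(eig$values), tolerance = 1e-12)
  sc <- predict(fit, rbind(x1, x2))
  expect_equal(abs(as.matrix(sc)), abs(pooled %*% eig$vectors),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCA loadings are orthonormal and degenerate inputs are caught", {
  set.seed(5)
  x <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("p", "q", "r")))
  y <- matrix(rnorm(60), ncol = 3, dimnames = list(NULL, c("p", "q", "r")))
  fit <- calibrate_pca(x, y)
  expect_equal(crossprod(fit$loadings), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(fit$explained), 1, tolerance = 1e-12)

  # two perfectly correlated variables collapse onto one axis
  z <- cbind(u = rnorm(30)); z2 <- cbind(u = rnorm(30))
  dup <- function(m) cbind(u = m[, 1], v = 2 * m[, 1] + 1)
  fit2 <- calibrate_pca(dup(z), dup(z2))
  expect_equal(fit2$explained[1], 1, tolerance = 1e-9)

  const <- cbind(u = rnorm(30), v = rep(1, 30))
  expect_error(calibrate_pca(const, const), "zero-variance.*v")
})

test_that("niche-grid densities normalize and peak where occurrences cluster", {
  set.seed(21)
  bkg <- cbind(runif(2000, -2, 2), runif(2000, -2, 2))
  occ <- cbind(rnorm(200, 1, 0.08), rnorm(200, -1, 0.08))
  g <- niche_grid(occ, bkg, R = 60)
  expect_equal(sum(g$z_occ), 1, tolerance = 1e-9)
  expect_equal(sum(g$z_env), 1, tolerance = 1e-9)
  expect_equal(sum(g$z_cor), 1, tolerance = 1e-9)
  expect_true(all(g$z_occ >= 0) && all(g$z_cor >= 0))
  peak <- arrayInd(which.max(g$z_cor), dim(g$z_cor))
  expect_equal(g$gx[peak[1]], 1, tolerance = 0.15)
  expect_equal(g$gy[peak[2]], -1, tolerance = 0.15)
  # occupancy cannot extend beyond available environment
  expect_true(all(g$z_env[g$occupancy] > 0))
  expect_error(niche_grid(occ[1:4, ], bkg), "at least 5")
})

test_that("kernel density agrees with analytic and reference implementations", {
  set.seed(33)
  n <- 20000
  occ <- cbind(rnorm(n), rnorm(n, 0, 0.5))
  bkg <- cbind(runif(4000, -4, 4), runif(4000, -4, 4))
  bounds <- list(x = c(-4, 4), y = c(-4, 4))
  g <- niche_grid(occ, bkg, bounds = bounds, R = 80)
  # analytic cell masses of the generating Gaussian
  truth <- outer(dnorm(g$gx), dnorm(g$gy, 0, 0.5))
  truth <- truth / sum(truth)
  expect_lt(max(abs(g$z_occ - truth)), 0.1 * max(truth))
  expect_lt(0.5 * sum(abs(g$z_occ - truth)), 0.05)
  # cross-check against MASS::kde2d with matching bandwidths (kde2d scales
  # its h by 1/4) on the same grid
  skip_if_not_installed("MASS")
  ref <- MASS::kde2d(occ[, 1], occ[, 2],
                     h = 4 * c(silverman_bw(occ[, 1]), silverman_bw(occ[, 2])),
                     n = 80, lims = c(bounds$x, bounds$y))
  refz <- ref$z / sum(ref$z)
  expect_lt(max(abs(g$z_occ - refz)), 1e-6)
})

test_that("Schoener's D obeys its identities and hand-computed values", {
  expect_equal(schoener_d(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  z <- matrix(runif(25), 5)
  expect_equal(schoener_d(z, z), 1)
  expect_equal(schoener_d(c(1, 0), c(0, 1)), 0)
  a <- runif(25); b <- runif(25)
  expect_equal(schoener_d(a, b), schoener_d(b, a))
  expect_error(schoener_d(matrix(1, 2, 2), matrix(1, 3, 3)), "mismatch")
  g1 <- fake_niche_grid(matrix(c(1, 0, 0, 0), 2))
  g2 <- fake_niche_grid(matrix(c(0, 0, 0, 1), 2))
  expect_equal(schoener_d(g1, g2), 0)
})

test_that("niche dynamics reproduce hand-evaluated expansion and unfilled", {
  # toy 3-cell masses: native (0.6, 0.4, 0), invaded (0, 0.3, 0.7)
  gn <- fake_niche_grid(matrix(c(0.6, 0.4, 0), 1))
  gi <- fake_niche_grid(matrix(c(0, 0.3, 0.7), 1))
  dyn <- niche_dynamics(gn, gi, correct = FALSE)
  expect_equal(dyn$expansion, 0.7)
  expect_equal(dyn$stability, 0.3)
  expect_equal(dyn$unfilled, 0.6)

  same <- niche_dynamics(gn, gn, correct = FALSE)
  expect_equal(same$expansion, 0)
  expect_equal(same$stability, 1)
  expect_equal(same$unfilled, 0)

  # disjoint supports: complete expansion, nothing shared, nothing filled
  gd1 <- fake_niche_grid(matrix(c(1, 0, 0, 0), 2))
  gd2 <- fake_niche_grid(matrix(c(0, 0, 0, 1), 2))
  ddyn <- niche_dynamics(gd1, gd2, correct = FALSE)
  expect_equal(unlist(ddyn), c(expansion = 1, stability = 0, unfilled = 1))
})

test_that("expansion and stability always sum to one across random niches", {
  set.seed(13)
  for (i in 1:20) {
    zn <- matrix(runif(36) * rbinom(36, 1, 0.6), 6)
    zi <- matrix(runif(36) * rbinom(36, 1, 0.6), 6)
    zn[1] <- zn[1] + 0.1; zi[36] <- zi[36] + 0.1  # keep masks non-empty
    dyn <- niche_dynamics(fake_niche_grid(zn), fake_niche_grid(zi),
                          correct = FALSE)
    expect_equal(dyn$expansion + dyn$stability, 1, tolerance = 1e-9)
    expect_true(all(unlist(dyn) >= 0 & unlist(dyn) <= 1))
  }
})

test_that("similarity test is seed-reproducible and internally consistent", {
  set.seed(61)
  bkg <- matrix(rnorm(2000), ncol = 2)
  occ_n <- matrix(rnorm(160, 0, 0.4), ncol = 2)
  occ_i <- matrix(rnorm(160, 0, 0.4), ncol = 2)
  bounds <- list(x = range(bkg[, 1]), y = range(bkg[, 2]))
  gn <- niche_grid(occ_n, bkg, bounds = bounds, R = 50)
  gi <- niche_grid(occ_i, bkg, bounds = bounds, R = 50)
  for (method in c("shift", "resample")) {
    s1 <- similarity_test(gn, gi, occ_n, occ_i, n_rand = 99,
                          method = method, seed = 4)
    s2 <- similarity_test(gn, gi, occ_n, occ_i, n_rand = 99,
                          method = method, seed = 4)
    expect_equal(s1$d_null, s2$d_null)
    expect_equal(s1$p, (sum(s1$d_null >= s1$d_obs) + 1) / 100)
    expect_gt(s1$p, 0); expect_lte(s1$p, 1)
  }
  # two tight identical niches overlap far more than random relocations:
  # the one-sided p hits its floor 1/(n_rand + 1)
  s <- similarity_test(gn, gi, occ_n, occ_i, n_rand = 99, method = "shift",
                       seed = 9)
  expect_equal(s$p, 1 / 100)
  expect_error(similarity_test(gn, gi, n_rand = 50), "n_rand")
})

test_that("climate profile differences are signed reference minus introduced", {
  d <- climate_profile_diff(c(1000, 1000), c(466, 466), variable = "rain")
  expect_equal(d$difference, 534)
  same <- climate_profile_diff(tibble::tibble(t = 1:5), tibble::tibble(t = 1:5))
  expect_equal(same$difference, 0)
  neg <- climate_profile_diff(tibble::tibble(t = c(10, 12)),
                              tibble::tibble(t = c(20, 30)))
  expect_lt(neg$difference, 0)
  multi <- climate_profile_diff(tibble::tibble(a = 1:4, b = c(2, 2, 2, 2)),
                                tibble::tibble(a = 5:8, b = c(1, 1, 1, 1)))
  expect_equal(multi$variable, c("a", "b"))
  expect_equal(multi$difference,
               multi$mean_international - multi$mean_australian)
})

test_that("the full overlap wrapper ties the pieces together", {
  scn <- make_shift_scenario(17, delta = 2, n_per_range = 250,
                             n_background = 1200)
  ov <- scenario_overlap(scn, R = 60, n_rand = 99, seed = 3)
  td <- tidy(ov)
  expect_named(td, c("D", "similarity_p", "expansion", "stability",
                     "unfilled"))
  expect_true(all(td >= 0 & td <= 1))
  expect_equal(td$expansion + td$stability, 1, tolerance = 1e-9)
  expect_equal(glance(ov)$n_rand, 99L)
})
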
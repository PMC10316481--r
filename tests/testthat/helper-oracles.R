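# Independent oracles and small fixture builders shared across tests.

# Bellman-Ford-style iterative relaxation over the 8-neighbour lattice:
# repeatedly relax every edge until no accumulated cost changes. Independent
# of the graph-based implementation.
oracle_accumulated_cost <- function(suit, sources, epsilon = 1e-3) {
  nr <- nrow(suit); nc <- ncol(suit)
  cond <- pmax(suit, epsilon)
  trav <- !is.na(suit) & cond > 0
  cost <- matrix(Inf, nr, nc)
  for (s in sources) {
    r <- (s - 1) %/% nc + 1; c <- (s - 1) %% nc + 1
    if (trav[r, c]) cost[r, c] <- 0
  }
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (!trav[r, c]) next
      for (k in seq_len(nrow(shifts))) {
        r2 <- r + shifts$dr[k]; c2 <- c + shifts$dc[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !trav[r2, c2]) next
        d <- if (shifts$dr[k] != 0 && shifts$dc[k] != 0) sqrt(2) else 1
        w <- 0.5 * (1 / cond[r, c] + 1 / cond[r2, c2]) * d
        if (cost[r2, c2] + w < cost[r, c] - 1e-15) {
          cost[r, c] <- cost[r2, c2] + w
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  as.vector(t(cost))
}

# Direct per-point MESS oracle: plain percentile logic, written independently
# of the vectorized implementation.
oracle_mess_point <- function(ref_df, point) {
  vals <- vapply(names(ref_df), function(v) {
    ref <- ref_df[[v]]; x <- point[[v]]
    n <- length(ref)
    f <- 100 * (sum(ref < x) + 0.5 * sum(ref == x)) / n
    if (x <= min(ref)) 100 * (x - min(ref)) / (max(ref) - min(ref))
    else if (x >= max(ref)) 100 * (max(ref) - x) / (max(ref) - min(ref))
    else if (f <= 50) 2 * f
    else 2 * (100 - f)
  }, numeric(1))
  list(value = min(vals), variable = names(ref_df)[which.min(vals)])
}

# Monte-Carlo oracle for the scenario truth D: both occupancy densities are
# products of per-axis Gaussians (availability x niche response), so D =
# E_f[min(1, g/f)] estimated by sampling from f.
oracle_truth_d_mc <- function(delta, widths = 1, env_shift_frac = 0,
                              n_draws = 1e6, seed = 1) {
  set.seed(seed)
  w <- rep_len(widths, 2)
  mu_n <- delta / sqrt(2); mu_a <- mu_n * env_shift_frac
  post <- function(a, c, w) {   # N(a,1) * N(c,w) product per axis
    v <- 1 / (1 + 1 / w^2)
    list(mu = v * (a + c / w^2), sd = sqrt(v))
  }
  f1 <- post(0, 0, w[1]); f2 <- post(0, 0, w[2])
  g1 <- post(mu_a, mu_n, w[1]); g2 <- post(mu_a, mu_n, w[2])
  x <- rnorm(n_draws, f1$mu, f1$sd); y <- rnorm(n_draws, f2$mu, f2$sd)
  lr <- dnorm(x, g1$mu, g1$sd, log = TRUE) + dnorm(y, g2$mu, g2$sd, log = TRUE) -
    dnorm(x, f1$mu, f1$sd, log = TRUE) - dnorm(y, f2$mu, f2$sd, log = TRUE)
  mean(pmin(1, exp(lr)))
}

# Minimal niche_grid stand-in for hand-crafted density examples.
fake_niche_grid <- function(z_occ, z_env = NULL, mask_quantile = 0) {
  z_occ <- as.matrix(z_occ)
  if (is.null(z_env)) z_env <- (z_occ > 0) / sum(z_occ > 0)
  z_cor <- ifelse(z_env > 0, z_occ / z_env, 0)
  z_cor <- z_cor / sum(z_cor)
  structure(list(gx = seq_len(nrow(z_occ)), gy = seq_len(ncol(z_occ)),
                 R = nrow(z_occ),
                 bounds = list(x = c(1, nrow(z_occ)), y = c(1, ncol(z_occ))),
                 z_occ = z_occ / sum(z_occ), z_env = z_env, z_cor = z_cor,
                 mask_quantile = mask_quantile,
                 occupancy = z_cor > 0),
            class = "niche_grid")
}

write_occ_fixture <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                                 .local_envir = parent.frame())) {
  readr::write_csv(rows, path)
  path
}

occ_rows <- function(lon, lat, unc = NA_real_, species = "sp") {
  tibble::tibble(species = species, decimalLongitude = lon,
                 decimalLatitude = lat,
                 coordinateUncertaintyInMeters = unc, source = "test")
}
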
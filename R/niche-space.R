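#' Calibrate a PCA on the pooled environmental space of two ranges
#'
#' Variables are standardized to zero mean and unit variance over the pooled
#' rows before the eigen-decomposition (a correlation PCA), so the resulting
#' axes weight all variables equally. Components are ordered by decreasing
#' eigenvalue with a deterministic sign convention: within each component the
#' largest-magnitude loading is positive.
#'
#' @param env1,env2 Point-by-variable matrices or data frames with identical
#'   columns -- typically the background environments of the reference and
#'   introduced ranges.
#' @return An object of class `env_pca` with elements `means`, `sds`,
#'   `loadings` (orthonormal columns), and `explained` (variance fractions).
#' @export
calibrate_pca <- function(env1, env2) {
  x1 <- as.matrix(env1); x2 <- as.matrix(env2)
  stopifnot(identical(colnames(x1), colnames(x2)))
  x <- rbind(x1, x2)
  if (nrow(x) < ncol(x)) stop("fewer pooled rows than variables")
  means <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x, center = means, scale = sds)
  eig <- eigen(stats::cov(xs), symmetric = TRUE)
  load <- eig$vectors
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(list(means = means, sds = sds, loadings = load,
                 explained = pmax(eig$values, 0) / sum(pmax(eig$values, 0))),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d variables; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$means), 100 * x$explained[1],
              100 * (x$explained[2] %||% 0)))
  invisible(x)
}

#' Project environments onto PCA axes
#'
#' @param object An [calibrate_pca()] fit.
#' @param newdata Point-by-variable matrix or data frame (model variables
#'   must all be present).
#' @param n_axes Number of leading components to return (default 2, the
#'   niche-space convention used throughout).
#' @param ... Unused.
#' @return A tibble of scores with columns `PC1`, `PC2`, ...
#' @export
predict.env_pca <- function(object, newdata, n_axes = 2, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[, names(object$means)])
  xs <- scale(x, center = object$means, scale = object$sds)
  sc <- xs %*% object$loadings[, seq_len(n_axes), drop = FALSE]
  tibble::as_tibble(sc)
}

# ---- kernel density on the niche grid ---------------------------------------

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, the per-axis rule used for the
#' product kernel on the niche grid.
#'
#' @param x Numeric vector.
#' @return Bandwidth (> 0).
#' @export
silverman_bw <- function(x) {
  n <- length(x)
  s <- min(stats::sd(x), stats::IQR(x) / 1.34)
  if (s == 0) s <- stats::sd(x)
  if (s == 0 || !is.finite(s)) stop("bandwidth undefined: degenerate sample")
  0.9 * s * n^(-1/5)
}

# Truncated-Gaussian product-kernel density on a regular grid.
# Truncation at `truncate` bandwidths gives the estimate genuinely compact
# support, which the occupancy masks rely on. Returns an R x R matrix
# (x along rows, y along columns) scaled to sum 1.
kde_on_grid <- function(x, y, gx, gy, hx, hy, truncate = 5) {
  Gx <- stats::dnorm(outer(gx, x, "-") / hx)
  Gx[abs(outer(gx, x, "-")) > truncate * hx] <- 0
  Gy <- stats::dnorm(outer(gy, y, "-") / hy)
  Gy[abs(outer(gy, y, "-")) > truncate * hy] <- 0
  z <- Gx %*% t(Gy)
  s <- sum(z)
  if (s == 0) stop("kernel density is zero everywhere on the grid")
  z / s
}

#' Kernel-smoothed occurrence and background densities in niche space
#'
#' Builds the R x R environmental-space grid for one range: `z_occ`, the
#' kernel density of the occurrence scores; `z_env`, the kernel density of
#' the background (available) environments; and `z_cor`, the
#' availability-corrected occupancy `z_occ / z_env` on cells with available
#' environment, renormalized. A Gaussian product kernel with Silverman's
#' bandwidth per axis is used, truncated at `kernel_truncate` bandwidths so
#' densities have compact support.
#'
#' @param occ_scores,bkg_scores Two-column (PC1, PC2) tibbles or matrices.
#' @param bounds Optional list with `x` and `y` ranges. Defaults to the
#'   background extent plus a 5% margin; pass shared bounds when two ranges
#'   must live on the same grid (see [niche_overlap()]).
#' @param R Grid resolution per axis (default 100).
#' @param margin Fractional margin added to default bounds.
#' @param mask_quantile Occupancy-mask threshold: cells whose corrected
#'   density exceeds this quantile of the positive densities are "occupied".
#'   The default 0 keeps the full support of the (truncated) kernel.
#' @param kernel_truncate Kernel support radius in bandwidths.
#' @param env_floor_quantile Stabilizer for the availability correction: the
#'   background density is floored at this quantile of its positive values
#'   before dividing, so near-zero availability at the edge of the
#'   background envelope cannot blow up the occupancy ratio.
#' @return An object of class `niche_grid`.
#' @export
niche_grid <- function(occ_scores, bkg_scores, bounds = NULL, R = 100,
                       margin = 0.05, mask_quantile = 0,
                       kernel_truncate = 5, env_floor_quantile = 0.05) {
  oc <- as.matrix(occ_scores); bk <- as.matrix(bkg_scores)
  if (nrow(oc) < 5) stop("need at least 5 occurrence points for a bandwidth")
  if (is.null(bounds)) {
    rx <- range(bk[, 1]); ry <- range(bk[, 2])
    bounds <- list(x = rx + c(-1, 1) * margin * diff(rx),
                   y = ry + c(-1, 1) * margin * diff(ry))
  }
  gx <- seq(bounds$x[1], bounds$x[2], length.out = R)
  gy <- seq(bounds$y[1], bounds$y[2], length.out = R)
  h_occ <- c(silverman_bw(oc[, 1]), silverman_bw(oc[, 2]))
  h_bkg <- c(silverman_bw(bk[, 1]), silverman_bw(bk[, 2]))
  z_occ <- kde_on_grid(oc[, 1], oc[, 2], gx, gy, h_occ[1], h_occ[2],
                       kernel_truncate)
  z_env <- kde_on_grid(bk[, 1], bk[, 2], gx, gy, h_bkg[1], h_bkg[2],
                       kernel_truncate)
  env_floor <- stats::quantile(z_env[z_env > 0], env_floor_quantile,
                               names = FALSE)
  z_cor <- ifelse(z_env > 0, z_occ / pmax(z_env, env_floor), 0)
  if (sum(z_cor) == 0) stop("occurrence density lies entirely outside the background envelope")
  z_cor <- z_cor / sum(z_cor)
  structure(list(gx = gx, gy = gy, R = R, bounds = bounds,
                 z_occ = z_occ, z_env = z_env, z_cor = z_cor,
                 bw_occ = h_occ, bw_bkg = h_bkg,
                 mask_quantile = mask_quantile,
                 occupancy = density_mask(z_cor, mask_quantile)),
            class = "niche_grid")
}

# Occupancy mask: support of z, optionally raised to a quantile of the
# positive densities.
density_mask <- function(z, quantile = 0) {
  if (quantile <= 0) return(z > 0)
  thr <- stats::quantile(z[z > 0], probs = quantile, names = FALSE)
  z >= thr
}

#' @export
print.niche_grid <- function(x, ...) {
  cat(sprintf("<niche_grid> %d x %d cells, occupancy over %d cells (%.1f%%)\n",
              x$R, x$R, sum(x$occupancy), 100 * mean(x$occupancy)))
  invisible(x)
}

#' @describeIn niche_grid Long-format tibble of grid densities.
#' @param x A `niche_grid`.
#' @param ... Unused.
#' @method as_tibble niche_grid
#' @export
as_tibble.niche_grid <- function(x, ...) {
  tibble::tibble(
    pc1 = rep(x$gx, times = x$R), pc2 = rep(x$gy, each = x$R),
    z_occ = as.vector(x$z_occ), z_env = as.vector(x$z_env),
    z_cor = as.vector(x$z_cor), occupied = as.vector(x$occupancy))
}

grid_z <- function(g, correct = TRUE) if (correct) g$z_cor else g$z_occ

# ---- overlap and dynamics ---------------------------------------------------

#' Schoener's D overlap between two density grids
#'
#' `D = 1 - 0.5 * sum(|zA - zB|)`, computed after renormalizing each density
#' to unit mass; 0 means completely disjoint niches, 1 identical ones.
#'
#' @param zA,zB [niche_grid()] objects (their corrected densities are
#'   compared; set `correct = FALSE` for the uncorrected occurrence
#'   densities) or plain non-negative matrices/vectors on a shared grid.
#' @param correct Use availability-corrected densities when grids are given.
#' @return D in `[0, 1]`.
#' @export
schoener_d <- function(zA, zB, correct = TRUE) {
  if (inherits(zA, "niche_grid") || inherits(zB, "niche_grid")) {
    stopifnot(inherits(zA, "niche_grid"), inherits(zB, "niche_grid"))
    if (!isTRUE(all.equal(zA$bounds, zB$bounds)) || zA$R != zB$R)
      stop("niche grids are not on the same bounds/resolution")
    zA <- grid_z(zA, correct); zB <- grid_z(zB, correct)
  }
  if (!identical(dim(zA), dim(zB)) || length(zA) != length(zB))
    stop("density grids have mismatched dimensions")
  zA <- zA / sum(zA); zB <- zB / sum(zB)
  1 - 0.5 * sum(abs(zA - zB))
}

#' Niche expansion, stability and unfilled indices
#'
#' Expansion is the introduced-range density mass lying outside the
#' reference range's occupancy; stability is its complement
#' (`expansion + stability = 1`); unfilled is the reference-range density
#' mass outside the introduced range's occupancy. With
#' `analogue_only = TRUE` all masses are restricted to analogue
#' environments, i.e. grid cells available in both backgrounds.
#'
#' @param native,invaded [niche_grid()] objects on shared bounds
#'   (reference and introduced ranges).
#' @param analogue_only Restrict to mutually available environments.
#' @param correct Use availability-corrected densities.
#' @return A one-row tibble with `expansion`, `stability`, `unfilled`.
#' @export
niche_dynamics <- function(native, invaded, analogue_only = FALSE,
                           correct = TRUE) {
  stopifnot(inherits(native, "niche_grid"), inherits(invaded, "niche_grid"))
  if (!isTRUE(all.equal(native$bounds, invaded$bounds)) ||
      native$R != invaded$R)
    stop("niche grids are not on the same bounds/resolution")
  zn <- grid_z(native, correct); zi <- grid_z(invaded, correct)
  mask_n <- density_mask(zn, native$mask_quantile)
  mask_i <- density_mask(zi, invaded$mask_quantile)
  if (!any(mask_n) || !any(mask_i)) stop("empty occupancy mask")
  dom <- if (analogue_only) native$z_env > 0 & invaded$z_env > 0
         else matrix(TRUE, nrow(zn), ncol(zn))
  zi_tot <- sum(zi[dom]); zn_tot <- sum(zn[dom])
  if (zi_tot == 0 || zn_tot == 0)
    stop("no density mass in the analogue environment")
  expansion <- sum(zi[dom & !mask_n]) / zi_tot
  unfilled <- sum(zn[dom & !mask_i]) / zn_tot
  tibble::tibble(expansion = expansion, stability = 1 - expansion,
                 unfilled = unfilled)
}

#' Quantify niche overlap and dynamics between two ranges
#'
#' The full environmental-space comparison for one species: a PCA calibrated
#' on the pooled backgrounds of both ranges, kernel density grids on shared
#' bounds, Schoener's D, the expansion/stability/unfilled indices, and
#' (optionally) the randomization similarity test.
#'
#' @param occ_env_native,occ_env_invaded Point-by-variable environment values
#'   at the occurrences of each range.
#' @param bkg_env_native,bkg_env_invaded Background environments of each
#'   range (e.g. all cells of the respective stacks).
#' @param R Niche-grid resolution.
#' @param correct Use availability-corrected densities (the default;
#'   `FALSE` compares raw occurrence densities).
#' @param mask_quantile Occupancy threshold passed to [niche_grid()].
#' @param analogue_only Restrict dynamics to analogue environments.
#' @param n_rand Similarity-test replicates (0 skips the test).
#' @param similarity_method Null model for the similarity test, see
#'   [similarity_test()].
#' @param seed Seed for the similarity test.
#' @return An object of class `niche_overlap`; see [tidy.niche_overlap()].
#' @export
niche_overlap <- function(occ_env_native, occ_env_invaded,
                          bkg_env_native, bkg_env_invaded,
                          R = 100, correct = TRUE, mask_quantile = 0,
                          analogue_only = FALSE, n_rand = 0,
                          similarity_method = c("shift", "resample"),
                          seed = NULL) {
  pca <- calibrate_pca(bkg_env_native, bkg_env_invaded)
  sc <- function(x) predict(pca, x)
  bn <- sc(bkg_env_native); bi <- sc(bkg_env_invaded)
  pooled <- rbind(as.matrix(bn), as.matrix(bi))
  rx <- range(pooled[, 1]); ry <- range(pooled[, 2])
  bounds <- list(x = rx + c(-1, 1) * 0.05 * diff(rx),
                 y = ry + c(-1, 1) * 0.05 * diff(ry))
  gn <- niche_grid(sc(occ_env_native), bn, bounds = bounds, R = R,
                   mask_quantile = mask_quantile)
  gi <- niche_grid(sc(occ_env_invaded), bi, bounds = bounds, R = R,
                   mask_quantile = mask_quantile)
  dyn <- niche_dynamics(gn, gi, analogue_only = analogue_only,
                        correct = correct)
  sim <- NULL
  if (n_rand > 0)
    sim <- similarity_test(gn, gi,
                           occ_scores_native = sc(occ_env_native),
                           occ_scores_invaded = sc(occ_env_invaded),
                           n_rand = n_rand,
                           method = match.arg(similarity_method),
                           correct = correct, seed = seed)
  structure(list(pca = pca, native = gn, invaded = gi,
                 D = schoener_d(gn, gi, correct = correct),
                 dynamics = dyn, similarity = sim, correct = correct),
            class = "niche_overlap")
}

#' @export
print.niche_overlap <- function(x, ...) {
  cat(sprintf("<niche_overlap> D = %.3f; expansion %.3f, stability %.3f, unfilled %.3f\n",
              x$D, x$dynamics$expansion, x$dynamics$stability,
              x$dynamics$unfilled))
  if (!is.null(x$similarity))
    cat(sprintf("  similarity test (%s null): p = %.4g over %d randomizations\n",
                x$similarity$method, x$similarity$p, x$similarity$n_rand))
  invisible(x)
}

#' @rdname niche_overlap
#' @param x A `niche_overlap` object.
#' @param ... Unused.
#' @method tidy niche_overlap
#' @export
tidy.niche_overlap <- function(x, ...) {
  tibble::tibble(
    D = x$D,
    similarity_p = if (is.null(x$similarity)) NA_real_ else x$similarity$p,
    expansion = x$dynamics$expansion,
    stability = x$dynamics$stability,
    unfilled = x$dynamics$unfilled)
}

#' @rdname niche_overlap
#' @method glance niche_overlap
#' @export
glance.niche_overlap <- function(x, ...) {
  tibble::tibble(
    R = x$native$R, corrected = x$correct,
    pc1_explained = x$pca$explained[1], pc2_explained = x$pca$explained[2],
    n_rand = if (is.null(x$similarity)) 0L else x$similarity$n_rand)
}

# ---- similarity randomization test ------------------------------------------

#' Randomization test for niche similarity
#'
#' Compares the observed Schoener's D with a null distribution obtained by
#' randomizing the introduced range, and reports the one-sided p-value for
#' the "more similar than random" alternative,
#' `p = (count(D_null >= D_obs) + 1) / (n_rand + 1)`.
#'
#' Two nulls are implemented. `"shift"` (default) relocates the whole
#' introduced-range occurrence density to a random position within its
#' background envelope and recomputes D -- a range-shift null asking whether
#' the observed overlap exceeds what an arbitrarily positioned niche would
#' give. `"resample"` randomly reassigns the pooled occurrence points to the
#' two ranges (an exchangeable permutation null; densities are rebuilt per
#' replicate with the pooled-sample bandwidth, uncorrected or corrected as
#' requested). The shift null has power against same-niche data and is not
#' exchangeable under it; only the resampling null is size-calibrated when
#' both ranges truly sample one niche.
#'
#' @param native,invaded [niche_grid()] objects on shared bounds.
#' @param occ_scores_native,occ_scores_invaded The PC scores of the two
#'   occurrence sets (required for the `"resample"` null).
#' @param n_rand Number of randomizations (>= 99).
#' @param method `"shift"` or `"resample"`.
#' @param correct Use availability-corrected densities.
#' @param seed Optional integer seed (reproducible null).
#' @return An object of class `similarity_test`: list with `p`, `d_obs`,
#'   `d_null`, `method`, `n_rand`.
#' @export
similarity_test <- function(native, invaded,
                            occ_scores_native = NULL,
                            occ_scores_invaded = NULL,
                            n_rand = 1000,
                            method = c("shift", "resample"),
                            correct = TRUE, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n_rand >= 99)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (method == "shift") {
    d_obs <- schoener_d(native, invaded, correct = correct)
    d_null <- shift_null_d(native, invaded, n_rand, correct)
  } else {
    if (is.null(occ_scores_native) || is.null(occ_scores_invaded))
      stop("the resample null needs the occurrence scores of both ranges")
    dd <- resample_null_d(native, invaded,
                          as.matrix(occ_scores_native),
                          as.matrix(occ_scores_invaded), n_rand, correct)
    d_obs <- dd$d_obs; d_null <- dd$d_null
  }
  structure(list(p = (sum(d_null >= d_obs) + 1) / (n_rand + 1),
                 d_obs = d_obs, d_null = d_null,
                 method = method, n_rand = n_rand),
            class = "similarity_test")
}

#' @export
print.similarity_test <- function(x, ...) {
  cat(sprintf("<similarity_test> %s null, %d randomizations: D_obs = %.3f, p = %.4g\n",
              x$method, x$n_rand, x$d_obs, x$p))
  invisible(x)
}

# Shift null: translate the invaded occurrence density so its mass centroid
# lands on a random background cell; mass shifted off-grid is dropped.
shift_null_d <- function(native, invaded, n_rand, correct) {
  zn <- grid_z(native, correct)
  R <- invaded$R
  zo <- invaded$z_occ
  w <- zo / sum(zo)
  ci <- round(sum(row(zo) * w)); cj <- round(sum(col(zo) * w))
  targets <- which(invaded$z_env > 0, arr.ind = TRUE)
  pick <- targets[sample.int(nrow(targets), n_rand, replace = TRUE), ,
                  drop = FALSE]
  vapply(seq_len(n_rand), function(k) {
    di <- pick[k, 1] - ci; dj <- pick[k, 2] - cj
    zs <- matrix(0, R, R)
    src_i <- seq_len(R) - di; src_j <- seq_len(R) - dj
    ok_i <- src_i >= 1 & src_i <= R; ok_j <- src_j >= 1 & src_j <= R
    zs[ok_i, ok_j] <- zo[src_i[ok_i], src_j[ok_j]]
    if (correct) zs <- ifelse(invaded$z_env > 0, zs / invaded$z_env, 0)
    if (sum(zs) == 0) return(0)
    schoener_d(zn, zs)
  }, numeric(1))
}

# Resample null: permute pooled point labels; densities rebuilt with the
# pooled-sample bandwidth via one kernel-basis matrix, so each replicate is
# two matrix products.
resample_null_d <- function(native, invaded, sc_n, sc_i, n_rand, correct) {
  R <- native$R
  pts <- rbind(sc_n, sc_i)
  n1 <- nrow(sc_n); n <- nrow(pts)
  hx <- silverman_bw(pts[, 1]); hy <- silverman_bw(pts[, 2])
  gx <- native$gx; gy <- native$gy
  Gx <- stats::dnorm(outer(gx, pts[, 1], "-") / hx)
  Gx[abs(outer(gx, pts[, 1], "-")) > 5 * hx] <- 0
  Gy <- stats::dnorm(outer(gy, pts[, 2], "-") / hy)
  Gy[abs(outer(gy, pts[, 2], "-")) > 5 * hy] <- 0
  # per-point kernel basis over all R^2 cells (cells vary fastest over gx)
  K <- Gx[rep(seq_len(R), times = R), ] * Gy[rep(seq_len(R), each = R), ]
  if (correct) {
    # availability correction is a per-cell row scaling of the basis
    env_n <- as.vector(grid_env_for(native))
    env_i <- as.vector(grid_env_for(invaded))
    Kn <- K * ifelse(env_n > 0, 1 / env_n, 0)
    Ki <- K * ifelse(env_i > 0, 1 / env_i, 0)
  } else {
    Kn <- K; Ki <- K
  }
  W <- matrix(0, n, n_rand + 1)
  W[seq_len(n1), 1] <- 1
  for (k in seq_len(n_rand)) W[sample.int(n, n1), k + 1] <- 1
  Z1 <- Kn %*% W
  Z2 <- Ki %*% (1 - W)
  s1 <- colSums(Z1); s2 <- colSums(Z2)
  if (any(s1 == 0) || any(s2 == 0))
    stop("a resampled density fell entirely outside the background envelope")
  d_all <- 1 - 0.5 * colSums(abs(sweep(Z1, 2, s1, "/") -
                                   sweep(Z2, 2, s2, "/")))
  list(d_obs = d_all[1], d_null = d_all[-1])
}

grid_env_for <- function(g) g$z_env

# ---- per-variable niche profiles --------------------------------------------

#' Per-variable climate profile differences between two ranges
#'
#' Arithmetic means of each variable over the occurrences of the reference
#' (international) and introduced (e.g. Australian) ranges, and their signed
#' difference, reference minus introduced: a positive difference means the
#' introduced range is lower in that variable.
#'
#' @param env_international,env_australian Point-by-variable environment
#'   values at the occurrences of each range (data frames with matching
#'   columns), or two numeric vectors for a single variable.
#' @param variable Variable label used when vectors are given.
#' @return A tibble with `variable`, `mean_international`,
#'   `mean_australian`, `difference`.
#' @export
climate_profile_diff <- function(env_international, env_australian,
                                 variable = "variable") {
  if (is.numeric(env_international) && is.null(dim(env_international))) {
    env_international <- tibble::tibble(!!variable := env_international)
    env_australian <- tibble::tibble(!!variable := env_australian)
  }
  a <- tibble::as_tibble(env_international)
  b <- tibble::as_tibble(env_australian)
  stopifnot(identical(names(a), names(b)), nrow(a) > 0, nrow(b) > 0)
  tibble::tibble(
    variable = names(a),
    mean_international = unname(purrr::map_dbl(a, mean)),
    mean_australian = unname(purrr::map_dbl(b, mean))) |>
    dplyr::mutate(difference = .data$mean_international - .data$mean_australian)
}
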
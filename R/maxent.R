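#' Feature expansion for maximum-entropy modeling
#'
#' Defines the feature classes over named variables: linear, quadratic,
#' pairwise product, and hinge (forward and reverse, `n_knots` knots per
#' variable on an even grid). Variables are rescaled to `[0, 1]` using the
#' background minimum/maximum (values outside are clamped at prediction
#' time), so every feature lies in `[0, 1]` over the background. With
#' `classes = "auto"` the classes enabled follow the conventional
#' presence-count rules: `< 10` linear only; `< 15` adds quadratic; `< 80`
#' adds hinge; otherwise also product. Threshold features are not built;
#' hinge features subsume them.
#'
#' @param background_env Point-by-variable background environments (sets the
#'   normalization bounds).
#' @param n_presence Presence count used by the auto rules.
#' @param classes `"auto"` or a string of class letters among `"lqph"`.
#' @param n_knots Hinge knots per variable and direction.
#' @return An object of class `maxent_features`.
#' @export
maxent_features <- function(background_env, n_presence,
                            classes = "auto", n_knots = 50) {
  bk <- as.matrix(background_env)
  if (classes == "auto") {
    classes <- if (n_presence < 10) "l"
    else if (n_presence < 15) "lq"
    else if (n_presence < 80) "lqh"
    else "lqph"
  }
  stopifnot(grepl("^[lqph]+$", classes))
  structure(list(
    vars = colnames(bk),
    lower = apply(bk, 2, min), upper = apply(bk, 2, max),
    classes = strsplit(classes, "")[[1]],
    knots = seq(0, 1, length.out = n_knots + 2)[2:(n_knots + 1)]),
    class = "maxent_features")
}

# Normalize raw variables to [0,1] over the background bounds; clamping
# outside the bounds is counted and reported via attribute.
normalize01 <- function(fe, X) {
  X <- as.matrix(tibble::as_tibble(X)[, fe$vars])
  rng <- pmax(fe$upper - fe$lower, .Machine$double.eps)
  V <- sweep(sweep(X, 2, fe$lower), 2, rng, "/")
  clamped <- sum(V < 0 | V > 1)
  V[V < 0] <- 0; V[V > 1] <- 1
  attr(V, "n_clamped") <- clamped
  V
}

# Build the design matrix; columns carry a "class" attribute for the
# per-class regularization.
feature_matrix <- function(fe, X) {
  V <- normalize01(fe, X)
  cols <- list(); cls <- character()
  p <- length(fe$vars)
  if ("l" %in% fe$classes) {
    cols <- c(cols, list(V))
    cls <- c(cls, rep("l", p))
  }
  if ("q" %in% fe$classes) {
    Q <- V^2; colnames(Q) <- paste0(fe$vars, "^2")
    cols <- c(cols, list(Q)); cls <- c(cls, rep("q", p))
  }
  if ("p" %in% fe$classes && p >= 2) {
    pr <- utils::combn(p, 2)
    P <- V[, pr[1, ], drop = FALSE] * V[, pr[2, ], drop = FALSE]
    colnames(P) <- paste0(fe$vars[pr[1, ]], ":", fe$vars[pr[2, ]])
    cols <- c(cols, list(P)); cls <- c(cls, rep("p", ncol(P)))
  }
  if ("h" %in% fe$classes) {
    for (j in seq_len(p)) {
      Hf <- vapply(fe$knots, function(k) pmax(0, (V[, j] - k) / (1 - k)),
                   numeric(nrow(V)))
      Hr <- vapply(fe$knots, function(k) pmax(0, (k - V[, j]) / k),
                   numeric(nrow(V)))
      colnames(Hf) <- sprintf("h(%s>%0.3f)", fe$vars[j], fe$knots)
      colnames(Hr) <- sprintf("h(%s<%0.3f)", fe$vars[j], fe$knots)
      cols <- c(cols, list(Hf), list(Hr))
      cls <- c(cls, rep("h", ncol(Hf) + ncol(Hr)))
    }
  }
  M <- do.call(cbind, cols)
  if (any(!is.finite(M))) stop("non-finite feature values")
  attr(M, "class_of") <- cls
  attr(M, "n_clamped") <- attr(V, "n_clamped")
  M
}

# Default per-class regularization, interpolated over presence counts.
reg_betas <- function(cls, n_presence) {
  ip <- function(x, y) stats::approx(x, y, n_presence, rule = 2)$y
  vapply(cls, function(cl) switch(cl,
    l = ip(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05)),
    q = ip(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05)),
    p = ip(c(0, 10, 17, 30, 100), c(2.6, 1.6, 0.9, 0.55, 0.05)),
    h = 0.5), numeric(1))
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit a maximum-entropy suitability model
#'
#' Maximizes the L1-penalized presence log-likelihood of the Gibbs
#' distribution over the background,
#' `mean(presence eta) - log sum(exp(background eta)) - sum(penalty * |lambda|)`,
#' by proximal-gradient ascent with a monotone backtracking line search.
#' Per-feature penalties follow the published default per-class
#' regularization tables, scaled by the class beta, the presence-feature
#' standard deviation and `1/sqrt(n_presence)`, times `reg_multiplier`.
#'
#' @param presence_env,background_env Point-by-variable environment values.
#' @param features A [maxent_features()]; built automatically when `NULL`.
#' @param reg_multiplier Scales all penalties (0 = unpenalized).
#' @param classes,n_knots Passed to [maxent_features()] when building.
#' @param tol Convergence tolerance on the penalized objective.
#' @param max_iter Iteration cap (warns on non-convergence).
#' @return An object of class `maxent_model` with the fitted weights, the
#'   training-background raw distribution, its entropy, and the objective
#'   trace.
#' @export
fit_maxent <- function(presence_env, background_env, features = NULL,
                       reg_multiplier = 1, classes = "auto", n_knots = 50,
                       tol = 1e-6, max_iter = 500) {
  np <- nrow(tibble::as_tibble(presence_env))
  if (np < 5) stop("need at least 5 presences")
  if (is.null(features))
    features <- maxent_features(background_env, np, classes = classes,
                                n_knots = n_knots)
  Fp <- feature_matrix(features, presence_env)
  Fb <- feature_matrix(features, background_env)
  if (nrow(Fb) < np) stop("background must be at least as large as presences")
  cls <- attr(Fp, "class_of")
  sds <- apply(Fp, 2, stats::sd)
  penalty <- reg_multiplier * reg_betas(cls, np) *
    pmax(sds, 1e-3) / sqrt(np)

  fbar <- colMeans(Fp)
  m <- ncol(Fp)
  lambda <- numeric(m)
  obj <- function(l) {
    mean(Fp %*% l) - logsumexp(Fb %*% l) - sum(penalty * abs(l))
  }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  cur <- obj(lambda)
  trace <- cur
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta_b <- as.vector(Fb %*% lambda)
    q <- exp(eta_b - logsumexp(eta_b))
    g <- fbar - as.vector(crossprod(Fb, q))
    improved <- FALSE
    for (try in 1:60) {
      cand <- soft(lambda + step * g, step * penalty)
      val <- obj(cand)
      if (val >= cur) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    delta <- val - cur
    lambda <- cand; cur <- val
    trace <- c(trace, cur)
    step <- step * 1.2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("maxent fit did not converge in %d iterations (last objective change %.3g)",
                    max_iter, trace[length(trace)] - trace[length(trace) - 1]))
  names(lambda) <- colnames(Fp)
  eta_b <- as.vector(Fb %*% lambda)
  logZ <- logsumexp(eta_b)
  q <- exp(eta_b - logZ)
  H <- -sum(q[q > 0] * log(q[q > 0]))
  structure(list(features = features, lambda = lambda, penalty = penalty,
                 feature_class = cls, logZ = logZ, q_background = q,
                 entropy = H, trace = trace, converged = converged,
                 n_presence = np, vars = features$vars),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d features over %d variables (%d active), entropy %.3f\n",
              length(x$lambda), length(x$vars), sum(x$lambda != 0), x$entropy))
  invisible(x)
}

#' @rdname fit_maxent
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(term = names(x$lambda), class = x$feature_class,
                 estimate = unname(x$lambda), penalty = unname(x$penalty))
}

#' @rdname fit_maxent
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence,
                 n_features = length(x$lambda),
                 n_active = sum(x$lambda != 0),
                 entropy = x$entropy,
                 objective = x$trace[length(x$trace)],
                 iterations = length(x$trace) - 1L,
                 converged = x$converged)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' `"raw"` is the Gibbs density normalized to sum 1 over the prediction
#' cells; `"cumulative"` is the percentage of total raw mass at cells with a
#' raw value less than or equal to the cell's (so the maximum-raw cell is
#' 100); `"logistic"` is the conventional `[0, 1]` suitability index derived
#' from the training-background entropy. Values outside the feature
#' normalization bounds are clamped (counted in `attr(, "n_clamped")`).
#'
#' @param object A [fit_maxent()] model.
#' @param newdata An [env_stack()] (all model variables must be layers) or a
#'   point-by-variable matrix/data frame.
#' @param type `"raw"`, `"cumulative"`, `"logistic"`, or `"link"` (the
#'   linear predictor).
#' @param ... Unused.
#' @return For an `env_stack`, a one-layer `env_stack` named after `type`;
#'   otherwise a numeric vector.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "cumulative",
                                          "link"), ...) {
  type <- match.arg(type)
  is_stack <- inherits(newdata, "env_stack")
  if (is_stack) {
    missing <- setdiff(object$vars, newdata$layer_names)
    if (length(missing))
      stop("missing layer(s): ", paste(missing, collapse = ", "))
    X <- newdata$values[!newdata$nodata_mask, object$vars, drop = FALSE]
  } else {
    X <- tibble::as_tibble(newdata)[, object$vars]
  }
  M <- feature_matrix(object$features, X)
  eta <- as.vector(M %*% object$lambda)
  out <- switch(type,
    link = eta,
    raw = exp(eta - logsumexp(eta)),
    cumulative = {
      raw <- exp(eta - logsumexp(eta))
      100 * vapply(raw, function(r) sum(raw[raw <= r]), numeric(1))
    },
    logistic = {
      qx <- exp(eta - object$logZ)
      eh <- exp(object$entropy)
      eh * qx / (1 + eh * qx)
    })
  if (is_stack) {
    v <- rep(NA_real_, n_cells(newdata$grid))
    v[!newdata$nodata_mask] <- out
    res <- env_stack(newdata$grid, matrix(v, ncol = 1), layer_names = type,
                     nodata_mask = newdata$nodata_mask)
  } else res <- out
  attr(res, "n_clamped") <- attr(M, "n_clamped")
  res
}

#' Threshold a cumulative-output layer into suitable habitat
#'
#' Suitable habitat is every cell with cumulative output at or above `c`;
#' the conventional "fixed cumulative value 10" rule uses `c = 10`, chosen
#' to keep even marginally suitable habitat.
#'
#' @param cumulative A one-layer [env_stack()] of cumulative output (0-100),
#'   or a numeric vector/matrix.
#' @param c Cumulative threshold.
#' @return Logical mask with the same shape (NA on nodata cells of a stack).
#' @export
threshold_cumulative <- function(cumulative, c = 10) {
  if (inherits(cumulative, "env_stack")) {
    v <- cumulative$values[, 1]
    out <- v >= c
    out[cumulative$nodata_mask] <- NA
    return(out)
  }
  cumulative >= c
}

# Rank-based two-sample AUC (probability a presence outscores a background
# point, ties counted half).
auc_scores <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Cross-validated AUC for a maximum-entropy model
#'
#' Presences are assigned to `k` folds (seeded); each fold is held out in
#' turn, the model is refitted on the remainder, and the AUC of the held-out
#' presences against the background is computed on the linear predictor.
#'
#' @param presence_env,background_env Point-by-variable environment values.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [fit_maxent()].
#' @return An object of class `maxent_cv`: tibble of fold AUCs plus
#'   `mean_auc`.
#' @export
maxent_cv <- function(presence_env, background_env, k = 10, seed = NULL,
                      ...) {
  pres <- tibble::as_tibble(presence_env)
  np <- nrow(pres)
  if (np < k) stop(sprintf("only %d presences for %d folds; use smaller k",
                           np, k))
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = np))
  aucs <- purrr::map_dbl(seq_len(k), function(i) {
    fit <- fit_maxent(pres[fold != i, ], background_env, ...)
    auc_scores(predict(fit, pres[fold == i, ], type = "link"),
               predict(fit, background_env, type = "link"))
  })
  structure(list(folds = tibble::tibble(fold = seq_len(k), auc = aucs),
                 mean_auc = mean(aucs), k = k),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("<maxent_cv> %d folds, mean AUC %.3f (range %.3f-%.3f)\n",
              x$k, x$mean_auc, min(x$folds$auc), max(x$folds$auc)))
  invisible(x)
}

#' @rdname maxent_cv
#' @param x A `maxent_cv`.
#' @param ... Unused.
#' @method tidy maxent_cv
#' @export
tidy.maxent_cv <- function(x, ...) x$folds

#' @rdname maxent_cv
#' @method glance maxent_cv
#' @export
glance.maxent_cv <- function(x, ...) {
  tibble::tibble(k = x$k, mean_auc = x$mean_auc, sd_auc = stats::sd(x$folds$auc))
}

#' Permutation-importance variable selection
#'
#' Permutation importance of a variable is the drop in training AUC when
#' that variable's values are permuted across the pooled presence and
#' background points (averaged over `n_perm` seeded permutations, negative
#' drops truncated at zero), normalized so the importances sum to 100.
#' Variables above `min_importance_pct` are retained and the model refitted
#' on them.
#'
#' @param presence_env,background_env Point-by-variable environment values.
#' @param model Optional prefitted [fit_maxent()] model on all variables.
#' @param min_importance_pct Retention cutoff in percent (default 1).
#' @param n_perm Permutations per variable.
#' @param seed Seed for the permutations.
#' @param ... Passed to [fit_maxent()] for the refit (and initial fit).
#' @return An object of class `maxent_selection`: the refitted `model`, the
#'   `importance` tibble, and the `selected` variable labels.
#' @export
select_variables <- function(presence_env, background_env, model = NULL,
                             min_importance_pct = 1, n_perm = 10,
                             seed = NULL, ...) {
  pres <- tibble::as_tibble(presence_env)
  bkg <- tibble::as_tibble(background_env)
  if (is.null(model)) model <- fit_maxent(pres, bkg, ...)
  if (!is.null(seed)) set.seed(seed)
  np <- nrow(pres)
  pool <- dplyr::bind_rows(pres[model$vars], bkg[model$vars])
  sc <- predict(model, pool, type = "link")
  base_auc <- auc_scores(sc[seq_len(np)], sc[-seq_len(np)])
  drops <- purrr::map_dbl(model$vars, function(v) {
    mean(purrr::map_dbl(seq_len(n_perm), function(i) {
      perm <- pool
      perm[[v]] <- sample(perm[[v]])
      s <- predict(model, perm, type = "link")
      base_auc - auc_scores(s[seq_len(np)], s[-seq_len(np)])
    }))
  })
  drops <- pmax(drops, 0)
  if (sum(drops) == 0) stop("no variable has positive permutation importance")
  importance <- tibble::tibble(variable = model$vars,
                               importance_pct = 100 * drops / sum(drops)) |>
    dplyr::arrange(dplyr::desc(.data$importance_pct))
  selected <- importance$variable[importance$importance_pct > min_importance_pct]
  if (length(selected) == 0)
    stop("all variables fall below the importance cutoff; degenerate model")
  refit <- fit_maxent(pres[selected], bkg[selected], ...)
  structure(list(model = refit, importance = importance, selected = selected,
                 base_auc = base_auc),
            class = "maxent_selection")
}

#' @export
print.maxent_selection <- function(x, ...) {
  cat(sprintf("<maxent_selection> %d of %d variables retained: %s\n",
              length(x$selected), nrow(x$importance),
              paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @rdname select_variables
#' @param x A `maxent_selection`.
#' @param ... Unused.
#' @method tidy maxent_selection
#' @export
tidy.maxent_selection <- function(x, ...) x$importance

#' Build a target-group background
#'
#' Pools occurrence sets of similarly surveyed taxa, thins them to one
#' record per grid cell, and (if more than `n_background` remain) takes a
#' seeded uniform subsample. Target-group backgrounds carry the survey bias
#' of the occurrence data into the background, cancelling it in the
#' presence/background contrast.
#'
#' @param target_occs An [occ_set()] or list of them.
#' @param grid A [grid_spec()] used for thinning.
#' @param n_background Maximum background size (default 10000).
#' @param seed Seed for the subsample.
#' @return An [occ_set()] of background points.
#' @export
make_background <- function(target_occs, grid, n_background = 10000,
                            seed = NULL) {
  if (inherits(target_occs, "occ_set")) target_occs <- list(target_occs)
  stopifnot(length(target_occs) >= 1)
  pooled <- occ_set(dplyr::bind_rows(purrr::map(target_occs,
                                                tibble::as_tibble)))
  if (nrow(pooled) == 0) stop("empty target-group pool")
  pooled <- occ_log(pooled, "make_background: pooled %d target-group records",
                    nrow(pooled))
  thinned <- thin_to_grid(pooled, grid)
  if (nrow(thinned) > n_background) {
    if (!is.null(seed)) set.seed(seed)
    keep <- sort(sample.int(nrow(thinned), n_background))
    thinned <- reoccset(thinned[keep, ], thinned,
      "make_background: subsampled %d of %d thinned records",
      n_background, nrow(thinned))
  } else if (nrow(thinned) < n_background) {
    warning(sprintf("only %d background points available (requested %d)",
                    nrow(thinned), n_background))
    thinned <- occ_log(thinned,
      "make_background: %d available, below requested %d; all returned",
      nrow(thinned), n_background)
  }
  thinned
}
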
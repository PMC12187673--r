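#' Assemble the metric feature table from sweep records
#'
#' Keeps the rows with a complete 15-entry metric vector and a finite
#' accuracy; error-tagged records are excluded and counted.
#'
#' @param records A [run_sweep()] record table (possibly several datasets
#'   row-bound together).
#' @return A `feature_table`: list with `features` (records x 15 matrix),
#'   `response`, `dataset_id`, `replicate`, `n_excluded`.
#' @export
feature_table <- function(records) {
  nm <- metric_vector_names()
  feats <- as.matrix(records[, nm])
  ok <- stats::complete.cases(feats) & is.finite(records$accuracy)
  structure(
    list(
      features = feats[ok, , drop = FALSE],
      response = records$accuracy[ok],
      dataset_id = as.character(records$dataset_id[ok]),
      replicate = records$replicate[ok],
      n_excluded = sum(!ok)
    ),
    class = "feature_table"
  )
}

#' Elastic net with cross-validated penalty
#'
#' Features are z-scored with training statistics (zero-variance features
#' are dropped with a warning); the penalized least-squares objective
#' `(1/2n) sum (y - yhat)^2 + alpha * (l1_ratio * |b|_1 +
#' ((1 - l1_ratio)/2) * |b|_2^2)` is minimized by coordinate descent
#' (delegated to glmnet, whose objective is identical), with `alpha` chosen
#' by minimal mean validation error over `folds`-fold cross-validation with
#' seed-fixed fold assignment.
#'
#' @param x Feature matrix (or a [feature_table()]).
#' @param y Response vector (ignored when `x` is a feature table).
#' @param l1_ratio Mixing parameter in `[0, 1]` (default 0.5).
#' @param alpha_grid Penalty grid; default 50 log-spaced values in
#'   `[1e-4, 10]`.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An `elasticnet_fit`: `coefficients` (named, one per feature;
#'   dropped features carry 0), `intercept`, `alpha`, `l1_ratio`,
#'   `standardization` (`mean`, `sd`), `cv_error`.
#' @export
fit_elasticnet_cv <- function(x, y = NULL, l1_ratio = 0.5,
                              alpha_grid = default_alpha_grid(),
                              folds = 5L, seed = 1L) {
  if (inherits(x, "feature_table")) {
    y <- x$response
    x <- x$features
  }
  x <- as.matrix(x)
  if (nrow(x) < folds) stopf("invalid_input", "need at least %d rows", folds)
  if (l1_ratio < 0 || l1_ratio > 1) stopf("invalid_input", "l1_ratio must be in [0, 1]")
  std <- feature_standardizer(x)
  xz <- std$transform(x)
  coefs <- setNames(rep(0, ncol(x)), colnames(x))
  if (sd(y) == 0) {
    warnf("constant response; returning intercept-only fit")
    return(new_elasticnet_fit(coefs, mean(y), NA_real_, l1_ratio, std, NA_real_))
  }
  keep <- std$keep
  xk <- xz[, keep, drop = FALSE]
  grid <- sort(unique(alpha_grid), decreasing = TRUE)
  foldid <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  err <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    cf_tr <- glmnet_exact(xk[tr, , drop = FALSE], y[tr], grid, l1_ratio)
    pred <- cbind(1, xk[!tr, , drop = FALSE]) %*% cf_tr
    err[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(err)
  best <- grid[which.min(cvm)]
  cf <- glmnet_exact(xk, y, grid, l1_ratio)[, as.character(best)]
  coefs[keep] <- cf[-1]
  new_elasticnet_fit(coefs, cf[1], best, l1_ratio, std, min(cvm))
}

#' Elastic net at fixed penalties (no cross-validation)
#'
#' Coordinate-descent solutions over a decreasing `alpha` sequence on
#' already-standardized (or raw) features; used for penalty-path analysis
#' and oracle checks.
#'
#' @inheritParams fit_elasticnet_cv
#' @param alphas Penalty values.
#' @return Matrix of coefficients, one column per `alpha` (rows: intercept
#'   then features), with the alphas as column names.
#' @export
fit_elasticnet_path <- function(x, y, alphas, l1_ratio = 0.5) {
  glmnet_exact(as.matrix(x), y, alphas, l1_ratio)
}

# Coordinate-descent elastic net at the exact penalty
# alpha * (rho |b|_1 + (1 - rho)/2 |b|_2^2) on the (1/2n) RSS scale.
# glmnet standardizes the response internally, which rescales its ridge
# term by 1/sd(y); because both penalty pieces are linear in alpha this is
# undone exactly by one reparameterization of (lambda, alpha).
glmnet_exact <- function(x, y, alphas, l1_ratio) {
  yc <- y - mean(y)
  sy <- sqrt(mean(yc^2))
  scale_f <- l1_ratio + (1 - l1_ratio) * sy
  phi <- if (scale_f > 0) l1_ratio / scale_f else 1
  lam <- sort(unique(alphas), decreasing = TRUE) * scale_f
  fit <- glmnet::glmnet(x, y, alpha = phi, lambda = lam,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
  out <- as.matrix(coef(fit, s = alphas * scale_f))  # knots: no interpolation
  colnames(out) <- as.character(alphas)
  out
}

default_alpha_grid <- function() exp(seq(log(1e-4), log(10), length.out = 50))

feature_standardizer <- function(x) {
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  keep <- sg > 0
  if (!all(keep)) {
    warnf("dropping %d zero-variance feature(s): %s", sum(!keep),
          paste(colnames(x)[!keep], collapse = ", "))
  }
  sg_safe <- ifelse(keep, sg, 1)
  list(
    mean = mu, sd = sg, keep = keep,
    transform = function(m) sweep(sweep(as.matrix(m), 2, mu), 2, sg_safe, "/")
  )
}

new_elasticnet_fit <- function(coefs, intercept, alpha, l1_ratio, std, cv_error) {
  structure(
    list(coefficients = coefs, intercept = intercept, alpha = alpha,
         l1_ratio = l1_ratio,
         standardization = list(mean = std$mean, sd = std$sd, keep = std$keep),
         cv_error = cv_error),
    class = "elasticnet_fit"
  )
}

#' Predict from an elastic-net fit
#'
#' @param object An `elasticnet_fit`.
#' @param newdata Feature matrix on the original (unstandardized) scale.
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.elasticnet_fit <- function(object, newdata, ...) {
  xz <- sweep(sweep(as.matrix(newdata), 2, object$standardization$mean), 2,
              ifelse(object$standardization$keep, object$standardization$sd, 1), "/")
  drop(object$intercept + xz %*% object$coefficients)
}

test_r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
test_rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Intra-dataset leave-one-unit-out validation
#'
#' Leaves out one subsample replicate at a time (all of its
#' configurations, avoiding configuration leakage across folds), fits the
#' elastic net on the remaining replicates and scores the held-out unit.
#'
#' @param tab A [feature_table()] for a single dataset.
#' @param l1_ratio,alpha_grid,folds,seed Passed to [fit_elasticnet_cv()].
#' @return A `validation_report`: `scheme = "intra_loo"`, `per_unit`
#'   data.frame (`unit`, `r2`, `rmse`), `r2_mean`, `r2_sd`, `rmse_mean`,
#'   `rmse_sd`.
#' @export
validate_intra <- function(tab, l1_ratio = 0.5, alpha_grid = default_alpha_grid(),
                           folds = 5L, seed = 1L) {
  units <- sort(unique(tab$replicate))
  if (length(units) < 3) stopf("invalid_input", "need >= 3 replicate units")
  rows <- list()
  for (u in units) {
    test <- tab$replicate == u
    if (sum(test) < 2) {
      warnf("unit %s has < 2 records; skipped", u)
      next
    }
    fit <- fit_elasticnet_cv(tab$features[!test, , drop = FALSE],
                             tab$response[!test], l1_ratio, alpha_grid,
                             folds, derive_seed(seed, u))
    yhat <- predict(fit, tab$features[test, , drop = FALSE])
    rows[[as.character(u)]] <- data.frame(
      unit = u, r2 = test_r2(tab$response[test], yhat),
      rmse = test_rmse(tab$response[test], yhat)
    )
  }
  per_unit <- do.call(rbind, rows)
  rownames(per_unit) <- NULL
  structure(
    list(scheme = "intra_loo", per_unit = per_unit,
         r2_mean = mean(per_unit$r2), r2_sd = sd(per_unit$r2),
         rmse_mean = mean(per_unit$rmse), rmse_sd = sd(per_unit$rmse)),
    class = "validation_report"
  )
}

#' Cross-dataset validation
#'
#' For each dataset, fits the elastic net on the concatenation of the other
#' datasets (standardization statistics from the training pool only) and
#' scores the held-out dataset.
#'
#' @param tabs Named list of [feature_table()] objects (>= 2), or a single
#'   feature table spanning several `dataset_id` values.
#' @inheritParams validate_intra
#' @return List of `validation_report`s (`scheme = "cross_dataset"`), one
#'   per held-out dataset, each with `r2`, `rmse` and the training `fit`.
#' @export
validate_cross <- function(tabs, l1_ratio = 0.5, alpha_grid = default_alpha_grid(),
                           folds = 5L, seed = 1L) {
  if (inherits(tabs, "feature_table")) tabs <- split_feature_table(tabs)
  if (length(tabs) < 2) stopf("invalid_input", "need >= 2 datasets")
  ids <- names(tabs)
  out <- list()
  for (i in seq_along(tabs)) {
    train_x <- do.call(rbind, lapply(tabs[-i], `[[`, "features"))
    train_y <- unlist(lapply(tabs[-i], `[[`, "response"), use.names = FALSE)
    fit <- fit_elasticnet_cv(train_x, train_y, l1_ratio, alpha_grid, folds,
                             derive_seed(seed, i))
    yhat <- predict(fit, tabs[[i]]$features)
    out[[ids[i]]] <- structure(
      list(scheme = "cross_dataset", held_out = ids[i],
           r2 = test_r2(tabs[[i]]$response, yhat),
           rmse = test_rmse(tabs[[i]]$response, yhat), fit = fit),
      class = "validation_report"
    )
  }
  out
}

#' Split a pooled feature table by dataset
#'
#' @param tab A [feature_table()].
#' @return Named list of per-dataset feature tables.
#' @export
split_feature_table <- function(tab) {
  ids <- sort(unique(tab$dataset_id))
  setNames(lapply(ids, function(id) {
    sel <- tab$dataset_id == id
    structure(list(features = tab$features[sel, , drop = FALSE],
                   response = tab$response[sel],
                   dataset_id = tab$dataset_id[sel],
                   replicate = tab$replicate[sel], n_excluded = 0L),
              class = "feature_table")
  }), ids)
}

#' Rank features by selection consistency across fits
#'
#' Orders features by (1) the number of fits that retained them with a
#' nonzero coefficient, (2) sign consistency across those fits, (3) mean
#' absolute coefficient; features never selected are dropped.
#'
#' @param fits List of `elasticnet_fit` objects (>= 2).
#' @return Data.frame with `feature`, `n_selected`, `sign_consistent`,
#'   `mean_abs_coef`, `sign`, ordered best first.
#' @export
rank_consistent_features <- function(fits) {
  if (length(fits) < 2) stopf("invalid_input", "need >= 2 fits")
  cmat <- do.call(cbind, lapply(fits, `[[`, "coefficients"))
  n_sel <- rowSums(cmat != 0)
  sign_cons <- apply(cmat, 1, function(v) {
    nz <- v[v != 0]
    length(nz) > 0 && (all(nz > 0) || all(nz < 0))
  })
  mean_abs <- rowMeans(abs(cmat))
  dominant_sign <- apply(cmat, 1, function(v) {
    nz <- v[v != 0]
    if (!length(nz)) 0 else sign(sum(sign(nz)))
  })
  out <- data.frame(
    feature = rownames(cmat), n_selected = n_sel,
    sign_consistent = sign_cons, mean_abs_coef = mean_abs,
    sign = dominant_sign, row.names = NULL
  )
  out <- out[out$n_selected > 0, , drop = FALSE]
  out[order(-out$n_selected, -out$sign_consistent, -out$mean_abs_coef), ,
      drop = FALSE]
}

#' Spearman association and hierarchical grouping of the metrics
#'
#' 15 x 15 Spearman correlation (average-rank ties) and average-linkage
#' hierarchical clustering on the distance `1 - |rho|`, so strongly
#' anticorrelated metric pairs group together.  Zero-variance features are
#' flagged and excluded from the clustering.
#'
#' @param tab A [feature_table()] or a numeric feature matrix.
#' @return List with `correlation` (full matrix, `NA` rows for excluded
#'   features), `hclust` (average linkage), `excluded`.
#' @export
metric_association <- function(tab) {
  x <- if (inherits(tab, "feature_table")) tab$features else as.matrix(tab)
  if (nrow(x) < 3) stopf("invalid_input", "need >= 3 records")
  sg <- apply(x, 2, sd)
  excluded <- colnames(x)[sg == 0]
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[sg == 0, ] <- NA_real_
  rho[, sg == 0] <- NA_real_
  use <- sg > 0
  hc <- stats::hclust(stats::as.dist(1 - abs(rho[use, use, drop = FALSE])),
                      method = "average")
  list(correlation = rho, hclust = hc, excluded = excluded)
}

#' Deviation from linearity of accuracy proxies
#'
#' Min-max normalizes each listed measure, regresses it linearly on
#' accuracy, and reports the residual standard deviation as the
#' linearity-deviation score (smaller = more usable as a linear proxy).
#'
#' @param records Sweep record table (metrics + `accuracy`, optionally
#'   `ari`/`nmi`).
#' @param measures Column names to assess.
#' @return List with `summary` (data.frame `measure`, `slope`,
#'   `residual_sd`, `flagged`) and `residuals` (named list).
#' @export
linearity_deviation <- function(records,
                                measures = c("wc_dispersion", "banfield_raftery",
                                             "silhouette", "ari", "nmi")) {
  measures <- intersect(measures, names(records))
  if (!length(measures)) stopf("invalid_input", "no requested measure present")
  rows <- list()
  resids <- list()
  for (m in measures) {
    ok <- is.finite(records[[m]]) & is.finite(records$accuracy)
    v <- records[[m]][ok]
    acc <- records$accuracy[ok]
    rng <- range(v)
    if (diff(rng) == 0) {
      rows[[m]] <- data.frame(measure = m, slope = NA_real_,
                              residual_sd = NA_real_, flagged = TRUE)
      next
    }
    vn <- (v - rng[1]) / diff(rng)
    fit <- stats::lm.fit(cbind(1, acc), vn)
    rows[[m]] <- data.frame(measure = m, slope = fit$coefficients[2],
                            residual_sd = sd(fit$residuals), flagged = FALSE)
    resids[[m]] <- fit$residuals
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, residuals = resids)
}
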
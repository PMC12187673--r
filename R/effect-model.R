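#' Describe the factorial design for the accuracy model
#'
#' Treatment (dummy) coding of the sweep factors against stated reference
#' levels, optionally with all pairwise interactions, plus a sum-to-zero
#' coded subsample block factor.  The default reference levels are
#' method = gauss, resolution = 0.5, pc = 10, nn = 10, metric = cosine.
#'
#' @param factors Named list; each element is `list(levels = ..., ref = ...)`.
#' @param include_interactions Include all pairwise interaction columns.
#' @param block Name of the replicate (subsample) column, or `NULL`.
#' @return A `design_spec` list.
#' @export
design_spec <- function(factors, include_interactions = TRUE, block = "replicate") {
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (!as.character(f$ref) %in% as.character(f$levels)) {
      stopf("invalid_spec", "reference level %s not among levels of %s", f$ref, nm)
    }
  }
  structure(list(factors = factors,
                 include_interactions = isTRUE(include_interactions),
                 block = block),
            class = "design_spec")
}

#' Default design from a sweep record table
#'
#' Includes each sweep factor observed at two or more levels, with the
#' standard reference levels (pc 10, nn 10, res 0.5, method gauss, metric
#' cosine; if a reference value is absent the lowest / first level is used).
#'
#' @param records A [run_sweep()] record table.
#' @param include_interactions Include pairwise interactions.
#' @return A [design_spec()].
#' @export
default_design_spec <- function(records, include_interactions = TRUE) {
  refs <- list(pc = "10", nn = "10", res = "0.5", method = "gauss", metric = "cosine")
  factors <- list()
  for (nm in names(refs)) {
    lev <- sort(unique(as.character(records[[nm]])))
    if (nm %in% c("pc", "nn", "res")) {
      lev <- as.character(sort(unique(as.numeric(lev))))
    }
    if (length(lev) < 2) next
    ref <- if (refs[[nm]] %in% lev) refs[[nm]] else lev[1]
    factors[[nm]] <- list(levels = lev, ref = ref)
  }
  design_spec(factors, include_interactions)
}

#' Build the model matrix and response for the effect model
#'
#' @param records Record table with the factor columns, the block column and
#'   an `accuracy` response.
#' @param spec A [design_spec()].
#' @param response Name of the response column.
#' @return List with `X` (model matrix including intercept), `y`,
#'   `main_cols`, `interaction_cols`, `block_cols`.
#' @export
build_design <- function(records, spec, response = "accuracy") {
  n <- nrow(records)
  cols <- list(`(Intercept)` = rep(1, n))
  dummies <- list()
  for (nm in names(spec$factors)) {
    f <- spec$factors[[nm]]
    obs <- as.character(records[[nm]])
    unseen <- setdiff(unique(obs), as.character(f$levels))
    if (length(unseen)) {
      stopf("invalid_input", "unseen level(s) %s in factor %s",
            paste(unseen, collapse = ","), nm)
    }
    for (lev in setdiff(as.character(f$levels), as.character(f$ref))) {
      cname <- paste0(nm, ":", lev)
      v <- as.numeric(obs == lev)
      cols[[cname]] <- v
      dummies[[nm]] <- c(dummies[[nm]], cname)
    }
  }
  main_cols <- unlist(dummies, use.names = FALSE)
  interaction_cols <- character(0)
  if (spec$include_interactions && length(dummies) >= 2) {
    fns <- names(dummies)
    for (a in seq_len(length(fns) - 1)) {
      for (b in seq((a + 1), length(fns))) {
        for (ca in dummies[[fns[a]]]) {
          for (cb in dummies[[fns[b]]]) {
            cname <- paste0(ca, "×", cb)
            cols[[cname]] <- cols[[ca]] * cols[[cb]]
            interaction_cols <- c(interaction_cols, cname)
          }
        }
      }
    }
  }
  block_cols <- character(0)
  if (!is.null(spec$block) && spec$block %in% names(records)) {
    blk <- factor(records[[spec$block]])
    if (nlevels(blk) >= 2) {
      levs <- levels(blk)
      for (b in seq_len(nlevels(blk) - 1)) {
        cname <- paste0("block:", levs[b])
        v <- numeric(n)
        v[blk == levs[b]] <- 1
        v[blk == levs[nlevels(blk)]] <- -1  # sum-to-zero coding
        cols[[cname]] <- v
        block_cols <- c(block_cols, cname)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  y <- if (response %in% names(records)) records[[response]] else NULL
  list(X = X, y = y, main_cols = main_cols,
       interaction_cols = interaction_cols, block_cols = block_cols)
}

#' Huber M-estimation of the effect model by IRLS
#'
#' Iteratively reweighted least squares with the Huber weight
#' `min(1, c * s / |r|)`, scale `s` the normalized MAD of the residuals,
#' re-estimated each iteration.  The subsample block enters as sum-to-zero
#' fixed effects, approximating a per-subsample random intercept.
#' Convergence when the largest coefficient change falls below `tol`.
#'
#' @param design A [build_design()] result (or a bare matrix).
#' @param response Response vector (taken from the design if `NULL`).
#' @param tuning Huber tuning constant (default 1.345, 95% Gaussian
#'   efficiency).
#' @param max_iter,tol IRLS controls.
#' @return An `effect_fit`: coefficients, robust_weights, scale, bias, rmse,
#'   r2, converged, n_iter, robust (sandwich) `se` and `p`, residuals,
#'   fitted.
#' @export
fit_robust_effects <- function(design, response = NULL, tuning = 1.345,
                               max_iter = 100L, tol = 1e-8) {
  X <- if (is.list(design)) design$X else design
  y <- response %||% design$y
  if (is.null(y)) stopf("invalid_input", "no response supplied")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stopf("rank_deficiency", "design is rank deficient; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  w <- rep(1, length(y))
  converged <- FALSE
  it <- 0L
  y_scale <- sd(y) + 1e-12
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- mad(r)
    if (s < 1e-10 * y_scale) {  # (near-)perfect fit: unweighted solution stands
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    w <- pmin(1, tuning * s / pmax(abs(r), 1e-300))
    beta_new <- lm.wfit(X, y, w)$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warnf("Huber IRLS did not converge in %d iterations", max_iter)
  r <- y - drop(X %*% beta)
  s <- mad(r)
  n <- length(y)
  p <- ncol(X)
  # M-estimation sandwich variance: s^2 * E[psi^2] / (E[psi'])^2 * (X'X)^-1
  se <- p_val <- rep(NA_real_, p)
  if (s > 0) {
    u <- r / s
    psi <- pmin(pmax(u, -tuning), tuning)
    psi_d <- as.numeric(abs(u) <= tuning)
    kappa <- (s^2 * sum(psi^2) / (n - p)) / mean(psi_d)^2
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(pmax(kappa * diag(xtx_inv), 0))
    p_val <- 2 * pnorm(-abs(beta / se))
  }
  structure(
    list(
      coefficients = beta, robust_weights = w, scale = s,
      bias = mean(r), rmse = sqrt(mean(r^2)),
      r2 = 1 - sum(r^2) / sum((y - mean(y))^2),
      converged = converged, n_iter = it,
      se = setNames(se, names(beta)), p = setNames(p_val, names(beta)),
      residuals = r, fitted = drop(X %*% beta), tuning = tuning
    ),
    class = "effect_fit"
  )
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("Huber-IRLS effect fit: %d coefficients, r2 = %.4f, rmse = %.4g, bias = %.3g (%s in %d iters)\n",
              length(x$coefficients), x$r2, x$rmse, x$bias,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Residual diagnostics of an effect fit
#'
#' Bias, RMSE, R-squared plus Kolmogorov-Smirnov and Anderson-Darling
#' normality tests on the residuals.
#'
#' @param fit An `effect_fit`.
#' @return Named list of diagnostics.
#' @export
effect_diagnostics <- function(fit) {
  r <- fit$residuals
  ks <- suppressWarnings(stats::ks.test(scale(r), "pnorm"))
  ad <- tryCatch(nortest::ad.test(r), error = function(e) NULL)
  list(
    bias = fit$bias, rmse = fit$rmse, r2 = fit$r2,
    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
    ad_statistic = if (is.null(ad)) NA_real_ else unname(ad$statistic),
    ad_p = if (is.null(ad)) NA_real_ else ad$p.value,
    converged = fit$converged
  )
}

#' Kruskal-Wallis comparison with Dunn's post-hoc test
#'
#' Compares accuracy distributions across groups (e.g. datasets) with the
#' Kruskal-Wallis rank-sum test, followed by all pairwise Dunn z tests with
#' Bonferroni correction (adjusted p capped at 1).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return A `comparison_report`: `kw_statistic`, `kw_p`, `pairwise`
#'   data.frame (`group1`, `group2`, `z`, `p_unadj`, `p_adj`).
#' @export
compare_groups <- function(values_by_group) {
  if (length(values_by_group) < 2) stopf("invalid_input", "need >= 2 groups")
  if (any(lengths(values_by_group) < 2)) stopf("invalid_input", "each group needs >= 2 values")
  values <- unlist(values_by_group, use.names = FALSE)
  groups <- factor(rep(names(values_by_group), lengths(values_by_group)))
  n <- length(values)
  if (length(unique(values)) == 1) {  # everything tied: no evidence by convention
    pairs <- utils::combn(names(values_by_group), 2)
    return(structure(list(
      kw_statistic = 0, kw_p = 1,
      pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                            z = 0, p_unadj = 1, p_adj = 1)
    ), class = "comparison_report"))
  }
  kw <- kruskal.test(values, groups)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  sizes <- tapply(rk, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(values_by_group), 2)
  z <- p_unadj <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z[j] <- (mean_rank[[g1]] - mean_rank[[g2]]) / sigma
    p_unadj[j] <- 2 * pnorm(-abs(z[j]))
  }
  structure(list(
    kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          z = z, p_unadj = p_unadj,
                          p_adj = pmin(1, p_unadj * ncol(pairs)))
  ), class = "comparison_report")
}

#' Best and worst configurations predicted by the effect model
#'
#' Predicts the mean accuracy of every grid configuration from the fitted
#' coefficients with the block effect at zero (its sum-to-zero average) and
#' returns the argmax and argmin; ties are broken by grid order.
#'
#' @param fit An `effect_fit`.
#' @param grid A configuration grid from [enumerate_grid()].
#' @param spec The [design_spec()] used for the fit.
#' @return List with `best`, `worst` (one-row data.frames with the
#'   configuration and `predicted`), `predicted` (all grid predictions) and
#'   `sd` (residual-based spread of the prediction).
#' @export
extract_extreme_configs <- function(fit, grid, spec) {
  if (!fit$converged) warnf("extracting extremes from a non-converged fit")
  spec_noblock <- spec
  spec_noblock$block <- NULL
  d <- build_design(grid, spec_noblock, response = "none")
  keep <- intersect(colnames(d$X), names(fit$coefficients))
  pred <- drop(d$X[, keep, drop = FALSE] %*% fit$coefficients[keep])
  best_i <- which.max(pred)
  worst_i <- which.min(pred)
  best <- cbind(grid[best_i, , drop = FALSE], predicted = pred[best_i])
  worst <- cbind(grid[worst_i, , drop = FALSE], predicted = pred[worst_i])
  rownames(best) <- rownames(worst) <- NULL
  list(best = best, worst = worst, predicted = pred, sd = fit$rmse)
}
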
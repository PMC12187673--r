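# n x p design with (1/n) X'X = I and mean-zero columns, for which the
# elastic-net solution has the soft-threshold closed form
orthonormal_design <- function(n = 60, p = 6, seed = 1) {
  set.seed(seed)
  raw <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  x <- sqrt(n) * qr.Q(qr(raw))
  colnames(x) <- paste0("f", seq_len(p))
  x
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

test_that("coordinate descent matches the orthonormal closed form across the path", {
  x <- orthonormal_design()
  n <- nrow(x)
  set.seed(2)
  beta_true <- c(1.5, -1, 0.6, 0, 0, -0.2)
  y <- drop(x %*% beta_true) + rnorm(n, sd = 0.05)
  beta_ols <- drop(crossprod(x, y)) / n
  rho <- 0.5
  alphas <- exp(seq(log(1e-3), log(2), length.out = 15))
  path <- fit_elasticnet_path(x, y - mean(y), alphas, l1_ratio = rho)
  for (j in seq_along(alphas)) {
    a <- alphas[j]
    expected <- soft_threshold(beta_ols, a * rho) / (1 + a * (1 - rho))
    expect_equal(unname(path[-1, j]), unname(expected), tolerance = 1e-8)
  }
})

test_that("the number of selected features never grows with the penalty", {
  x <- orthonormal_design(seed = 3)
  set.seed(3)
  y <- drop(x %*% c(2, -1, 0.5, 0.2, 0, 0)) + rnorm(nrow(x), sd = 0.1)
  alphas <- sort(exp(seq(log(1e-3), log(5), length.out = 25)))
  path <- fit_elasticnet_path(x, y - mean(y), alphas, l1_ratio = 0.5)
  nonzero <- colSums(path[-1, , drop = FALSE] != 0)
  expect_true(all(diff(nonzero) <= 0))
})

test_that("vanishing penalty recovers least squares; zero response gives zero fit", {
  set.seed(4)
  x <- matrix(rnorm(80 * 5), 80, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- drop(x %*% c(1, 0.5, -2, 0, 1)) + rnorm(80, sd = 0.01)
  path <- fit_elasticnet_path(x, y, alphas = c(1e-7, 1e-6), l1_ratio = 0.5)
  ls <- qr.coef(qr(cbind(1, x)), y)
  expect_equal(unname(path[, 1]), unname(ls), tolerance = 1e-6)

  fit0 <- suppressWarnings(fit_elasticnet_cv(x, rep(0, 80), seed = 5))
  expect_true(all(fit0$coefficients == 0))
})

test_that("cross-validated fit standardizes with training statistics and is seeded", {
  set.seed(6)
  x <- matrix(rnorm(100 * 15), 100, 15)
  colnames(x) <- metric_vector_names()
  y <- 0.5 - 0.2 * x[, "wc_dispersion"] + rnorm(100, sd = 0.05)
  f1 <- fit_elasticnet_cv(x, y, seed = 9)
  f2 <- fit_elasticnet_cv(x, y, seed = 9)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(f1$standardization$mean, colMeans(x))
  expect_equal(f1$standardization$sd, apply(x, 2, sd))
  expect_lt(f1$coefficients[["wc_dispersion"]], 0)
  # zero-variance feature dropped with a warning, coefficient forced to 0
  x2 <- x
  x2[, "tss"] <- 1
  expect_warning(f3 <- fit_elasticnet_cv(x2, y, seed = 9), "zero-variance")
  expect_equal(f3$coefficients[["tss"]], 0)
})

make_table <- function(n_rep, per_rep, beta, sd = 0.01, seed = 1, shift = 0,
                       id = "d1") {
  set.seed(seed)
  n <- n_rep * per_rep
  x <- matrix(rnorm(n * 15), n, 15)
  colnames(x) <- metric_vector_names()
  y <- 0.4 + drop(x %*% beta) + rnorm(n, sd = sd) + shift
  structure(list(features = x, response = y, dataset_id = rep(id, n),
                 replicate = rep(seq_len(n_rep), each = per_rep),
                 n_excluded = 0L),
            class = "feature_table")
}

beta_wc <- { b <- rep(0, 15); b[2] <- -0.15; b }

test_that("intra-dataset validation is leave-one-replicate-out", {
  tab <- make_table(5, 30, beta_wc, sd = 1e-6, seed = 7)
  rep_ <- validate_intra(tab, seed = 3)
  expect_equal(nrow(rep_$per_unit), 5)
  expect_true(all(rep_$per_unit$r2 > 0.999))
  expect_true(all(rep_$per_unit$rmse < 1e-3))
})

test_that("pure-noise response yields held-out r2 at or below zero on average", {
  r2s <- vapply(1:20, function(s) {
    tab <- make_table(4, 12, rep(0, 15), sd = 1, seed = 100 + s)
    validate_intra(tab, seed = s)$r2_mean
  }, numeric(1))
  expect_lt(mean(r2s), 0.05)
})

test_that("cross-dataset validation trains on the complement without leakage", {
  tabs <- list(
    d1 = make_table(3, 25, beta_wc, seed = 11, id = "d1"),
    d2 = make_table(3, 25, beta_wc, seed = 12, id = "d2"),
    d3 = make_table(3, 25, beta_wc, seed = 13, id = "d3")
  )
  reps <- validate_cross(tabs, seed = 21)
  expect_named(reps, c("d1", "d2", "d3"))
  for (id in names(reps)) {
    expect_equal(reps[[id]]$scheme, "cross_dataset")
    expect_gt(reps[[id]]$r2, 0.95)
    # standardization comes from the training pool only
    train <- do.call(rbind, lapply(tabs[setdiff(names(tabs), id)], `[[`, "features"))
    expect_equal(reps[[id]]$fit$standardization$mean, colMeans(train))
  }
  expect_error(validate_cross(tabs[1]), class = "invalid_input")
})

test_that("a constant shift in the held-out response inflates rmse, not coefficients", {
  tabs <- list(
    d1 = make_table(3, 25, beta_wc, seed = 31, id = "d1"),
    d2 = make_table(3, 25, beta_wc, seed = 32, id = "d2"),
    d3 = make_table(3, 25, beta_wc, seed = 33, id = "d3")
  )
  base <- validate_cross(tabs, seed = 5)
  tabs_shift <- tabs
  tabs_shift$d3$response <- tabs_shift$d3$response + 0.5
  shifted <- validate_cross(tabs_shift, seed = 5)
  expect_equal(shifted$d3$fit$coefficients, base$d3$fit$coefficients)
  expect_gte(shifted$d3$rmse, 0.45)
  expect_lt(base$d3$rmse, 0.1)
})

test_that("feature ranking follows (count, sign consistency, magnitude)", {
  mk <- function(v) structure(list(coefficients = setNames(v, c("A", "B", "C", "D"))),
                              class = "elasticnet_fit")
  fits <- list(
    mk(c(-0.5, 0.2, 0.9, 0)),
    mk(c(-0.4, 0.0, -0.8, 0)),
    mk(c(-0.6, 0.1, 0.7, 0))
  )
  rk <- rank_consistent_features(fits)
  # brute-force ordering by the stated key
  key <- data.frame(
    feature = c("A", "B", "C", "D"),
    n = c(3, 2, 3, 0),
    cons = c(TRUE, TRUE, FALSE, FALSE),
    mag = c(0.5, 0.1, 0.8, 0)
  )
  key <- key[key$n > 0, ]
  key <- key[order(-key$n, -key$cons, -key$mag), ]
  expect_equal(rk$feature, key$feature)
  expect_equal(rk$sign[rk$feature == "A"], -1)
  # all-zero fits give an empty selection
  empty <- rank_consistent_features(list(mk(rep(0, 4)), mk(rep(0, 4))))
  expect_equal(nrow(empty), 0)
})

test_that("metric association recovers hand-computed correlations and linkage", {
  n <- 30
  f1 <- seq_len(n)
  tab <- cbind(a = f1, b = f1^2, c = -f1)  # b monotone in a; c its negation
  ma <- metric_association(tab)
  expect_equal(ma$correlation["a", "b"], 1)
  expect_equal(ma$correlation["a", "c"], -1)

  set.seed(41)
  base <- rnorm(60)
  x3 <- cbind(p = base + rnorm(60, sd = 0.1),
              q = base + rnorm(60, sd = 0.1),
              r = rnorm(60))
  ma3 <- metric_association(x3)
  # first merge joins the strongly correlated pair (p, q)
  expect_setequal(-ma3$hclust$merge[1, ], c(1, 2))

  x4 <- cbind(x3, const = 1)
  ma4 <- metric_association(x4)
  expect_equal(ma4$excluded, "const")
  expect_true(all(is.na(ma4$correlation["const", ])))
})

test_that("linearity deviation separates affine from curved proxies", {
  acc <- seq(0, 1, length.out = 200)
  records <- data.frame(
    accuracy = acc,
    wc_dispersion = 3 - 2 * acc,          # exactly affine
    banfield_raftery = (acc - 0.5)^2,     # quadratic
    silhouette = 3 - 2 * acc + rnorm(200, sd = 0.1),
    ari = acc, nmi = acc
  )
  ld <- linearity_deviation(records)
  s <- ld$summary
  sd_of <- function(m) s$residual_sd[s$measure == m]
  expect_equal(sd_of("wc_dispersion"), 0, tolerance = 1e-10)
  expect_gt(sd_of("banfield_raftery"), 0.01)
  expect_lt(sd_of("wc_dispersion"), sd_of("silhouette"))
  # residuals of a line fit to a parabola are U-shaped in accuracy
  resid_br <- ld$residuals$banfield_raftery
  expect_gt(cor(resid_br, (acc - 0.5)^2), 0.9)
  # a constant measure is flagged
  records$const <- 1
  ld2 <- linearity_deviation(records, measures = "const")
  expect_true(ld2$summary$flagged)
})
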
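make_sweep_frame <- function(n_rep = 4, seed = 1) {
  set.seed(seed)
  g <- expand.grid(
    metric = c("cosine", "euclidean"), method = c("gauss", "umap"),
    res = c(0.5, 0.8, 1, 2), nn = c(10, 20, 30), pc = c(10, 20, 30, 50),
    stringsAsFactors = FALSE
  )
  do.call(rbind, lapply(seq_len(n_rep), function(r) cbind(g, replicate = r)))
}

test_that("design matrix has the expected treatment and interaction columns", {
  df <- make_sweep_frame(1)
  # factors with (2,4,4,3,2)-level structure, main effects only:
  spec <- design_spec(list(
    method = list(levels = c("gauss", "umap"), ref = "gauss"),
    res = list(levels = c("0.5", "0.8", "1", "2"), ref = "0.5"),
    pc = list(levels = c("10", "20", "30", "50"), ref = "10"),
    nn = list(levels = c("10", "20", "30"), ref = "10"),
    metric = list(levels = c("cosine", "euclidean"), ref = "cosine")
  ), include_interactions = FALSE, block = NULL)
  d <- build_design(df, spec, response = "none")
  expect_equal(ncol(d$X), 11)  # 1 + 1 + 3 + 3 + 2 + 1
  expect_true("res:2" %in% colnames(d$X))

  # two 2-level factors give exactly one interaction column
  spec2 <- design_spec(list(
    method = list(levels = c("gauss", "umap"), ref = "gauss"),
    metric = list(levels = c("cosine", "euclidean"), ref = "cosine")
  ), include_interactions = TRUE, block = NULL)
  d2 <- build_design(df, spec2, response = "none")
  expect_equal(d2$interaction_cols, "method:umap×metric:euclidean")

  # a reference-level-only row is all zeros outside the intercept
  ref_row <- df$method == "gauss" & df$res == 0.5 & df$pc == 10 &
    df$nn == 10 & df$metric == "cosine"
  expect_equal(unname(d$X[which(ref_row)[1], -1]), rep(0, 10))

  # unseen level rejected
  df_bad <- df
  df_bad$method[1] <- "tsne"
  expect_error(build_design(df_bad, spec, response = "none"),
               class = "invalid_input")
})

test_that("block coding is sum-to-zero", {
  df <- make_sweep_frame(3)
  spec <- default_design_spec(df)
  d <- build_design(df, spec, response = "none")
  expect_length(d$block_cols, 2)
  expect_equal(colSums(d$X[, d$block_cols, drop = FALSE]), c(`block:1` = 0, `block:2` = 0))
})

test_that("noiseless effects are recovered exactly", {
  df <- make_sweep_frame(2)
  df$accuracy <- 0.6 + 0.1 * (df$res == 2)
  fit <- fit_robust_effects(build_design(df, default_design_spec(df)))
  expect_equal(unname(fit$coefficients["res:2"]), 0.1, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.6, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$bias, 0, tolerance = 1e-12)
  expect_true(fit$converged)
  other <- setdiff(names(fit$coefficients), c("(Intercept)", "res:2"))
  expect_equal(max(abs(fit$coefficients[other])), 0, tolerance = 1e-9)
})

test_that("constant response yields zero effects", {
  df <- make_sweep_frame(2)
  df$accuracy <- 0.7
  fit <- fit_robust_effects(build_design(df, default_design_spec(df)))
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.7, tolerance = 1e-12)
  expect_equal(max(abs(fit$coefficients[-1])), 0, tolerance = 1e-10)
})

test_that("with bounded symmetric noise the robust fit equals least squares", {
  df <- make_sweep_frame(4, seed = 4)
  set.seed(4)
  noise <- 0.02 * sample(c(-1, 1), nrow(df), replace = TRUE)  # Rademacher
  df$accuracy <- 0.6 + 0.08 * (df$res == 2) - 0.05 * (df$nn == 30) + noise
  # main-effects design: low leverage keeps every residual inside the
  # Huber threshold, so no observation is downweighted
  d <- build_design(df, default_design_spec(df, include_interactions = FALSE))
  fit <- fit_robust_effects(d)
  expect_true(all(fit$robust_weights == 1))
  ols <- qr.coef(qr(d$X), d$y)
  expect_equal(fit$coefficients, ols, tolerance = 1e-6)
  # reported r2 equals an independent recomputation from the residuals
  expect_equal(fit$r2, 1 - sum(fit$residuals^2) / sum((d$y - mean(d$y))^2),
               tolerance = 1e-12)
})

test_that("rank deficiency is reported with the collinear columns named", {
  df <- make_sweep_frame(1)
  df$accuracy <- rnorm(nrow(df))
  spec <- default_design_spec(df, include_interactions = FALSE)
  d <- build_design(df, spec)
  d$X <- cbind(d$X, `res:2copy` = d$X[, "res:2"])
  expect_error(fit_robust_effects(d), "res:2copy", class = "rank_deficiency")
})

test_that("huber fit agrees with MASS::rlm on an outlier-contaminated design", {
  skip_if_not_installed("MASS")
  set.seed(11)
  x <- cbind(1, rnorm(200), rnorm(200))
  colnames(x) <- c("(Intercept)", "a", "b")
  y <- drop(x %*% c(1, 2, -1)) + rnorm(200, sd = 0.1)
  y[1:10] <- y[1:10] + 3
  fit <- fit_robust_effects(x, y)
  rlm_fit <- MASS::rlm(x, y, k = 1.345, maxit = 100)
  expect_equal(unname(fit$coefficients), unname(coef(rlm_fit)), tolerance = 0.02)
})

test_that("fitted signs recover the generating signs across many seeds", {
  ok <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    df <- make_sweep_frame(4, seed = s)
    keep <- df$pc == 10 & df$metric == "cosine" & df$method == "gauss"
    df <- df[keep, ]
    noise <- rnorm(nrow(df), sd = 0.03)
    out <- rbinom(nrow(df), 1, 0.05) * 0.3
    df$accuracy <- 0.5 + 0.1 * (df$res == 2) - 0.06 * (df$nn == 30) + noise + out
    fit <- fit_robust_effects(build_design(df, default_design_spec(df)))
    if (fit$coefficients["res:2"] > 0 && fit$coefficients["nn:30"] < 0) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("group comparison reports Kruskal-Wallis and Dunn results coherently", {
  groups <- list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1))
  rep0 <- compare_groups(groups)
  expect_equal(rep0$kw_p, 1)
  expect_true(all(rep0$pairwise$p_adj == 1))

  set.seed(12)
  shifted <- list(a = rnorm(100), b = rnorm(100) + 10, c = rnorm(100) + 20)
  rep1 <- compare_groups(shifted)
  expect_lt(rep1$kw_p, 1e-6)
  expect_equal(nrow(rep1$pairwise), 3)
  expect_true(all(rep1$pairwise$p_adj < 1e-6))
  expect_true(all(rep1$pairwise$p_adj >= rep1$pairwise$p_unadj))
  expect_equal(unname(rep1$kw_statistic),
               unname(kruskal.test(unlist(shifted),
                                   factor(rep(letters[1:3], each = 100)))$statistic))

  # with two groups, the Dunn z statistic squares to the KW statistic
  two <- list(a = rnorm(30), b = rnorm(30) + 1)
  rep2 <- compare_groups(two)
  expect_equal(rep2$pairwise$z^2, unname(rep2$kw_statistic), tolerance = 1e-9)
})

test_that("extreme-configuration extraction honors coefficients and tie order", {
  df <- make_sweep_frame(2)
  df$accuracy <- 0.6 + 0.1 * (df$res == 2)
  spec <- default_design_spec(df)
  fit <- fit_robust_effects(build_design(df, spec))
  grid <- enumerate_grid(sweep_config())
  ext <- extract_extreme_configs(fit, grid, spec)
  expect_length(ext$predicted, 192)
  expect_equal(ext$best$res, 2)
  expect_equal(ext$worst$res, 0.5)

  # exact ties resolve by grid order: first res = 2 row wins
  pure <- list(converged = TRUE, rmse = 0.01,
               coefficients = c(`(Intercept)` = 0.6, `res:2` = 0.1))
  ext2 <- extract_extreme_configs(pure, grid, spec)
  first_res2 <- which(grid$res == 2)[1]
  expect_equal(ext2$best$predicted, ext2$predicted[first_res2])
  expect_equal(unname(as.matrix(ext2$best[, c("pc", "nn")])),
               unname(as.matrix(grid[first_res2, c("pc", "nn")])))
  expect_equal(unname(as.matrix(ext2$worst[, c("pc", "nn", "res")])),
               unname(as.matrix(grid[1, c("pc", "nn", "res")])))
})
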
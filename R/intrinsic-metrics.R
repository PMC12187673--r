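#' Fixed column order of the intrinsic metric vector
#'
#' This order is the interface contract for every CSV output and for the
#' accuracy-predictor feature table.
#'
#' @return Character vector of the 15 index names.
#' @export
metric_vector_names <- function() {
  c("tss", "wc_dispersion", "ball_hall", "banfield_raftery", "pbm",
    "wemmert_gancarski", "xie_beni", "ray_turi", "mclain_rao", "c_index",
    "dunn", "silhouette", "point_biserial", "sd_scattering", "sd_separation")
}

#' Within/between scatter summary of a partitioned embedding
#'
#' All sums use Euclidean norms: `T_k` is the within trace
#' `sum_{i in C_k} ||x_i - c_k||^2`, `tss` the total scatter around the
#' barycenter, `E_T`/`E_W` the corresponding unsquared distance sums.
#'
#' @param x Numeric matrix (cells x dims).
#' @param labels Partition (factor/integer/character), K >= 2, all clusters
#'   non-empty.
#' @return A `scatter_summary` list: `barycenter`, `centroids` (K x d),
#'   `sizes`, `T_k`, `tss`, `E_T`, `E_W`.
#' @export
scatter_stats <- function(x, labels) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("undefined_partition", "need K >= 2 clusters")
  if (nrow(x) != length(labels)) stopf("invalid_input", "rows != labels")
  sizes <- as.integer(table(labels))
  centroids <- rowsum(x, labels) / sizes
  bc <- colMeans(x)
  own <- centroids[as.integer(labels), , drop = FALSE]
  d2_own <- rowSums((x - own)^2)
  d2_bc <- rowSums(sweep(x, 2, bc)^2)
  structure(
    list(
      barycenter = bc,
      centroids = unname(centroids),
      sizes = sizes,
      T_k = as.vector(rowsum(d2_own, labels)),
      tss = sum(d2_bc),
      E_T = sum(sqrt(d2_bc)),
      E_W = sum(sqrt(d2_own))
    ),
    class = "scatter_summary"
  )
}

# Internal engine: computes all 15 indices, returning values plus a named
# vector of degeneracy tags for the indices that are undefined on this
# instance (never silently imputed).
metric_vector_impl <- function(x, labels) {
  x <- as.matrix(x)
  labels <- droplevels(as.factor(labels))
  s <- scatter_stats(x, labels)
  n <- nrow(x)
  k <- length(s$sizes)
  values <- setNames(rep(NA_real_, 15), metric_vector_names())
  errors <- character(0)

  values["tss"] <- s$tss
  wc <- sum(s$T_k)
  values["wc_dispersion"] <- wc
  values["ball_hall"] <- mean(s$T_k / s$sizes)

  if (any(s$T_k == 0)) {
    errors["banfield_raftery"] <- "degenerate-cluster"
  } else {
    values["banfield_raftery"] <- sum(s$sizes * log(s$T_k / s$sizes))
  }

  cd <- pairwise_distances(s$centroids, "euclidean")
  cd_off <- cd[upper.tri(cd)]
  if (s$E_W == 0) {
    errors["pbm"] <- "degenerate-cluster"
  } else {
    values["pbm"] <- ((1 / k) * (s$E_T / s$E_W) * max(cd_off))^2
  }

  # Wemmert-Gancarski: ratio of own-centroid to nearest-other-centroid distance
  pc <- point_centroid_distances(x, s$centroids)
  li <- as.integer(labels)
  d_own <- pc[cbind(seq_len(n), li)]
  pc_other <- pc
  pc_other[cbind(seq_len(n), li)] <- Inf
  d_other <- apply(pc_other, 1, min)
  r <- ifelse(d_other > 0, d_own / d_other, ifelse(d_own == 0, 1, Inf))
  mean_r <- as.vector(rowsum(r, labels)) / s$sizes
  values["wemmert_gancarski"] <- sum(s$sizes * pmax(0, 1 - mean_r)) / n

  dmat <- pairwise_distances(x, "euclidean")
  same <- outer(li, li, "==")
  ut <- upper.tri(dmat)
  dvec <- dmat[ut]
  svec <- same[ut]
  d_between <- dvec[!svec]
  d_within <- dvec[svec]
  min_between <- min(d_between)
  values["xie_beni"] <- (wc / n) / min_between^2
  values["ray_turi"] <- (wc / n) / min(cd_off)^2

  n_w <- length(d_within)
  n_b <- length(d_between)
  if (n_w == 0) {
    errors["mclain_rao"] <- "degenerate-partition"
    errors["c_index"] <- "degenerate-partition"
  } else {
    values["mclain_rao"] <- (sum(d_within) / n_w) / (sum(d_between) / n_b)
    d_sorted <- sort(dvec)
    s_min <- sum(d_sorted[seq_len(n_w)])
    s_max <- sum(d_sorted[seq(length(dvec) - n_w + 1, length(dvec))])
    values["c_index"] <- if (s_max > s_min) (sum(d_within) - s_min) / (s_max - s_min) else 0
  }

  d_max_within <- if (n_w == 0) 0 else max(d_within)
  if (d_max_within == 0) {
    errors["dunn"] <- "degenerate-cluster"
  } else {
    values["dunn"] <- min_between / d_max_within
  }

  values["silhouette"] <- silhouette_index(dmat, li, k, s$sizes)

  if (n_w == 0 || n_b == 0 || sd(dvec) == 0) {
    errors["point_biserial"] <- "degenerate"
  } else {
    values["point_biserial"] <- cor(dvec, as.numeric(svec))
  }

  # SD index, scattering and separation reported separately
  pop_var <- function(m) colMeans(m^2) - colMeans(m)^2
  vx_norm <- sqrt(sum(pop_var(x)^2))
  scat <- vapply(seq_len(k), function(j) {
    sqrt(sum(pop_var(x[li == j, , drop = FALSE])^2))
  }, numeric(1))
  values["sd_scattering"] <- mean(scat) / vx_norm
  values["sd_separation"] <- (max(cd_off) / min(cd_off)) * sum(1 / rowSums(cd))

  list(values = values, errors = errors)
}

point_centroid_distances <- function(x, centroids) {
  # ||x_i - c_k||^2 = |x_i|^2 + |c_k|^2 - 2 x_i . c_k
  cross <- tcrossprod(x, centroids)
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") - 2 * cross
  sqrt(pmax(d2, 0))
}

silhouette_index <- function(dmat, li, k, sizes) {
  n <- length(li)
  # mean distance from each point to each cluster (own cluster: exclude self)
  sums <- rowsum(t(dmat), li)          # k x n : sum of distances to cluster j
  s_i <- numeric(n)
  for (i in seq_len(n)) {
    own <- li[i]
    if (sizes[own] == 1) { s_i[i] <- 0; next }
    a <- sums[own, i] / (sizes[own] - 1)
    b <- min(sums[-own, i] / sizes[-own])
    s_i[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  # global index: mean over clusters of the per-cluster mean silhouette
  mean(as.vector(rowsum(s_i, li)) / sizes)
}

#' Dispersion-based validity indices
#'
#' TSS, within-cluster dispersion, Ball-Hall, Banfield-Raftery, PBM,
#' Wemmert-Gancarski, Xie-Beni and Ray-Turi, computed from the scatter
#' summary of the embedding.  Degenerate inputs (a zero-trace cluster for
#' Banfield-Raftery, zero within distance sum for PBM) raise classed errors
#' rather than returning imputed values.
#'
#' @inheritParams scatter_stats
#' @return Named numeric vector of the 8 dispersion indices.
#' @export
dispersion_indices <- function(x, labels) {
  nm <- metric_vector_names()[1:8]
  pick_indices(x, labels, nm)
}

#' Pairwise-distance validity indices
#'
#' McClain-Rao, C-index, Dunn, Silhouette, Point-Biserial and the two SD
#' components (average scattering and total separation), computed from the
#' full Euclidean pairwise-distance matrix.
#'
#' @inheritParams scatter_stats
#' @return Named numeric vector of the 7 pairwise indices.
#' @export
pairwise_indices <- function(x, labels) {
  nm <- metric_vector_names()[9:15]
  pick_indices(x, labels, nm)
}

pick_indices <- function(x, labels, nm) {
  res <- metric_vector_impl(x, labels)
  bad <- intersect(names(res$errors), nm)
  if (length(bad)) {
    stopf(res$errors[[bad[1]]],
          "index %s undefined on this instance (%s)", bad[1], res$errors[[bad[1]]])
  }
  res$values[nm]
}

#' The full 15-entry intrinsic metric vector
#'
#' Concatenation of [dispersion_indices()] and [pairwise_indices()] in the
#' fixed [metric_vector_names()] order.  All indices are computed on the
#' same embedding with Euclidean distances.
#'
#' @inheritParams scatter_stats
#' @param na_on_degenerate If `TRUE`, indices that are undefined on this
#'   instance are returned as `NA` with the degeneracy tags in the
#'   `"errors"` attribute; if `FALSE` (default) the first degeneracy raises
#'   a classed error.
#' @return Named numeric vector of length 15.
#' @export
compute_metric_vector <- function(x, labels, na_on_degenerate = FALSE) {
  res <- metric_vector_impl(x, labels)
  if (length(res$errors) && !na_on_degenerate) {
    nm <- names(res$errors)[1]
    stopf(res$errors[[1]], "index %s undefined on this instance (%s)",
          nm, res$errors[[1]])
  }
  out <- res$values
  if (length(res$errors)) attr(out, "errors") <- res$errors
  out
}
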
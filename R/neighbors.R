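#' Pairwise distances under the configured metric
#'
#' @param coords Numeric matrix (cells x dims).
#' @param metric `"euclidean"` or `"cosine"` (1 - cosine similarity).
#' @return Dense symmetric distance matrix with zero diagonal.
#' @keywords internal
pairwise_distances <- function(coords, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    d <- as.matrix(dist(coords))
  } else {
    nrm <- sqrt(rowSums(coords^2))
    nrm[nrm == 0] <- 1e-12  # zero vectors: undefined angle, guard the division
    s <- tcrossprod(coords / nrm)
    s <- pmin(pmax(s, -1), 1)
    d <- 1 - s
    diag(d) <- 0
  }
  unname(d)
}

#' Build a weighted k-nearest-neighbor graph
#'
#' Finds each cell's `n_neighbors` nearest cells under `metric`, then turns
#' the directed kNN relation into a symmetric weighted adjacency:
#'
#' * `gauss`: adaptive-bandwidth kernel `w_ij = exp(-d_ij^2 / (sigma_i *
#'   sigma_j))` with `sigma_i` the distance to cell i's `n_neighbors`-th
#'   neighbor (the diffusion-maps convention), symmetrized by the maximum.
#' * `umap`: fuzzy simplicial-set connectivities — per-point `rho_i`
#'   (distance to the nearest neighbor) and `sigma_i` calibrated by binary
#'   search so the smoothed neighborhood has effective size `log2(k)`,
#'   combined by the fuzzy union `a + b - ab`; weights lie in `[0, 1]`.
#'
#' @param embedding An [pca_embed()] result, or a bare coordinate matrix.
#' @param n_neighbors Neighborhood size; must be `< n_cells`.
#' @param method `"gauss"` or `"umap"`.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return A `neighbor_graph`: list with `adjacency` (symmetric sparse
#'   `dgCMatrix`, zero diagonal), `n_neighbors`, `method`, `metric`.
#' @export
build_knn_graph <- function(embedding, n_neighbors,
                            method = c("gauss", "umap"),
                            metric = c("cosine", "euclidean")) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  coords <- if (is.list(embedding)) embedding$coords else embedding
  n <- nrow(coords)
  if (!is_count(n_neighbors) || n_neighbors >= n) {
    stopf("invalid_parameter", "need 1 <= n_neighbors < n_cells (= %d)", n)
  }
  d <- pairwise_distances(coords, metric)
  k <- as.integer(n_neighbors)
  # kNN (excluding self), deterministic tie-break by index order
  nn_idx <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    nn_idx[i, ] <- ord
    nn_dist[i, ] <- d[i, ord]
  }
  w <- if (method == "gauss") {
    gauss_connectivities(d, nn_idx, nn_dist)
  } else {
    umap_connectivities(nn_idx, nn_dist)
  }
  structure(
    list(adjacency = w, n_neighbors = k, method = method, metric = metric),
    class = "neighbor_graph"
  )
}

gauss_connectivities <- function(d, nn_idx, nn_dist) {
  n <- nrow(nn_idx)
  k <- ncol(nn_idx)
  sigma <- nn_dist[, k]
  sigma[sigma == 0] <- 1e-12
  i <- rep(seq_len(n), k)
  j <- as.vector(nn_idx)
  dij <- as.vector(nn_dist)
  wij <- exp(-dij^2 / (sigma[i] * sigma[j]))
  a <- Matrix::sparseMatrix(i = i, j = j, x = wij, dims = c(n, n))
  w <- pmax_sparse(a, Matrix::t(a))  # symmetrize by maximum
  Matrix::diag(w) <- 0
  Matrix::drop0(w)
}

umap_connectivities <- function(nn_idx, nn_dist) {
  n <- nrow(nn_idx)
  k <- ncol(nn_idx)
  target <- log2(k)
  rho <- numeric(n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    di <- nn_dist[i, ]
    pos <- di[di > 0]
    rho[i] <- if (length(pos)) min(pos) else 0
    sigma[i] <- smooth_knn_sigma(di, rho[i], target)
  }
  i <- rep(seq_len(n), k)
  j <- as.vector(nn_idx)
  m <- exp(-pmax(as.vector(nn_dist) - rho[i], 0) / sigma[i])
  a <- Matrix::sparseMatrix(i = i, j = j, x = m, dims = c(n, n))
  at <- Matrix::t(a)
  w <- a + at - a * at  # fuzzy set union
  Matrix::diag(w) <- 0
  Matrix::drop0(w)
}

# Binary search for the smooth-kNN bandwidth: find sigma with
# sum_j exp(-max(d_j - rho, 0) / sigma) = target.
smooth_knn_sigma <- function(dists, rho, target, n_iter = 64, tol = 1e-5) {
  lo <- 0
  hi <- Inf
  mid <- 1
  for (it in seq_len(n_iter)) {
    val <- sum(exp(-pmax(dists - rho, 0) / mid))
    if (abs(val - target) < tol) break
    if (val > target) {
      hi <- mid
      mid <- (lo + hi) / 2
    } else {
      lo <- mid
      mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2
    }
  }
  max(mid, 1e-12)
}

# Elementwise maximum of two non-negative sparse matrices.
pmax_sparse <- function(a, b) {
  s <- (a + b + abs(a - b)) / 2
  methods::as(s, "CsparseMatrix")
}
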
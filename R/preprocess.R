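#' Tag a cells x genes matrix with its layer
#'
#' Light wrapper used by the preprocessing chain to keep track of whether a
#' matrix holds raw counts or library-size-normalized log values.
#'
#' @param values Numeric matrix, cells x genes, with dimnames.
#' @param layer `"counts"` or `"lognorm"`.
#' @return The matrix with a `layer` attribute and class `expr_matrix`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values)) stopf("invalid_input", "values must be a matrix")
  if (layer == "counts" && any(values < 0)) {
    stopf("invalid_input", "counts layer must be non-negative")
  }
  if (is.null(rownames(values))) rownames(values) <- sprintf("cell%05d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("gene%05d", seq_len(ncol(values)))
  structure(values, layer = layer, class = c("expr_matrix", "matrix", "array"))
}

expr_layer <- function(x) attr(x, "layer") %||% "counts"

`%||%` <- function(a, b) if (is.null(a)) b else a

require_layer <- function(x, layer, op) {
  if (!identical(expr_layer(x), layer)) {
    stopf("invalid_input", "%s expects the %s layer, got %s", op, layer, expr_layer(x))
  }
}

#' Filter genes by the number of expressing cells
#'
#' Keeps exactly the genes with a nonzero count in at least `min_cells`
#' cells; the cell set is unchanged.
#'
#' @param x A counts-layer [expression_matrix()].
#' @param min_cells Minimum number of cells with nonzero expression.
#' @return The filtered counts matrix.
#' @export
filter_genes <- function(x, min_cells = 3L) {
  require_layer(x, "counts", "filter_genes")
  if (!is_count(min_cells)) stopf("invalid_input", "min_cells must be a positive integer")
  keep <- colSums(x > 0) >= min_cells
  if (!any(keep)) stopf("degenerate_input", "no gene present in >= %d cells", min_cells)
  expression_matrix(unclass(x)[, keep, drop = FALSE], "counts")
}

#' Library-size normalization and log transform
#'
#' Scales every cell to a total of `target_sum` counts and applies
#' `log1p` (natural log), the standard variance-stabilizing step before
#' HVG selection and PCA.
#'
#' @param x A counts-layer [expression_matrix()].
#' @param target_sum Per-cell total after scaling (default 1e4).
#' @return A lognorm-layer matrix.
#' @export
normalize_log <- function(x, target_sum = 1e4) {
  require_layer(x, "counts", "normalize_log")
  if (!(target_sum > 0)) stopf("invalid_input", "target_sum must be > 0")
  lib <- rowSums(x)
  if (any(lib == 0)) stopf("degenerate_input", "all-zero cell at row %d", which(lib == 0)[1])
  out <- log1p(unclass(x) * (target_sum / lib))
  expression_matrix(out, "lognorm")
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Ranks genes by their dispersion (variance / mean of the log-normalized
#' values) z-scored within 20 equal-width mean bins, a Seurat-style
#' mean-variance-plot criterion.  Ties are broken by gene id order, so the
#' selection is deterministic.
#'
#' @param x A lognorm-layer [expression_matrix()].
#' @param n_top Number of genes to retain; clamped (with a warning) to the
#'   number of genes available.
#' @param n_bins Number of mean bins (default 20).
#' @return The matrix restricted to the selected genes, in original gene
#'   order.
#' @export
select_hvg <- function(x, n_top = 2000L, n_bins = 20L) {
  require_layer(x, "lognorm", "select_hvg")
  if (!is_count(n_top)) stopf("invalid_input", "n_top must be a positive integer")
  p <- ncol(x)
  if (n_top > p) {
    warnf("n_top = %d exceeds gene count %d; clamping", n_top, p)
    n_top <- p
  }
  m <- colMeans(x)
  v <- colMeans(x^2) - m^2  # population variance; scale-consistent, deterministic
  disp <- ifelse(m > 0, v / m, 0)
  bins <- if (n_bins >= 2) {
    cut(m, breaks = n_bins, include.lowest = TRUE)
  } else {
    factor(rep("bin1", p))
  }
  z <- disp
  for (b in levels(bins)) {
    in_b <- which(bins == b)
    if (length(in_b) == 0) next
    mu <- mean(disp[in_b])
    sg <- sd(disp[in_b])
    z[in_b] <- if (is.na(sg) || sg == 0) 0 else (disp[in_b] - mu) / sg
  }
  # zero-dispersion genes rank last regardless of bin statistics
  z[disp == 0] <- -Inf
  ord <- order(-z, seq_len(p))
  keep <- sort(ord[seq_len(n_top)])
  expression_matrix(unclass(x)[, keep, drop = FALSE], "lognorm")
}

#' Principal-component embedding
#'
#' Scores of the top `n_pc` components of the column-centered (unscaled)
#' matrix.  The sign convention fixes the largest-magnitude loading of each
#' component to be positive, so embeddings are reproducible across BLAS
#' implementations.
#'
#' @param x A lognorm-layer [expression_matrix()].
#' @param n_pc Number of components; must not exceed `min(cells - 1, genes)`.
#' @return An `embedding`: list with `coords` (cells x n_pc),
#'   `explained_variance` and `n_pc`.
#' @export
pca_embed <- function(x, n_pc) {
  require_layer(x, "lognorm", "pca_embed")
  if (!is_count(n_pc)) stopf("invalid_input", "n_pc must be a positive integer")
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (n_pc > rank_max) {
    stopf("rank_deficiency", "n_pc = %d exceeds attainable rank %d", n_pc, rank_max)
  }
  pr <- prcomp(unclass(x), center = TRUE, scale. = FALSE, rank. = n_pc)
  coords <- pr$x[, seq_len(n_pc), drop = FALSE]
  rot <- pr$rotation[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      coords[, j] <- -coords[, j]
      rot[, j] <- -rot[, j]
    }
  }
  structure(
    list(coords = coords, n_pc = as.integer(n_pc),
         explained_variance = pr$sdev[seq_len(n_pc)]^2, rotation = rot),
    class = "embedding"
  )
}

#' Preprocess a count matrix end to end
#'
#' Convenience chain: [filter_genes()] -> [normalize_log()] ->
#' [select_hvg()]; returns the log-normalized HVG matrix ready for
#' [pca_embed()].
#'
#' @param counts Cells x genes count matrix.
#' @param min_cells,target_sum,n_hvg Chain parameters.
#' @return A lognorm-layer matrix.
#' @export
preprocess_counts <- function(counts, min_cells = 3L, target_sum = 1e4, n_hvg = 2000L) {
  x <- expression_matrix(as.matrix(counts), "counts")
  select_hvg(normalize_log(filter_genes(x, min_cells), target_sum), n_hvg)
}
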
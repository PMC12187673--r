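#' Define a factorial clustering-parameter grid
#'
#' The full design crosses the number of principal components, neighborhood
#' size, community-detection resolution, neighbor-graph method and distance
#' metric; the default lists give the 4 x 3 x 4 x 2 x 2 = 192-configuration
#' design.
#'
#' @param pcs Integer list of principal-component counts.
#' @param neighbors Integer list of neighborhood sizes.
#' @param resolutions Positive real list of resolutions.
#' @param methods Subset of `c("gauss", "umap")`.
#' @param metrics Subset of `c("cosine", "euclidean")`.
#' @param seed Master seed for the sweep.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(pcs = c(10L, 20L, 30L, 50L),
                         neighbors = c(10L, 20L, 30L),
                         resolutions = c(0.5, 0.8, 1, 2),
                         methods = c("gauss", "umap"),
                         metrics = c("cosine", "euclidean"),
                         seed = 1L) {
  methods <- match.arg(methods, c("gauss", "umap"), several.ok = TRUE)
  metrics <- match.arg(metrics, c("cosine", "euclidean"), several.ok = TRUE)
  if (!length(pcs) || !length(neighbors) || !length(resolutions)) {
    stopf("invalid_spec", "all parameter lists must be non-empty")
  }
  if (any(resolutions <= 0)) stopf("invalid_spec", "resolutions must be > 0")
  structure(
    list(pcs = as.integer(pcs), neighbors = as.integer(neighbors),
         resolutions = as.double(resolutions), methods = methods,
         metrics = metrics, seed = as.integer(seed)),
    class = "sweep_config"
  )
}

#' Enumerate the Cartesian configuration grid
#'
#' Fixed lexicographic order with `pc` varying slowest:
#' (pc, nn, res, method, metric).
#'
#' @param cfg A [sweep_config()].
#' @return A data.frame with one row per configuration and columns `pc`,
#'   `nn`, `res`, `method`, `metric`.
#' @export
enumerate_grid <- function(cfg) {
  g <- expand.grid(
    metric = cfg$metrics, method = cfg$methods, res = cfg$resolutions,
    nn = cfg$neighbors, pc = cfg$pcs,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, c("pc", "nn", "res", "method", "metric")]
  rownames(g) <- NULL
  g
}

#' Graph community detection at a given resolution
#'
#' Partitions all cells by Leiden modularity optimization on the weighted
#' neighbor graph (delegated to [igraph::cluster_leiden()]).  Community ids
#' are relabeled to contiguous `0..K-1` by first occurrence, so downstream
#' code never sees backend-native ids.  Isolated nodes become singleton
#' communities with a warning.
#'
#' @param graph A [build_knn_graph()] result.
#' @param resolution Positive resolution parameter.
#' @param seed Integer seed; fixed seed gives a reproducible assignment.
#' @param n_iterations Leiden refinement iterations (default 3).
#' @return A `clustering_result`: list with `assignment` (integer, 0-based),
#'   `n_clusters`, `resolution`, `seed`.
#' @export
community_cluster <- function(graph, resolution, seed = 1L, n_iterations = 3L) {
  if (!(resolution > 0)) stopf("invalid_parameter", "resolution must be > 0")
  adj <- if (inherits(graph, "neighbor_graph")) graph$adjacency else graph
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
  if (any(igraph::degree(g) == 0)) {
    warnf("graph has isolated nodes; they become singleton communities")
  }
  member <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = n_iterations
    ))
  })
  assignment <- relabel_first_occurrence(as.integer(member))
  structure(
    list(assignment = assignment, n_clusters = length(unique(assignment)),
         resolution = resolution, seed = as.integer(seed)),
    class = "clustering_result"
  )
}

relabel_first_occurrence <- function(ids) {
  match(ids, unique(ids)) - 1L
}

#' Run the full clustering sweep over subsample replicates
#'
#' For every subsample replicate and every grid configuration: preprocess,
#' embed, build the neighbor graph, cluster, score against the true labels
#' and compute the 15 intrinsic validity indices.  PCA is cached per `pc`
#' and graphs per `(pc, nn, method, metric)` within a replicate, so shared
#' stages run once.  Stage failures (e.g. degenerate single-cluster
#' partitions for some indices) are recorded per record in the `error`
#' column and the sweep continues.
#'
#' @param dataset A `synthetic_dataset` (or list with `counts`, `labels`).
#' @param subsamples A [stratified_subsample()] result.
#' @param cfg A [sweep_config()].
#' @param dataset_id Identifier written into the records.
#' @param min_cells,target_sum,n_hvg Preprocessing parameters.
#' @return A data.frame with one row per (replicate x configuration):
#'   `dataset_id`, `replicate`, `pc`, `nn`, `res`, `method`, `metric`,
#'   `n_clusters`, `accuracy`, `ari`, `nmi`, the 15 metric columns in
#'   [metric_vector_names()] order, and `error` (`NA` when clean).
#' @export
run_sweep <- function(dataset, subsamples, cfg, dataset_id = "dataset1",
                      min_cells = 3L, target_sum = 1e4, n_hvg = 2000L) {
  grid <- enumerate_grid(cfg)
  records <- vector("list", length(subsamples$replicate_indices) * nrow(grid))
  rec <- 0L
  for (r in seq_along(subsamples$replicate_indices)) {
    idx <- subsamples$replicate_indices[[r]]
    counts <- dataset$counts[idx, , drop = FALSE]
    truth <- droplevels(factor(dataset$labels[idx]))
    lognorm <- tryCatch(
      preprocess_counts(counts, min_cells, target_sum, n_hvg),
      error = function(e) e
    )
    pca_cache <- list()
    graph_cache <- list()
    for (ci in seq_len(nrow(grid))) {
      rec <- rec + 1L
      conf <- grid[ci, ]
      row <- data.frame(
        dataset_id = dataset_id, replicate = r, conf,
        n_clusters = NA_integer_, accuracy = NA_real_, ari = NA_real_,
        nmi = NA_real_, stringsAsFactors = FALSE
      )
      row[metric_vector_names()] <- NA_real_
      row$error <- NA_character_
      records[[rec]] <- tryCatch({
        if (inherits(lognorm, "error")) stop(lognorm)
        pckey <- as.character(conf$pc)
        if (is.null(pca_cache[[pckey]])) {
          pca_cache[[pckey]] <- pca_embed(lognorm, conf$pc)
        }
        emb <- pca_cache[[pckey]]
        gkey <- paste(conf$pc, conf$nn, conf$method, conf$metric, sep = "|")
        if (is.null(graph_cache[[gkey]])) {
          graph_cache[[gkey]] <- build_knn_graph(emb, conf$nn, conf$method, conf$metric)
        }
        cl_seed <- derive_seed(cfg$seed, r, ci)
        clu <- suppressWarnings(
          community_cluster(graph_cache[[gkey]], conf$res, cl_seed)
        )
        row$n_clusters <- clu$n_clusters
        sc <- score_clustering(clu$assignment, truth)
        row$accuracy <- sc$accuracy
        row$ari <- sc$ari
        row$nmi <- sc$nmi
        if (clu$n_clusters >= 2) {
          mv <- compute_metric_vector(emb$coords, clu$assignment,
                                      na_on_degenerate = TRUE)
          row[metric_vector_names()] <- as.list(unclass(mv)[metric_vector_names()])
          errs <- attr(mv, "errors")
          if (length(errs)) {
            row$error <- paste(names(errs), errs, sep = ":", collapse = ";")
          }
        } else {
          row$error <- "metrics:undefined-partition"
        }
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
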
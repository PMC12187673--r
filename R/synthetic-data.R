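#' Specify a synthetic cell-population structure
#'
#' Describes K cell populations of unequal sizes with a minority of
#' population-discriminative marker genes, negative-binomial overdispersion
#' and lognormal library-size variation — the structural features of
#' droplet scRNA-seq count matrices that the downstream validity indices
#' must tolerate.
#'
#' @param n_cells_per_cluster Integer vector of population sizes (length K,
#'   K >= 2, every size >= 2).
#' @param n_genes Number of genes.
#' @param n_marker_genes_per_cluster Marker genes elevated in each
#'   population; marker blocks are disjoint, so `K * markers <= n_genes`.
#' @param log_fold_change Log-space elevation of marker-gene means in their
#'   own population (natural log; 0 means no cluster signal).
#' @param dispersion Negative-binomial shape (size) parameter; smaller
#'   values mean more overdispersion. Must be > 0.
#' @param library_size_log_mean,library_size_log_sd Meanlog and sdlog of the
#'   lognormal per-cell library-size factor.
#' @param gene_mean_log_mean,gene_mean_log_sd Meanlog and sdlog of the
#'   lognormal baseline gene means.
#' @param seed Integer seed; identical specs generate bit-identical data.
#' @return A `population_spec` object (validated list).
#' @export
population_spec <- function(n_cells_per_cluster,
                            n_genes,
                            n_marker_genes_per_cluster = 0L,
                            log_fold_change = 1,
                            dispersion = 1,
                            library_size_log_mean = 0,
                            library_size_log_sd = 0.35,
                            gene_mean_log_mean = -1,
                            gene_mean_log_sd = 1,
                            seed = 1L) {
  spec <- structure(
    list(
      n_cells_per_cluster = as.integer(n_cells_per_cluster),
      n_genes = as.integer(n_genes),
      n_marker_genes_per_cluster = as.integer(n_marker_genes_per_cluster),
      log_fold_change = as.double(log_fold_change),
      dispersion = as.double(dispersion),
      library_size_log_mean = as.double(library_size_log_mean),
      library_size_log_sd = as.double(library_size_log_sd),
      gene_mean_log_mean = as.double(gene_mean_log_mean),
      gene_mean_log_sd = as.double(gene_mean_log_sd),
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  k <- length(spec$n_cells_per_cluster)
  if (k < 2) stopf("invalid_spec", "need K >= 2 populations, got %d", k)
  if (any(spec$n_cells_per_cluster < 2)) {
    stopf("invalid_spec", "every population needs >= 2 cells")
  }
  if (!is_count(spec$n_genes)) stopf("invalid_spec", "n_genes must be a positive integer")
  if (spec$n_marker_genes_per_cluster < 0) {
    stopf("invalid_spec", "n_marker_genes_per_cluster must be >= 0")
  }
  if (k * spec$n_marker_genes_per_cluster > spec$n_genes) {
    stopf("invalid_spec", "marker blocks (%d x %d) exceed n_genes (%d)",
          k, spec$n_marker_genes_per_cluster, spec$n_genes)
  }
  if (spec$log_fold_change < 0) stopf("invalid_spec", "log_fold_change must be >= 0")
  if (!(spec$dispersion > 0)) stopf("invalid_spec", "dispersion must be > 0")
  if (spec$library_size_log_sd < 0) stopf("invalid_spec", "library_size_log_sd must be >= 0")
  invisible(spec)
}

#' Generate a labeled synthetic count matrix
#'
#' Baseline gene means are drawn lognormal; each population elevates its own
#' disjoint marker-gene block by `exp(log_fold_change)`; counts are drawn
#' `NB(mu = libsize_factor * gene_mean, size = dispersion)` with a lognormal
#' per-cell library-size factor.  The same spec (including its seed) always
#' produces bit-identical output.
#'
#' @param spec A [population_spec()].
#' @return A `synthetic_dataset`: list with `counts` (cells x genes integer
#'   matrix), `labels` (factor, length n_cells) and `spec`.
#' @export
generate_dataset <- function(spec) {
  validate_population_spec(spec)
  k <- length(spec$n_cells_per_cluster)
  n_cells <- sum(spec$n_cells_per_cluster)
  n_genes <- spec$n_genes
  labels <- factor(rep(sprintf("pop%02d", seq_len(k)), spec$n_cells_per_cluster))

  with_seed(spec$seed, {
    base_mean <- rlnorm(n_genes, spec$gene_mean_log_mean, spec$gene_mean_log_sd)
    libf <- rlnorm(n_cells, spec$library_size_log_mean, spec$library_size_log_sd)
    # cluster-conditional gene means: disjoint marker blocks, multiplicative lfc
    mu_cluster <- matrix(rep(base_mean, each = k), nrow = k)
    m <- spec$n_marker_genes_per_cluster
    if (m > 0 && spec$log_fold_change > 0) {
      for (j in seq_len(k)) {
        idx <- ((j - 1) * m + 1):(j * m)
        mu_cluster[j, idx] <- mu_cluster[j, idx] * exp(spec$log_fold_change)
      }
    }
    cl <- as.integer(labels)
    counts <- matrix(0L, n_cells, n_genes)
    for (i in seq_len(n_cells)) {
      counts[i, ] <- rnbinom(n_genes, size = spec$dispersion,
                             mu = libf[i] * mu_cluster[cl[i], ])
    }
    # invariant: no all-zero cell; give such a cell one count in a seeded gene
    zero_cells <- which(rowSums(counts) == 0)
    for (i in zero_cells) {
      counts[i, sample.int(n_genes, 1)] <- 1L
    }
    rownames(counts) <- sprintf("cell%05d", seq_len(n_cells))
    colnames(counts) <- sprintf("gene%05d", seq_len(n_genes))
    structure(list(counts = counts, labels = labels, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d cells x %d genes, %d populations\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Stratified subsampling with largest-remainder allocation
#'
#' Draws `n_replicates` independent subsamples that preserve the relative
#' frequency of each label stratum.  Stratum `s` of size `n_s` contributes
#' its largest-remainder share of `fraction * n_s` cells, never fewer than
#' one, so rare populations are retained.  Replicates differ only through
#' per-replicate seeds derived from the master seed.
#'
#' @param labels Categorical vector (factor or character) of cell labels.
#' @param fraction Sampling fraction in (0, 1].
#' @param n_replicates Number of replicates.
#' @param seed Master integer seed.
#' @return A `subsample_set`: list with `replicate_indices` (list of sorted
#'   integer vectors), `fraction`, `seed`, `stratum_sizes`.
#' @export
stratified_subsample <- function(labels, fraction, n_replicates, seed = 1L) {
  if (length(labels) == 0) stopf("invalid_input", "labels is empty")
  if (!(fraction > 0 && fraction <= 1)) {
    stopf("invalid_input", "fraction must be in (0, 1]")
  }
  if (!is_count(n_replicates)) stopf("invalid_input", "n_replicates must be a positive integer")
  labels <- as.factor(labels)
  sizes <- table(labels)
  take <- largest_remainder(fraction * as.double(sizes))
  take <- pmax(take, 1L)
  idx_by_stratum <- split(seq_along(labels), labels)
  reps <- lapply(seq_len(n_replicates), function(r) {
    with_seed(derive_seed(seed, r), {
      picked <- unlist(lapply(seq_along(idx_by_stratum), function(s) {
        pool <- idx_by_stratum[[s]]
        if (take[s] >= length(pool)) pool else sort(sample(pool, take[s]))
      }), use.names = FALSE)
      sort(picked)
    })
  })
  structure(
    list(replicate_indices = reps, fraction = fraction, seed = as.integer(seed),
         stratum_sizes = as.integer(sizes), stratum_take = take,
         n_replicates = as.integer(n_replicates)),
    class = "subsample_set"
  )
}

# Largest-remainder rounding of non-negative quotas so the allocation sums
# to round(sum(quotas)); ties go to the earlier stratum.
largest_remainder <- function(quota) {
  base <- floor(quota)
  short <- round(sum(quota)) - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
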
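#' Map clusters to reference labels by majority vote
#'
#' Each cluster is assigned the modal ground-truth label among its members;
#' ties are broken by lexicographic label order.  With known truth this
#' modal mapping plays the role of a cluster-annotation step: it preserves
#' the quantity "agreement of the clustering with the true cell partition"
#' without requiring a trained classifier.
#'
#' @param assignment Integer cluster id per cell.
#' @param truth Ground-truth label per cell (factor or character).
#' @return A `label_mapping`: named character vector, names = cluster ids.
#' @export
map_clusters_to_labels <- function(assignment, truth) {
  check_paired(assignment, truth)
  truth <- as.character(truth)
  ids <- sort(unique(assignment))
  mapping <- vapply(ids, function(cl) {
    tab <- table(truth[assignment == cl])
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]  # lexicographic tie-break
  }, character(1))
  structure(mapping, names = as.character(ids), class = "label_mapping")
}

#' Clustering accuracy under the majority-vote mapping
#'
#' Fraction of cells whose cluster's modal label equals their true label.
#' Invariant to cluster relabeling.
#'
#' @inheritParams map_clusters_to_labels
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(assignment, truth) {
  mapping <- map_clusters_to_labels(assignment, truth)
  predicted <- unclass(mapping)[as.character(assignment)]
  mean(predicted == as.character(truth))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie ARI from the contingency table:
#' `(sum_ij C(n_ij,2) - E) / (max - E)` with the usual expectation and
#' maximum under fixed margins.  Two single-cluster partitions are
#' identical, so the degenerate `0/0` case returns 1.
#'
#' @param p,q Two partitions (any label coding) of the same cells.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p, q) {
  check_paired(p, q)
  tab <- table(p, q)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maximum <- (a + b) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Normalized mutual information
#'
#' Mutual information of the two partitions normalized by the arithmetic
#' mean of their entropies (natural logs).  If both partitions have zero
#' entropy they are identical (returns 1); if exactly one does, MI is 0 and
#' the convention 0 is returned.
#'
#' @inheritParams adjusted_rand_index
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(p, q) {
  check_paired(p, q)
  tab <- table(p, q)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  hp <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
  hq <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
  if (hp == 0 && hq == 0) return(1)
  if (hp == 0 || hq == 0) return(0)
  outer_p <- outer(pi_, pj_)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  mi / ((hp + hq) / 2)
}

#' All three extrinsic scores at once
#'
#' @inheritParams map_clusters_to_labels
#' @return Named list with `accuracy`, `ari`, `nmi`.
#' @export
score_clustering <- function(assignment, truth) {
  list(
    accuracy = clustering_accuracy(assignment, truth),
    ari = adjusted_rand_index(assignment, truth),
    nmi = normalized_mutual_information(assignment, truth)
  )
}

check_paired <- function(p, q) {
  if (length(p) == 0) stopf("invalid_input", "empty partition")
  if (length(p) != length(q)) {
    stopf("invalid_input", "partitions differ in length (%d vs %d)",
          length(p), length(q))
  }
  invisible(TRUE)
}
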
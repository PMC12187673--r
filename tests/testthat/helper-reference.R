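# Independent naive reference implementations used as oracles.  Everything
# here is written with literal loops straight from the index definitions and
# stays independent of the package's vectorized code paths.

ref_dist <- function(a, b) sqrt(sum((a - b)^2))

# All 15 validity indices by exhaustive loops; O(N^2)-O(N^3), N <= ~30.
ref_metric_vector <- function(x, labels) {
  x <- as.matrix(x)
  lab <- as.integer(factor(labels))
  n <- nrow(x)
  K <- max(lab)
  bc <- colMeans(x)
  centroids <- t(sapply(seq_len(K), function(k) colMeans(x[lab == k, , drop = FALSE])))
  if (ncol(x) == 1) centroids <- matrix(centroids, ncol = 1)
  sizes <- sapply(seq_len(K), function(k) sum(lab == k))

  tss <- 0
  for (i in seq_len(n)) tss <- tss + ref_dist(x[i, ], bc)^2
  T_k <- numeric(K)
  for (i in seq_len(n)) T_k[lab[i]] <- T_k[lab[i]] + ref_dist(x[i, ], centroids[lab[i], ])^2
  wc <- sum(T_k)
  ball_hall <- mean(T_k / sizes)
  banfield <- if (any(T_k == 0)) NA_real_ else sum(sizes * log(T_k / sizes))

  E_T <- 0
  for (i in seq_len(n)) E_T <- E_T + ref_dist(x[i, ], bc)
  E_W <- 0
  for (i in seq_len(n)) E_W <- E_W + ref_dist(x[i, ], centroids[lab[i], ])
  cd <- matrix(0, K, K)
  for (k in seq_len(K)) for (l in seq_len(K)) cd[k, l] <- ref_dist(centroids[k, ], centroids[l, ])
  pbm <- if (E_W == 0) NA_real_ else ((1 / K) * (E_T / E_W) * max(cd))^2

  wg_cluster <- numeric(K)
  for (k in seq_len(K)) {
    rs <- c()
    for (i in which(lab == k)) {
      d_own <- ref_dist(x[i, ], centroids[k, ])
      d_oth <- min(sapply(setdiff(seq_len(K), k), function(l) ref_dist(x[i, ], centroids[l, ])))
      rs <- c(rs, d_own / d_oth)
    }
    wg_cluster[k] <- max(0, 1 - mean(rs))
  }
  wg <- sum(sizes * wg_cluster) / n

  d_between <- c()
  d_within <- c()
  all_d <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d <- ref_dist(x[i, ], x[j, ])
    all_d <- c(all_d, d)
    if (lab[i] == lab[j]) d_within <- c(d_within, d) else d_between <- c(d_between, d)
  }
  xie_beni <- (wc / n) / min(d_between)^2
  ray_turi <- (wc / n) / min(cd[upper.tri(cd)])^2
  n_w <- length(d_within)
  mclain_rao <- (sum(d_within) / n_w) / (sum(d_between) / length(d_between))
  srt <- sort(all_d)
  s_min <- sum(srt[1:n_w])
  s_max <- sum(rev(srt)[1:n_w])
  c_index <- if (s_max > s_min) (sum(d_within) - s_min) / (s_max - s_min) else 0
  dunn <- if (max(d_within) == 0) NA_real_ else min(d_between) / max(d_within)

  s_i <- numeric(n)
  for (i in seq_len(n)) {
    own <- lab[i]
    if (sizes[own] == 1) { s_i[i] <- 0; next }
    a <- mean(sapply(setdiff(which(lab == own), i), function(j) ref_dist(x[i, ], x[j, ])))
    b <- min(sapply(setdiff(seq_len(K), own), function(l) {
      mean(sapply(which(lab == l), function(j) ref_dist(x[i, ], x[j, ])))
    }))
    s_i[i] <- (b - a) / max(a, b)
  }
  silhouette <- mean(sapply(seq_len(K), function(k) mean(s_i[lab == k])))

  ind <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) ind <- c(ind, as.numeric(lab[i] == lab[j]))
  point_biserial <- suppressWarnings(cor(all_d, ind))

  popvar <- function(v) mean(v^2) - mean(v)^2
  vnorm <- function(m) sqrt(sum(apply(m, 2, popvar)^2))
  sd_scat <- mean(sapply(seq_len(K), function(k) vnorm(x[lab == k, , drop = FALSE]))) / vnorm(x)
  cd_off <- cd[upper.tri(cd)]
  sep_sum <- 0
  for (k in seq_len(K)) sep_sum <- sep_sum + 1 / sum(cd[k, -k])
  sd_sep <- (max(cd_off) / min(cd_off)) * sep_sum

  c(tss = tss, wc_dispersion = wc, ball_hall = ball_hall,
    banfield_raftery = banfield, pbm = pbm, wemmert_gancarski = wg,
    xie_beni = xie_beni, ray_turi = ray_turi, mclain_rao = mclain_rao,
    c_index = c_index, dunn = dunn, silhouette = silhouette,
    point_biserial = point_biserial, sd_scattering = sd_scat,
    sd_separation = sd_sep)
}

# Random instance with every cluster size >= 2 (avoids degenerate indices).
random_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:30, 1)
  d <- sample(1:5, 1)
  K <- sample(2:4, 1)
  while (n < 2 * K) n <- n + 1
  lab <- c(rep(seq_len(K), 2), sample(seq_len(K), n - 2 * K, replace = TRUE))
  x <- matrix(rnorm(n * d, mean = 3 * lab), n, d)
  list(x = x, labels = lab)
}

# ARI by O(n^2) pair agreement counting.
ref_ari <- function(p, q) {
  n <- length(p)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    sp <- p[i] == p[j]
    sq <- q[i] == q[j]
    if (sp && sq) a <- a + 1
    else if (sp && !sq) b <- b + 1
    else if (!sp && sq) c_ <- c_ + 1
    else d <- d + 1
  }
  tot <- a + b + c_ + d
  expected <- (a + b) * (a + c_) / tot
  maximum <- ((a + b) + (a + c_)) / 2
  if (maximum == expected) return(1)
  (a - expected) / (maximum - expected)
}

# NMI by literal plug-in entropies (natural log, arithmetic-mean norm).
ref_nmi <- function(p, q) {
  n <- length(p)
  ent <- function(v) {
    pr <- table(v) / n
    -sum(pr * log(pr))
  }
  hp <- ent(p)
  hq <- ent(q)
  if (hp == 0 && hq == 0) return(1)
  if (hp == 0 || hq == 0) return(0)
  mi <- 0
  for (u in unique(p)) for (v in unique(q)) {
    pij <- sum(p == u & q == v) / n
    if (pij > 0) mi <- mi + pij * log(pij / ((sum(p == u) / n) * (sum(q == v) / n)))
  }
  mi / ((hp + hq) / 2)
}

# All set partitions of 1..n (restricted-growth strings); n <= 8 in tests.
all_partitions <- function(n) {
  out <- list()
  grow <- function(rgs, mx) {
    k <- length(rgs)
    if (k == n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(mx + 1)) grow(c(rgs, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# Resolution-parameterized Newman modularity of a weighted partition.
ref_modularity <- function(adj, membership, gamma = 1) {
  adj <- as.matrix(adj)
  m2 <- sum(adj)
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj))) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - gamma * deg[i] * deg[j] / m2
    }
  }
  q / m2
}

# Small labeled dataset + sweep used by several test files.
tiny_dataset <- function(seed = 7, k_sizes = c(60, 50, 40), n_genes = 300,
                         lfc = 2, dispersion = 1.5) {
  generate_dataset(population_spec(
    n_cells_per_cluster = k_sizes, n_genes = n_genes,
    n_marker_genes_per_cluster = 10L, log_fold_change = lfc,
    dispersion = dispersion, seed = seed
  ))
}
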
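# Independent oracles, deliberately written against different formulations
# than the package internals.

# Naive O(n^3) Ward agglomeration via the Lance-Williams update on Euclidean
# distances (ward.D2 parameterization).  Tracks the flat partition after each
# merge; returns a list mapping k -> canonical labels.  Ties broken toward
# the lexicographically smallest (i, j) pair.
naive_ward_partitions <- function(X) {
  n <- ncol(X)
  d <- as.matrix(stats::dist(t(X)))
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  partitions <- list()
  labels_at <- function() {
    lab <- integer(n)
    for (ci in seq_along(members))
      if (length(members[[ci]])) lab[members[[ci]]] <- ci
    canonical_labels(lab)
  }
  partitions[[n]] <- labels_at()
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_len(a - 1L)) {
        i <- active[b]; j <- active[a]   # i < j
        if (d[i, j] < best_d - 1e-12) { best <- c(i, j); best_d <- d[i, j] }
      }
    }
    i <- best[1L]; j <- best[2L]
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d_new <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                       nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- d_new
    }
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- integer(0)
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    partitions[[n - step]] <- labels_at()
  }
  partitions
}

# canonical renumbering by first appearance, for comparing partitions
canonical_labels <- function(lab) match(lab, unique(lab))

# Calinski-Harabasz via the total-scatter decomposition tr(B) = tr(T) - tr(W)
# (the package computes tr(B) directly from centroids).
chi_oracle <- function(X, labels) {
  X <- if (is.matrix(X)) X else rbind(X)
  n <- ncol(X); k <- length(unique(labels))
  tr_T <- sum((X - rowMeans(X))^2)
  tr_W <- 0
  for (q in unique(labels)) {
    Xq <- X[, labels == q, drop = FALSE]
    tr_W <- tr_W + sum((Xq - rowMeans(Xq))^2)
  }
  ((tr_T - tr_W) / tr_W) * (n - k) / (k - 1)
}

# small deterministic fixture matrix used across IO tests
fixture_matrix <- function() {
  sparse_data_matrix(matrix(c(1, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE,
                            dimnames = list(c("gA", "gB", "gC"),
                                            c("s1", "s2"))))
}

write_fixture_tsv <- function(path) {
  writeLines(c("feature_id\ts1\ts2", "gA\t1\t0", "gB\t0\t1", "gC\t1\t1"),
             path)
  path
}
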
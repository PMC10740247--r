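#' Entropy of a partition
#'
#' Shannon entropy of the cluster membership proportions,
#' `-sum(p_k * log(p_k))` in nats with `0 * log(0) = 0`.  It is 0 when all
#' samples fall in one cluster and maximal (`log k`) when clusters are equal
#' sized; small entropy flags the unstable situation where most samples sit
#' in one large cluster and the rest in a few tiny ones.
#'
#' @param assignment a [cluster_assignment()] (or a bare label vector).
#' @return Entropy in nats, a value in `[0, log(k)]`.
#' @export
cluster_entropy <- function(assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  p <- tabulate(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Calinski-Harabasz index
#'
#' Ratio of the between-cluster to within-cluster scatter traces, scaled by
#' `(n - k) / (k - 1)`:
#' \deqn{s = \frac{tr(B_k)}{tr(W_k)} \cdot \frac{n - k}{k - 1}}
#' where `W_k` sums squared deviations of each sample from its cluster
#' centroid and `B_k` sums squared deviations of the (size-weighted) cluster
#' centroids from the global centroid.  Larger values indicate tighter,
#' better-separated clusters.  The index is translation invariant and, since
#' the scale cancels in the trace ratio, invariant under isotropic scaling.
#'
#' @param points numeric matrix with samples as columns (feature vectors as
#'   in the rest of the package), or a plain vector for 1-D data.
#' @param assignment a [cluster_assignment()] (or a bare label vector)
#'   covering the samples in column order.
#' @return The index, a positive real.
#' @examples
#' calinski_harabasz(c(0, 1, 10, 11), c(1, 1, 2, 2))  # 200
#' @export
calinski_harabasz <- function(points, assignment) {
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$labels else as.integer(assignment)
  X <- if (is.matrix(points)) unclass_matrix(points) else rbind(points)
  n <- ncol(X)
  if (n != length(labels))
    stop("number of samples (", n, ") != number of labels (", length(labels),
         ")", call. = FALSE)
  k <- length(unique(labels))
  if (k < 2L)
    stop("Calinski-Harabasz requires at least 2 clusters (k - 1 division)",
         call. = FALSE)
  if (n <= k)
    stop("need more samples than clusters", call. = FALSE)
  global <- rowMeans(X)
  tr_W <- 0; tr_B <- 0
  for (q in unique(labels)) {
    Xq <- X[, labels == q, drop = FALSE]
    cq <- rowMeans(Xq)
    tr_W <- tr_W + sum((Xq - cq)^2)
    tr_B <- tr_B + ncol(Xq) * sum((cq - global)^2)
  }
  if (tr_W == 0)
    stop("degenerate clustering: within-cluster scatter is zero",
         call. = FALSE)
  (tr_B / tr_W) * (n - k) / (k - 1)
}

#' Entropy / Calinski-Harabasz sweep over cluster numbers
#'
#' For every `k` in `k_range`, clusters with the weighted pipeline and
#' evaluates partition entropy and the Calinski-Harabasz index; with
#' `baseline = TRUE` the unweighted Euclidean Ward baseline is evaluated
#' alongside.  By default each algorithm is scored in its own operating
#' space: the weighted labels on the correction-matrix sample vectors, the
#' baseline on the raw ones (`chi_space` switches the weighted scoring to the
#' raw space).
#'
#' @param matrix a [sparse_data_matrix()].
#' @param k_range integer vector of cluster numbers (default 2:15).
#' @param poly,mode weighting configuration, see [pwsc_cluster()].
#' @param baseline also evaluate the conventional Euclidean baseline.
#' @param chi_space `"weighted"` (default) or `"raw"`: the space in which the
#'   weighted algorithm's CHI is computed.
#' @return Data frame with one row per (k, algorithm): columns `k`,
#'   `algorithm` (`"pwsc"` / `"conventional"`), `entropy`, `chi`.
#' @export
metrics_sweep <- function(matrix, k_range = 2:15, poly = polynomial_spec(),
                          mode = c("nonzero_count", "row_sum"),
                          baseline = TRUE,
                          chi_space = c("weighted", "raw")) {
  mode <- match.arg(mode)
  chi_space <- match.arg(chi_space)
  k_range <- sort(unique(as.integer(k_range)))
  scheme <- weight_scheme(matrix, poly, mode)
  corrected <- apply_weights(matrix, scheme)
  dend_w <- ward_linkage(corrected)
  space_w <- if (chi_space == "weighted") corrected else unclass_matrix(matrix)
  rows <- lapply(k_range, function(k) {
    a <- cut_tree(dend_w, k)
    data.frame(k = k, algorithm = "pwsc", entropy = cluster_entropy(a),
               chi = calinski_harabasz(space_w, a))
  })
  if (baseline) {
    dend_r <- ward_linkage(matrix)
    rows_b <- lapply(k_range, function(k) {
      a <- cut_tree(dend_r, k)
      data.frame(k = k, algorithm = "conventional",
                 entropy = cluster_entropy(a),
                 chi = calinski_harabasz(unclass_matrix(matrix), a))
    })
    rows <- c(rows, rows_b)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney comparison of two metric curves
#'
#' Wilcoxon rank-sum test (midrank ties, exact p-value where available,
#' normal approximation otherwise) between two sets of metric values, e.g.
#' the entropy curves of the weighted and baseline algorithms over a range
#' of k.  The statistic `W` counts, with ties at 1/2, the pairs in which a
#' value of `a` exceeds a value of `b`.
#'
#' @param values_a,values_b non-empty numeric vectors.
#' @param alternative passed to [stats::wilcox.test()] (default
#'   `"two.sided"`).
#' @return List with `W` (the rank-sum statistic for `values_a`) and
#'   `p_value`.
#' @export
compare_curves <- function(values_a, values_b, alternative = "two.sided") {
  if (!length(values_a) || !length(values_b))
    stop("both samples must be non-empty", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = alternative))
  list(W = unname(ht$statistic), p_value = ht$p.value)
}
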
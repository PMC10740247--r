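#' Ward agglomerative clustering of samples
#'
#' Clusters the columns (samples) of a matrix by Ward's minimum-variance
#' agglomeration: at each step the pair of clusters whose merge least
#' increases the total within-cluster sum of squared deviations is joined.
#' Pairwise sample distances are Euclidean distances between column vectors,
#' and heights follow the convention in which merging two singletons has
#' height equal to their Euclidean distance (the `ward.D2` parameterization
#' of the Lance-Williams update), so heights are non-decreasing along the
#' merge order.
#'
#' @param matrix numeric matrix with samples as columns (a
#'   [sparse_data_matrix()] or [apply_weights()] output).
#' @return An object of class `pwsc_dendrogram`: a list with `merges` (the
#'   `(n-1) x 2` merge table in `stats::hclust` encoding), `heights`,
#'   `n_leaves`, `sample_ids` and the underlying `hclust` object.
#' @export
ward_linkage <- function(matrix) {
  n <- ncol(matrix)
  if (is.null(n) || n < 2L)
    stop("at least two sample columns are required", call. = FALSE)
  d <- stats::dist(t(unclass_matrix(matrix)), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  structure(list(merges = hc$merge, heights = hc$height, n_leaves = n,
                 sample_ids = colnames(matrix), hclust = hc),
            class = "pwsc_dendrogram")
}

#' @export
print.pwsc_dendrogram <- function(x, ...) {
  cat(sprintf("Ward dendrogram over %d samples (%d merges)\n",
              x$n_leaves, nrow(x$merges)))
  invisible(x)
}

#' Flat cluster assignment
#'
#' Container for a flat partition of samples into `k` clusters.  Labels are
#' canonicalized so clusters are numbered by first appearance in sample
#' order, making partitions comparable across runs regardless of the
#' labelling produced upstream.
#'
#' @param labels integer vector of cluster labels.
#' @param sample_ids character vector of sample identifiers.
#' @param canonicalize renumber clusters by first appearance (default TRUE).
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (integers in `1..k`, every value present), `k`, `sample_ids`.
#' @export
cluster_assignment <- function(labels, sample_ids = names(labels),
                               canonicalize = TRUE) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("labels must be integers", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_along(labels))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != length(labels))
    stop("sample_ids and labels differ in length", call. = FALSE)
  if (canonicalize) {
    first <- unique(labels)
    labels <- match(labels, first)
  }
  k <- max(labels)
  if (!setequal(unique(labels), seq_len(k)))
    stop("labels must cover 1..k with every cluster non-empty", call. = FALSE)
  structure(list(labels = labels, k = k, sample_ids = sample_ids),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster assignment: %d samples in %d clusters (sizes %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Cut a dendrogram into k flat clusters
#'
#' Undoes the last `k - 1` merges of the dendrogram, yielding exactly `k`
#' clusters, with labels canonicalized by first appearance.
#'
#' @param dendrogram a [ward_linkage()] result.
#' @param k integer number of clusters, `1 <= k <= n_leaves`.
#' @return A [cluster_assignment()].
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "pwsc_dendrogram"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > dendrogram$n_leaves)
    stop("k must be a single integer in [1, ", dendrogram$n_leaves, "]",
         call. = FALSE)
  labels <- stats::cutree(dendrogram$hclust, k = k)
  cluster_assignment(labels, dendrogram$sample_ids)
}

#' Polynomial weight-adjusted sparse clustering
#'
#' The full clustering pipeline: compute per-feature frequencies, evaluate
#' the weighting polynomial, normalize into weights, rescale the matrix rows,
#' then Ward-cluster the reweighted samples and cut at `k`.
#'
#' @param matrix a [sparse_data_matrix()].
#' @param k number of clusters.
#' @param poly a [polynomial_spec()]; default the quartic monomial `eta^4`.
#' @param mode frequency mode, see [compute_frequencies()].
#' @return A [cluster_assignment()] with attributes `"scheme"` (the
#'   [weight_scheme()] used) and `"dendrogram"`.
#' @examples
#' sim <- generate_planted(synthetic_spec(m = 40, n = 30, k_true = 2, seed = 1))
#' a <- pwsc_cluster(sim$matrix, k = 2)
#' table(a$labels, sim$labels)
#' @export
pwsc_cluster <- function(matrix, k, poly = polynomial_spec(),
                         mode = c("nonzero_count", "row_sum")) {
  mode <- match.arg(mode)
  scheme <- weight_scheme(matrix, poly, mode)
  corrected <- apply_weights(matrix, scheme)
  dend <- ward_linkage(corrected)
  out <- cut_tree(dend, k)
  attr(out, "scheme") <- scheme
  attr(out, "dendrogram") <- dend
  out
}

#' Conventional Euclidean-distance baseline clustering
#'
#' Ward clustering of the raw, unweighted matrix columns — the baseline every
#' metric contrast is made against.
#'
#' @inheritParams pwsc_cluster
#' @return A [cluster_assignment()] with attribute `"dendrogram"`.
#' @export
conventional_cluster <- function(matrix, k) {
  dend <- ward_linkage(matrix)
  out <- cut_tree(dend, k)
  attr(out, "dendrogram") <- dend
  out
}
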
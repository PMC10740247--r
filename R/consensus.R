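#' Resampling plan for consensus clustering
#'
#' Controls the Monti-style perturbation scheme: `n_iterations` subsamples of
#' `round(sample_fraction * N)` samples (at least 2) are drawn without
#' replacement and clustered.  With `reweight_per_subsample = TRUE` (default)
#' the frequency/weighting pipeline is recomputed inside each perturbed
#' dataset, i.e. the whole weighted clustering algorithm is the base
#' clusterer of the resampling scheme; with `FALSE` the full-data weights are
#' reused.
#'
#' @param n_iterations number of resampling iterations H (default 1000).
#' @param sample_fraction fraction f of samples per subsample, in (0, 1]
#'   (default 0.8).
#' @param seed integer seed driving all resampling randomness.
#' @param reweight_per_subsample logical, see above.
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_iterations = 1000, sample_fraction = 0.8,
                            seed = 1L, reweight_per_subsample = TRUE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed),
                 reweight_per_subsample = isTRUE(reweight_per_subsample)),
            class = "resampling_plan")
}

#' Connectivity and indicator matrices for one resampled clustering
#'
#' For an assignment of the samples in `subset` (indices into the full sample
#' set of size `n`), returns `M` with `M[i, j] = 1` iff samples i and j were
#' both in the subset and co-clustered, and `U` with `U[i, j] = 1` iff both
#' were in the subset.  Rows/columns of samples outside the subset are all
#' zero, diagonal included.
#'
#' @param assignment a [cluster_assignment()] covering exactly the subset, in
#'   subset order.
#' @param subset integer indices of the resampled samples in the full set.
#' @param n total number of samples N.
#' @return List with 0/1 integer matrices `M` and `U`, both `n x n` and
#'   symmetric.
#' @export
connectivity_matrix <- function(assignment, subset, n) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  subset <- as.integer(subset)
  if (length(subset) != length(assignment$labels))
    stop("assignment covers ", length(assignment$labels),
         " samples but subset has ", length(subset), call. = FALSE)
  if (any(subset < 1L | subset > n) || anyDuplicated(subset))
    stop("subset must be distinct indices in 1..n", call. = FALSE)
  M <- matrix(0L, n, n)
  U <- matrix(0L, n, n)
  U[subset, subset] <- 1L
  M[subset, subset] <- outer(assignment$labels, assignment$labels, "==") * 1L
  list(M = M, U = U)
}

#' Assemble a consensus matrix from connectivity/indicator matrices
#'
#' The consensus index of a sample pair is the number of times it was
#' co-clustered divided by the number of times it was co-selected.  Pairs
#' never co-selected get consensus 0 by convention (with a warning); the
#' diagonal is forced to 1.
#'
#' @param connectivities list of N x N 0/1 connectivity matrices M^h.
#' @param indicators list of N x N 0/1 indicator matrices U^h, same length.
#' @param k the cluster number these runs used (recorded, optional).
#' @return An object of class `consensus_result`: list with `k`, `consensus`
#'   (N x N in \[0, 1\], symmetric, unit diagonal), `co_cluster_counts`,
#'   `co_select_counts`.
#' @export
consensus_matrix <- function(connectivities, indicators, k = NA_integer_) {
  if (!length(connectivities) || length(connectivities) != length(indicators))
    stop("need equal-length non-empty lists of connectivity and indicator ",
         "matrices", call. = FALSE)
  M <- Reduce(`+`, connectivities)
  U <- Reduce(`+`, indicators)
  consensus_from_counts(M, U, k)
}

consensus_from_counts <- function(co_cluster, co_select, k = NA_integer_) {
  never <- co_select == 0
  diag(never) <- FALSE
  if (any(never))
    warning(sum(never) / 2, " sample pair(s) were never co-selected; ",
            "their consensus is set to 0", call. = FALSE)
  C <- ifelse(co_select > 0, co_cluster / pmax(co_select, 1L), 0)
  diag(C) <- 1
  dimnames(C) <- dimnames(co_cluster)
  structure(list(k = as.integer(k), consensus = C,
                 co_cluster_counts = co_cluster,
                 co_select_counts = co_select),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus matrix (k = %s) over %d samples\n",
              x$k, nrow(x$consensus)))
  invisible(x)
}

#' Monti consensus clustering over a range of cluster numbers
#'
#' Draws `plan$n_iterations` subsamples of the columns, clusters each with
#' the weighted Ward pipeline, and accumulates, for every `k` in `k_range`,
#' how often each sample pair was co-clustered relative to how often it was
#' co-selected.  One Ward tree is built per subsample and cut at every `k`.
#' Results are deterministic given `plan$seed` (per-iteration seeds are
#' derived from it up front).
#'
#' An iteration is re-drawn (with a message) if its subsample cannot be
#' clustered, e.g. all entries zero so no feature carries weight; after 100
#' consecutive failures the run aborts.
#'
#' @param matrix a [sparse_data_matrix()].
#' @param k_range integer vector of cluster numbers, each in `[2, N - 1]`.
#' @param plan a [resampling_plan()].
#' @param poly,mode weighting configuration, see [pwsc_cluster()].
#' @param weighted set `FALSE` to run the consensus scheme over the
#'   unweighted Euclidean baseline instead.
#' @return A list of [consensus_matrix()] results, one per `k`, named
#'   `"k=<k>"`.
#' @export
run_consensus <- function(matrix, k_range = 2:15, plan = resampling_plan(),
                          poly = polynomial_spec(),
                          mode = c("nonzero_count", "row_sum"),
                          weighted = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "resampling_plan"))
  N <- ncol(matrix)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > N - 1L))
    stop("k_range must lie within [2, N-1]", call. = FALSE)
  size <- max(2L, as.integer(round(plan$sample_fraction * N)))
  if (size < max(k_range))
    stop("subsample size ", size, " is smaller than max(k_range) = ",
         max(k_range), "; increase sample_fraction or lower k", call. = FALSE)

  full_weights <- if (weighted && !plan$reweight_per_subsample)
    weight_scheme(matrix, poly, mode, warn_zero = FALSE)$weights

  set.seed(plan$seed)
  iter_seeds <- sample.int(.Machine$integer.max, plan$n_iterations)

  co_cluster <- lapply(k_range, function(k) matrix(0L, N, N))
  names(co_cluster) <- paste0("k=", k_range)
  co_select <- matrix(0L, N, N)

  h <- 1L
  failures <- 0L
  while (h <= plan$n_iterations) {
    set.seed(iter_seeds[h])
    idx <- sort(sample.int(N, size))
    sub <- unclass_matrix(matrix)[, idx, drop = FALSE]
    dend <- tryCatch({
      corrected <- if (!weighted) sub
        else if (plan$reweight_per_subsample)
          apply_weights_raw(sub, weight_scheme(sub, poly, mode,
                                               warn_zero = FALSE)$weights)
        else apply_weights_raw(sub, full_weights)
      ward_linkage(corrected)
    }, error = function(e) e)
    if (inherits(dend, "error")) {
      failures <- failures + 1L
      message("consensus iteration ", h, " re-drawn: ",
              conditionMessage(dend))
      if (failures >= 100L)
        stop("100 consecutive resampling failures; last error: ",
             conditionMessage(dend), call. = FALSE)
      iter_seeds[h] <- iter_seeds[h] %% .Machine$integer.max + 1L
      next
    }
    failures <- 0L
    co_select[idx, idx] <- co_select[idx, idx] + 1L
    for (j in seq_along(k_range)) {
      lab <- stats::cutree(dend$hclust, k = k_range[j])
      same <- outer(lab, lab, "==") * 1L
      co_cluster[[j]][idx, idx] <- co_cluster[[j]][idx, idx] + same
    }
    h <- h + 1L
  }

  out <- lapply(seq_along(k_range), function(j) {
    cc <- co_cluster[[j]]
    dimnames(cc) <- list(colnames(matrix), colnames(matrix))
    cs <- co_select
    dimnames(cs) <- dimnames(cc)
    consensus_from_counts(cc, cs, k_range[j])
  })
  names(out) <- paste0("k=", k_range)
  out
}

# row scaling without sparse_data_matrix validation (used on subsamples,
# where a feature may legitimately vanish)
apply_weights_raw <- function(values, weights) values * as.numeric(weights)

#' Consensus CDF, PAC and area summaries
#'
#' Summarizes the stability of a consensus matrix via the empirical CDF of
#' its `N(N-1)/2` upper-triangle entries.  The proportion of ambiguous
#' clustering (PAC) is the CDF mass falling in `(u1, u2]` — the fraction of
#' sample pairs whose co-clustering was inconsistent across resampling runs;
#' a flat CDF middle (low PAC) marks a stable k.  The area under the CDF is
#' computed by the trapezoid rule over `[0, 1]`.
#'
#' @param result a [consensus_matrix()] result (or a bare consensus matrix).
#' @param u1,u2 ambiguity thresholds, defaults 0.1 and 0.9.
#' @return An object of class `cdf_summary`: list with `k`, `cdf` (a step
#'   function), `pac`, `area`, `u1`, `u2`.
#' @export
consensus_cdf <- function(result, u1 = 0.1, u2 = 0.9) {
  C <- if (inherits(result, "consensus_result")) result$consensus else result
  k <- if (inherits(result, "consensus_result")) result$k else NA_integer_
  if (!(u1 >= 0 && u1 < u2 && u2 <= 1))
    stop("need 0 <= u1 < u2 <= 1", call. = FALSE)
  vals <- C[upper.tri(C)]
  cdf <- stats::ecdf(vals)
  xs <- c(0, sort(unique(vals)), 1)
  ys <- cdf(xs)
  area <- sum(diff(xs) * (utils::head(ys, -1L) + utils::tail(ys, -1L)) / 2)
  structure(list(k = k, cdf = cdf, pac = cdf(u2) - cdf(u1), area = area,
                 u1 = u1, u2 = u2),
            class = "cdf_summary")
}

#' @export
print.cdf_summary <- function(x, ...) {
  cat(sprintf("consensus CDF (k = %s): PAC = %.4f, area = %.4f\n",
              x$k, x$pac, x$area))
  invisible(x)
}

#' Select the number of clusters from consensus summaries
#'
#' `criterion = "pac_min"` picks the k with the lowest PAC; ties go to the
#' smaller k, since a larger number of clusters gives a less stable (and more
#' costly) classification.  `criterion = "delta_area"` computes the relative
#' change in area under successive CDF curves — `delta(k_min) = area(k_min)`,
#' `delta(k) = (area(k) - area(k-1)) / area(k-1)` — and picks the smallest k
#' at a local peak of that curve.  The full per-k table is returned either
#' way so the trade-off can be inspected directly.
#'
#' @param summaries list of [consensus_cdf()] summaries (at least 2).
#' @param criterion `"pac_min"` (default) or `"delta_area"`.
#' @return List with `k` (the selected cluster number), `criterion`, and
#'   `table`, a data frame with columns `k`, `pac`, `area`, `delta_area`.
#' @export
select_optimal_k <- function(summaries, criterion = c("pac_min",
                                                      "delta_area")) {
  criterion <- match.arg(criterion)
  if (length(summaries) < 2L)
    stop("need summaries for at least two values of k", call. = FALSE)
  ks <- vapply(summaries, function(s) as.numeric(s$k), 0)
  o <- order(ks)
  ks <- ks[o]
  pac <- vapply(summaries, `[[`, 0, "pac")[o]
  area <- vapply(summaries, `[[`, 0, "area")[o]
  delta <- c(area[1L], diff(area) / utils::head(area, -1L))
  tab <- data.frame(k = ks, pac = pac, area = area, delta_area = delta)
  k_sel <- if (criterion == "pac_min") {
    ks[which.min(pac)]  # which.min takes the first minimum: the smaller k
  } else {
    dk <- delta[-1L]
    kk <- ks[-1L]
    if (length(dk) == 0L) ks[1L] else {
      peaks <- which(dk >= c(-Inf, utils::head(dk, -1L)) &
                     dk >= c(utils::tail(dk, -1L), -Inf))
      if (length(peaks)) kk[peaks[1L]] else kk[which.max(dk)]
    }
  }
  list(k = k_sel, criterion = criterion, table = tab)
}
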
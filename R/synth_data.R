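#' Specification for a planted-cluster sparse matrix
#'
#' Describes a synthetic feature-by-sample matrix with `k_true` planted
#' sample clusters.  Each cluster owns a disjoint set of `n_signature`
#' signature features, present in its own samples with probability
#' `p_signature`; every other entry is present with probability
#' `p_background`.  With `value_model = "lognormal_abundance"` each presence
#' is multiplied by a positive lognormal magnitude (meanlog 0, sdlog 1),
#' emulating relative-abundance data; `"binary"` leaves 0/1 indicators,
#' emulating mutation presence/absence.
#'
#' The expected matrix density has the closed form
#' `(n_signature * p_signature + (m - n_signature) * p_background) / m`
#' (independent of the cluster proportions when signature set sizes are
#' equal), which is what the presets are calibrated against.
#'
#' @param m,n numbers of features and samples.
#' @param k_true number of planted clusters.
#' @param proportions cluster mixing proportions (default equal); must sum
#'   to 1.
#' @param n_signature signature features per cluster (default 10).
#' @param p_signature presence probability of a signature feature inside its
#'   own cluster (default 0.6).
#' @param p_background presence probability everywhere else (default 0.01);
#'   must be `< p_signature`.
#' @param value_model `"binary"` (default) or `"lognormal_abundance"`.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m, n, k_true, proportions = NULL,
                           n_signature = 10L, p_signature = 0.6,
                           p_background = 0.01,
                           value_model = c("binary", "lognormal_abundance"),
                           seed = 1L) {
  value_model <- match.arg(value_model)
  if (is.null(proportions)) proportions <- rep(1 / k_true, k_true)
  if (length(proportions) != k_true || abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must have length k_true and sum to 1", call. = FALSE)
  if (!(p_background >= 0 && p_background < p_signature && p_signature <= 1))
    stop("need 0 <= p_background < p_signature <= 1", call. = FALSE)
  if (k_true * n_signature > m)
    stop("infeasible: ", k_true, " clusters x ", n_signature,
         " signature features exceed m = ", m, call. = FALSE)
  structure(list(m = as.integer(m), n = as.integer(n),
                 k_true = as.integer(k_true), proportions = proportions,
                 n_signature = as.integer(n_signature),
                 p_signature = p_signature, p_background = p_background,
                 value_model = value_model, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Expected density of a synthetic specification
#' @param spec a [synthetic_spec()].
#' @return Expected fraction of non-zero entries, in closed form.
#' @export
expected_density <- function(spec) {
  (spec$n_signature * spec$p_signature +
     (spec$m - spec$n_signature) * spec$p_background) / spec$m
}

#' Generate a planted-cluster sparse matrix
#'
#' Draws the matrix described by a [synthetic_spec()]: samples are assigned
#' to clusters by the mixing proportions (each cluster is guaranteed at
#' least one sample), presences are independent Bernoulli draws, and
#' abundances (if requested) are lognormal.  Deterministic given
#' `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with `matrix` (a [sparse_data_matrix()]), `labels` (the
#'   planted cluster of each sample) and `signature_features` (list of
#'   feature-ID vectors per cluster).
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m; n <- spec$n; k <- spec$k_true
  sizes <- pmax(1L, as.integer(round(spec$proportions * n)))
  while (sum(sizes) != n) {  # fix rounding drift on the largest cluster
    j <- which.max(sizes)
    sizes[j] <- sizes[j] + sign(n - sum(sizes))
  }
  labels <- rep(seq_len(k), times = sizes)
  feature_names <- sprintf("feature_%03d", seq_len(m))
  sig <- split(seq_len(k * spec$n_signature),
               rep(seq_len(k), each = spec$n_signature))
  p <- matrix(spec$p_background, m, n)
  for (q in seq_len(k))
    p[sig[[q]], labels == q] <- spec$p_signature
  vals <- matrix(as.numeric(stats::runif(m * n) < p), m, n)
  if (spec$value_model == "lognormal_abundance") {
    nz <- vals > 0
    vals[nz] <- vals[nz] * stats::rlnorm(sum(nz))
  }
  rownames(vals) <- feature_names
  colnames(vals) <- sprintf("sample_%03d", seq_len(n))
  list(matrix = sparse_data_matrix(vals), labels = labels,
       signature_features = lapply(sig, function(i) feature_names[i]))
}

#' Synthetic presets shaped like the two motivating cohorts
#'
#' Two ready-made [synthetic_spec()]s emulating the package's motivating
#' data shapes: `gastric_like`, a 69 x 331 binary mutation-style matrix with
#' about 1.6% non-zero entries in 4 planted clusters, and `colon_like`, a
#' 221 x 195 lognormal-abundance matrix with about 4% non-zero entries in 5
#' planted clusters.  Only the shape, sparsity and value model are emulated,
#' not the biology.
#'
#' @param seed integer seed stored in both specs.
#' @return Named list of `synthetic_spec` objects.
#' @export
cohort_presets <- function(seed = 1L) {
  list(
    gastric_like = synthetic_spec(
      m = 69, n = 331, k_true = 4, n_signature = 3L,
      p_signature = 0.25, p_background = 0.005,
      value_model = "binary", seed = seed),
    colon_like = synthetic_spec(
      m = 221, n = 195, k_true = 5, n_signature = 8L,
      p_signature = 0.5, p_background = 0.0225,
      value_model = "lognormal_abundance", seed = seed)
  )
}
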
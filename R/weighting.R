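#' Weighting polynomial specification
#'
#' The feature weighting is driven by a polynomial
#' `P(eta) = a_0 + a_1 eta + ... + a_n eta^n` of the feature's observation
#' frequency `eta`.  Coefficients are given in ascending order of degree.  The
#' default used throughout the package is the quartic monomial `eta^4`, which
#' aggressively upweights features observed in many samples.
#'
#' @param coefficients numeric vector `(a_0, ..., a_n)`; at least one must be
#'   non-zero.
#' @return An object of class `polynomial_spec` with elements `coefficients`
#'   and `degree`.
#' @examples
#' polynomial_spec()              # eta^4
#' polynomial_spec(c(1, 1))       # 1 + eta
#' @export
polynomial_spec <- function(coefficients = c(0, 0, 0, 0, 1)) {
  coefficients <- as.numeric(coefficients)
  if (!length(coefficients) || anyNA(coefficients))
    stop("coefficients must be a non-empty numeric vector", call. = FALSE)
  if (all(coefficients == 0))
    stop("at least one polynomial coefficient must be non-zero", call. = FALSE)
  structure(list(coefficients = coefficients,
                 degree = length(coefficients) - 1L),
            class = "polynomial_spec")
}

#' @export
print.polynomial_spec <- function(x, ...) {
  terms <- character(0)
  for (d in rev(seq_along(x$coefficients)) - 1L) {
    a <- x$coefficients[d + 1L]
    if (a == 0) next
    terms <- c(terms, if (d == 0L) format(a)
               else if (d == 1L) paste0(format(a), "*eta")
               else paste0(format(a), "*eta^", d))
  }
  cat("weighting polynomial: P(eta) =", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

#' Per-feature observation frequencies
#'
#' Counts how often each feature is observed across samples: either the
#' number of samples with a non-zero entry (`nonzero_count`, the natural
#' choice for 0/1 mutation matrices and the package default) or the row sum
#' (`row_sum`, for continuous abundances).  Frequencies are kept as raw
#' counts/sums; the subsequent weight normalization makes any fixed rescaling
#' immaterial for monomial polynomials.
#'
#' @param matrix a [sparse_data_matrix()] (any numeric matrix is accepted).
#' @param mode `"nonzero_count"` or `"row_sum"`.
#' @return Numeric vector of length `m`, named by feature.
#' @export
compute_frequencies <- function(matrix, mode = c("nonzero_count", "row_sum")) {
  mode <- match.arg(mode)
  if (mode == "nonzero_count") rowSums(matrix > 0) else rowSums(matrix)
}

#' Evaluate the weighting polynomial at each frequency
#'
#' Horner evaluation of `P(eta)` per feature.  A negative value at any
#' observed frequency is a configuration error (weights must be
#' non-negative), reported with the offending feature named.
#'
#' @param poly a [polynomial_spec()].
#' @param frequencies non-negative numeric vector (named by feature).
#' @return Numeric vector `P(eta_i)` of the same length and names.
#' @export
evaluate_polynomial <- function(poly, frequencies) {
  stopifnot(inherits(poly, "polynomial_spec"))
  if (any(frequencies < 0))
    stop("frequencies must be non-negative", call. = FALSE)
  a <- poly$coefficients
  vals <- rep(a[length(a)], length(frequencies))
  for (d in rev(seq_len(length(a) - 1L)))
    vals <- vals * frequencies + a[d]
  names(vals) <- names(frequencies)
  if (any(vals < 0)) {
    i <- which(vals < 0)[1L]
    who <- if (!is.null(names(vals))) names(vals)[i] else paste("index", i)
    stop("polynomial evaluates to a negative value (", format(vals[i]),
         ") at feature ", who, " (eta = ", format(frequencies[i]),
         "); choose coefficients that are non-negative over the observed ",
         "frequency range", call. = FALSE)
  }
  vals
}

#' Normalize polynomial values into feature weights
#'
#' Weights are the polynomial values divided by their sum, so they are
#' non-negative and sum to one.  An all-zero input means no feature carries
#' weight and is rejected.
#'
#' @param polynomial_values non-negative numeric vector.
#' @return Numeric weights summing to 1.
#' @export
normalize_weights <- function(polynomial_values) {
  if (!length(polynomial_values) || any(polynomial_values < 0))
    stop("polynomial values must be non-negative", call. = FALSE)
  total <- sum(polynomial_values)
  if (total == 0)
    stop("degenerate input: all polynomial values are zero, ",
         "no informative features", call. = FALSE)
  polynomial_values / total
}

#' Full weighting scheme for a matrix
#'
#' Convenience wrapper chaining [compute_frequencies()],
#' [evaluate_polynomial()] and [normalize_weights()].  Features with zero
#' frequency (for a monomial) end up with weight zero; they are retained as
#' inert all-zero rows, with a warning, so matrix shape and identifiers are
#' preserved.
#'
#' @inheritParams compute_frequencies
#' @param poly a [polynomial_spec()].
#' @param warn_zero warn when features receive weight zero (default TRUE;
#'   internal resampling loops silence it).
#' @return A list of class `weight_scheme`: `frequencies`,
#'   `polynomial_values`, `weights`, `frequency_mode`, `poly`.
#' @export
weight_scheme <- function(matrix, poly = polynomial_spec(),
                          mode = c("nonzero_count", "row_sum"),
                          warn_zero = TRUE) {
  mode <- match.arg(mode)
  freq <- compute_frequencies(matrix, mode)
  vals <- evaluate_polynomial(poly, freq)
  w <- normalize_weights(vals)
  if (warn_zero && any(w == 0))
    warning(sum(w == 0), " feature(s) received zero weight and become ",
            "inert all-zero rows", call. = FALSE)
  structure(list(frequencies = freq, polynomial_values = vals, weights = w,
                 frequency_mode = mode, poly = poly),
            class = "weight_scheme")
}

#' Apply feature weights to build the correction matrix
#'
#' Each feature row of the input is scaled by its normalized weight:
#' `Dbar[i, ] = D[i, ] * w[i]`.  The correction matrix is the space in which
#' samples are actually clustered; dividing each row by its (non-zero) weight
#' recovers the input exactly.
#'
#' @param matrix a [sparse_data_matrix()].
#' @param weights numeric vector of length `nrow(matrix)` (a bare weight
#'   vector or a `weight_scheme`).
#' @return A numeric matrix of the same shape and dimnames, with attribute
#'   `"weights"`, of class `correction_matrix`.
#' @export
apply_weights <- function(matrix, weights) {
  if (inherits(weights, "weight_scheme")) weights <- weights$weights
  if (length(weights) != nrow(matrix))
    stop("length of weights (", length(weights),
         ") must equal number of features (", nrow(matrix), ")",
         call. = FALSE)
  out <- unclass_matrix(matrix) * as.numeric(weights)
  structure(out, weights = as.numeric(weights),
            class = c("correction_matrix", "matrix", "array"))
}
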
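#' Sparse feature-by-sample data matrix
#'
#' The central input container: an `m x n` non-negative real matrix whose rows
#' are features (genes, microbial taxa, ...) and whose columns are samples
#' (patients).  Entries are either 0/1 presence indicators (e.g. somatic
#' mutation calls) or non-negative abundances.  All downstream operations
#' assume this orientation; loaders normalize to it.
#'
#' @param values numeric matrix, features as rows, samples as columns.
#' @param feature_ids character vector of unique row identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique column identifiers; defaults
#'   to `colnames(values)`.
#' @return An object of class `sparse_data_matrix`: the validated numeric
#'   matrix with feature and sample identifiers as dimnames.
#' @examples
#' m <- sparse_data_matrix(matrix(c(1, 0, 0, 1, 1, 1), nrow = 3, byrow = TRUE,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' matrix_density(m)  # 4/6
#' @export
sparse_data_matrix <- function(values, feature_ids = rownames(values),
                               sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  m <- nrow(values); n <- ncol(values)
  if (m < 1L) stop("matrix must have at least one feature row", call. = FALSE)
  if (n < 2L) stop("matrix must have at least two sample columns", call. = FALSE)
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(m))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != m)
    stop("feature_ids length (", length(feature_ids), ") != number of rows (",
         m, ")", call. = FALSE)
  if (length(sample_ids) != n)
    stop("sample_ids length (", length(sample_ids), ") != number of columns (",
         n, ")", call. = FALSE)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicated feature ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicated sample ID(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite entry at feature '", feature_ids[bad[1L, 1L]],
         "', sample '", sample_ids[bad[1L, 2L]], "'", call. = FALSE)
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative entry at feature '", feature_ids[bad[1L, 1L]],
         "', sample '", sample_ids[bad[1L, 2L]], "'", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, class = c("sparse_data_matrix", "matrix", "array"))
}

#' @export
print.sparse_data_matrix <- function(x, ...) {
  cat(sprintf("sparse_data_matrix: %d features x %d samples, density %.4f\n",
              nrow(x), ncol(x), matrix_density(x)))
  invisible(x)
}

#' Feature and sample identifiers
#' @param x a `sparse_data_matrix`.
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x)

#' Fraction of non-zero entries
#' @param x a `sparse_data_matrix` (or any numeric matrix).
#' @return Scalar in \[0, 1\]: `#nonzero / (m * n)`.
#' @export
matrix_density <- function(x) sum(x != 0) / length(x)

unclass_matrix <- function(x) {
  class(x) <- c("matrix", "array")
  x
}

#' Read a sparse feature-by-sample matrix
#'
#' Reads a delimited text file (TSV/CSV; first column feature IDs, header row
#' sample IDs) or a MatrixMarket coordinate file with two sidecar name files
#' (`<path>.rownames`, `<path>.colnames`, one ID per line).  Whatever the
#' on-disk orientation, the returned object always has features as rows:
#' `orientation = "samples_by_features"` transposes on load.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @param orientation `"features_by_samples"` (default) or
#'   `"samples_by_features"`.
#' @return A validated [sparse_data_matrix()].
#' @export
read_matrix <- function(path,
                        format = c("auto", "tsv", "csv", "mtx"),
                        orientation = c("features_by_samples",
                                        "samples_by_features")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    vals <- as.matrix(Matrix::readMM(path))
    storage.mode(vals) <- "double"  # pattern-format files read back logical
    rn_path <- paste0(path, ".rownames")
    cn_path <- paste0(path, ".colnames")
    for (p in c(rn_path, cn_path))
      if (!file.exists(p)) stop("missing name sidecar file: ", p, call. = FALSE)
    rownames(vals) <- readLines(rn_path)
    colnames(vals) <- readLines(cn_path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
      stop("file has no data rows: ", path, call. = FALSE)
    fields <- strsplit(lines, sep, fixed = TRUE)
    header <- fields[[1L]]
    ncols <- length(header) - 1L
    if (ncols < 1L) stop("header has no sample columns: ", path, call. = FALSE)
    body <- fields[-1L]
    widths <- lengths(body)
    if (any(widths != ncols + 1L)) {
      i <- which(widths != ncols + 1L)[1L]
      stop("ragged row ", i, " (ID '", body[[i]][1L], "'): expected ",
           ncols + 1L, " fields, found ", widths[i], call. = FALSE)
    }
    ids <- vapply(body, `[[`, "", 1L)
    vals <- matrix(NA_real_, nrow = length(body), ncol = ncols)
    for (i in seq_along(body)) {
      v <- suppressWarnings(as.numeric(body[[i]][-1L]))
      if (anyNA(v))
        stop("non-numeric or missing entry in row '", ids[i], "', column '",
             header[-1L][which(is.na(v))[1L]], "'", call. = FALSE)
      vals[i, ] <- v
    }
    rownames(vals) <- ids
    colnames(vals) <- header[-1L]
  }
  if (orientation == "samples_by_features") vals <- t(vals)
  sparse_data_matrix(vals)
}

#' Write a sparse matrix to delimited text or MatrixMarket
#'
#' `format = "mtx"` writes MatrixMarket coordinate format plus the
#' `.rownames`/`.colnames` sidecar files that [read_matrix()] expects.
#'
#' @param x a `sparse_data_matrix`.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass_matrix(x), sparse = TRUE), path)
    writeLines(feature_ids(x), paste0(path, ".rownames"))
    writeLines(sample_ids(x), paste0(path, ".colnames"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(feature_id = feature_ids(x), unclass_matrix(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write flat cluster assignments
#'
#' Assignments are stored as a two-column TSV (`sample_id`, `cluster`);
#' a write/read round trip reproduces the labels exactly.
#'
#' @param assignment a [cluster_assignment()].
#' @param path file path.
#' @return `write_assignment()` returns `path` invisibly; `read_assignment()`
#'   returns a `cluster_assignment`.
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- data.frame(sample_id = assignment$sample_ids,
                   cluster = assignment$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment
#' @export
read_assignment <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  cluster_assignment(df$cluster, df$sample_id, canonicalize = FALSE)
}

#' Write a consensus matrix as CSV
#'
#' Square numeric grid with sample IDs as both header and first column.
#'
#' @param consensus an N x N consensus matrix (or a `consensus_result`, whose
#'   `$consensus` element is taken).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  if (inherits(consensus, "consensus_result")) consensus <- consensus$consensus
  df <- data.frame(sample_id = rownames(consensus), consensus,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write a metrics table or a biomarker report
#'
#' Plain delimited text: metrics as CSV, biomarker reports as TSV.  Both can
#' be read back with `utils::read.table`/`read.csv`.
#'
#' @param x a metrics table (data frame from [metrics_sweep()]) or a
#'   `biomarker_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics
#' @export
write_biomarkers <- function(x, path) {
  if (inherits(x, "biomarker_report")) x <- x$table
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
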
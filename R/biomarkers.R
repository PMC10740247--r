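#' Per-cluster feature occurrence counts
#'
#' For each cluster, counts the samples in which each feature is present
#' (non-zero entry), giving the raw material for subtype interpretation:
#' a feature observed in most members of one cluster and few others is a
#' candidate defining biomarker for that subtype.
#'
#' @param matrix a [sparse_data_matrix()].
#' @param assignment a [cluster_assignment()] over the same samples, in the
#'   same order.
#' @return An object of class `biomarker_report`: list with `table` (data
#'   frame: `cluster`, `cluster_size`, `feature_id`, `count`, `prevalence`,
#'   `flagged`) and `rule` (filled in by [most_valuable()]).  Counts summed
#'   over clusters equal each feature's total non-zero count.
#' @export
occurrence_counts <- function(matrix, assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (length(assignment$labels) != ncol(matrix))
    stop("assignment covers ", length(assignment$labels),
         " samples but matrix has ", ncol(matrix), call. = FALSE)
  if (!identical(assignment$sample_ids, sample_ids(matrix)))
    stop("assignment sample IDs do not match matrix sample IDs",
         call. = FALSE)
  present <- unclass_matrix(matrix) > 0
  rows <- lapply(seq_len(assignment$k), function(q) {
    members <- assignment$labels == q
    counts <- rowSums(present[, members, drop = FALSE])
    data.frame(cluster = q, cluster_size = sum(members),
               feature_id = feature_ids(matrix),
               count = as.integer(counts),
               prevalence = counts / sum(members),
               flagged = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, rule = NULL), class = "biomarker_report")
}

#' Flag the most valuable biomarkers per cluster
#'
#' Applies a transparent flagging rule to an occurrence report:
#' `rule = "prevalence"` flags features present in at least a fraction `tau`
#' of the cluster's samples; `rule = "top_n"` flags the `n` highest-count
#' features in each cluster.  Within a cluster, features are ranked by
#' prevalence, then count, then feature ID (so ties are broken
#' alphabetically and deterministically).
#'
#' @param report an [occurrence_counts()] result.
#' @param rule `"prevalence"` (default) or `"top_n"`.
#' @param tau prevalence threshold in (0, 1], default 0.5.
#' @param n number of features to flag per cluster for `"top_n"`, default 5.
#' @return The report with `flagged` set, rows ordered by cluster then rank,
#'   and `rule` recording the parameters used.
#' @export
most_valuable <- function(report, rule = c("prevalence", "top_n"),
                          tau = 0.5, n = 5L) {
  stopifnot(inherits(report, "biomarker_report"))
  rule <- match.arg(rule)
  if (rule == "prevalence" && (tau <= 0 || tau > 1))
    stop("tau must lie in (0, 1]", call. = FALSE)
  tab <- report$table
  ord <- order(tab$cluster, -tab$prevalence, -tab$count, tab$feature_id)
  tab <- tab[ord, , drop = FALSE]
  if (rule == "prevalence") {
    tab$flagged <- tab$prevalence >= tau
  } else {
    tab$flagged <- stats::ave(seq_len(nrow(tab)), tab$cluster,
                              FUN = seq_along) <= n
  }
  rownames(tab) <- NULL
  structure(list(table = tab,
                 rule = if (rule == "prevalence")
                   list(rule = rule, tau = tau) else list(rule = rule, n = n)),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  cat(sprintf("biomarker report: %d clusters, %d features\n",
              length(unique(x$table$cluster)),
              length(unique(x$table$feature_id))))
  if (!is.null(x$rule)) {
    cat("rule:", x$rule$rule,
        if (x$rule$rule == "prevalence") paste0("(tau = ", x$rule$tau, ")")
        else paste0("(n = ", x$rule$n, ")"), "\n")
    flagged <- x$table[x$table$flagged, , drop = FALSE]
    for (q in unique(flagged$cluster))
      cat(sprintf("  cluster %d: %s\n", q,
                  paste(flagged$feature_id[flagged$cluster == q],
                        collapse = ", ")))
  }
  invisible(x)
}
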
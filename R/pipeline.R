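#' Configuration for a full pipeline run
#'
#' Bundles every knob of the weights -> cluster -> consensus -> metrics ->
#' biomarkers workflow into one serializable object.  The effective
#' configuration is always written next to a run's outputs
#' (`run_config.txt`), so any output directory can be regenerated from that
#' file alone.
#'
#' @param input path to the input matrix, or a [sparse_data_matrix()].
#' @param out_dir output directory (created if needed).
#' @param format,orientation input format options, see [read_matrix()].
#' @param coefficients weighting polynomial coefficients `(a_0, ..., a_n)`.
#' @param mode frequency mode, see [compute_frequencies()].
#' @param k_min,k_max range of cluster numbers to scan.
#' @param n_iterations,sample_fraction,reweight_per_subsample consensus
#'   resampling controls, see [resampling_plan()].
#' @param u1,u2 PAC thresholds, see [consensus_cdf()].
#' @param criterion k-selection criterion, see [select_optimal_k()].
#' @param biomarker_rule,tau,top_n flagging rule, see [most_valuable()].
#' @param seed integer seed for all resampling randomness.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(input, out_dir,
                       format = "auto", orientation = "features_by_samples",
                       coefficients = c(0, 0, 0, 0, 1),
                       mode = "nonzero_count",
                       k_min = 2L, k_max = 15L,
                       n_iterations = 1000L, sample_fraction = 0.8,
                       reweight_per_subsample = TRUE,
                       u1 = 0.1, u2 = 0.9, criterion = "pac_min",
                       biomarker_rule = "prevalence", tau = 0.5, top_n = 5L,
                       seed = 1L) {
  structure(list(input = input, out_dir = out_dir, format = format,
                 orientation = orientation,
                 coefficients = as.numeric(coefficients), mode = mode,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_iterations = as.integer(n_iterations),
                 sample_fraction = sample_fraction,
                 reweight_per_subsample = isTRUE(reweight_per_subsample),
                 u1 = u1, u2 = u2, criterion = criterion,
                 biomarker_rule = biomarker_rule, tau = tau,
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "run_config")
}

#' Read and write run configurations
#'
#' Plain `key = value` text, one setting per line; lists (polynomial
#' coefficients) are comma separated.  Unknown keys are rejected.
#'
#' @param path file path.
#' @param config a [run_config()].
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([a-z_0-9]+)\\s*=\\s*(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad))
    stop("unparseable config line: ", lines[bad][1L], call. = FALSE)
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  defaults <- formals(run_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (i in seq_along(keys)) {
    key <- keys[i]; v <- vals[i]
    args[[key]] <- switch(key,
      input = , out_dir = , format = , orientation = , mode = ,
      criterion = , biomarker_rule = v,
      coefficients = as.numeric(strsplit(v, ",")[[1L]]),
      reweight_per_subsample = as.logical(v),
      k_min = , k_max = , n_iterations = , top_n = , seed = as.integer(v),
      as.numeric(v))
  }
  if (!all(c("input", "out_dir") %in% names(args)))
    stop("config must set at least `input` and `out_dir`", call. = FALSE)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cfg <- unclass(config)
  if (!is.character(cfg$input))
    cfg$input <- "<in-memory matrix>"
  lines <- vapply(names(cfg), function(key) {
    v <- cfg[[key]]
    paste0(key, " = ", paste(v, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Run the full weighted sparse clustering workflow
#'
#' Executes the whole pipeline on one input matrix: feature weighting, Ward
#' clustering at every k in the configured range, Monti consensus resampling
#' with PAC/delta-area selection of the cluster number, the entropy /
#' Calinski-Harabasz comparison against the unweighted Euclidean baseline,
#' and the biomarker occurrence report at the selected k.  All artifacts are
#' written to `config$out_dir` as delimited text, together with the
#' effective configuration and a run log.  Any stage failure aborts with a
#' stage-named error; artifacts already written are retained.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the selected `k`, the selection `table`,
#'   the `metrics` data frame, the `biomarkers` report and `out_dir`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = log_path,
                                append = TRUE)
  stage <- function(name, expr) {
    log_line("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      log_line("stage ", name, " FAILED: ", conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cat(sprintf("pwsc %s, R %s, seed %d\n",
              as.character(utils::packageVersion("pwsc")),
              getRversion(), config$seed),
      file = log_path)
  write_run_config(config, file.path(config$out_dir, "run_config.txt"))

  mat <- stage("input", {
    if (inherits(config$input, "sparse_data_matrix")) config$input
    else read_matrix(config$input, config$format, config$orientation)
  })
  poly <- polynomial_spec(config$coefficients)
  k_range <- seq.int(config$k_min, config$k_max)

  scheme <- stage("weighting", weight_scheme(mat, poly, config$mode))
  utils::write.table(
    data.frame(feature_id = feature_ids(mat),
               frequency = scheme$frequencies,
               polynomial_value = scheme$polynomial_values,
               weight = scheme$weights),
    file.path(config$out_dir, "weights.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  dend <- stage("clustering", ward_linkage(apply_weights(mat, scheme)))
  assignments <- lapply(k_range, function(k) cut_tree(dend, k))
  names(assignments) <- as.character(k_range)
  for (k in k_range)
    write_assignment(assignments[[as.character(k)]],
                     file.path(config$out_dir, sprintf("labels_k%d.tsv", k)))

  plan <- resampling_plan(config$n_iterations, config$sample_fraction,
                          config$seed, config$reweight_per_subsample)
  consensus <- stage("consensus",
                     run_consensus(mat, k_range, plan, poly, config$mode))
  for (res in consensus)
    write_consensus(res, file.path(config$out_dir,
                                   sprintf("consensus_k%d.csv", res$k)))
  summaries <- lapply(consensus, consensus_cdf, u1 = config$u1,
                      u2 = config$u2)
  selection <- select_optimal_k(summaries, config$criterion)
  utils::write.table(selection$table,
                     file.path(config$out_dir, "cdf_pac.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  log_line("selected k = ", selection$k, " by ", config$criterion)

  metrics <- stage("metrics",
                   metrics_sweep(mat, k_range, poly, config$mode,
                                 baseline = TRUE))
  write_metrics(metrics, file.path(config$out_dir, "metrics.csv"))

  biomarkers <- stage("biomarkers", {
    rep0 <- occurrence_counts(mat, assignments[[as.character(selection$k)]])
    if (config$biomarker_rule == "prevalence")
      most_valuable(rep0, "prevalence", tau = config$tau)
    else most_valuable(rep0, "top_n", n = config$top_n)
  })
  write_biomarkers(biomarkers, file.path(config$out_dir, "biomarkers.tsv"))
  log_line("run complete")

  invisible(list(k = selection$k, table = selection$table, metrics = metrics,
                 biomarkers = biomarkers, out_dir = config$out_dir))
}
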
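#' Assemble a full experiment configuration
#'
#' Defaults reproduce the headline experimental setup: ten context window
#' sizes 2..20 in steps of 2, 200-dimensional vectors, forests of 500 trees,
#' 10-fold cross-validation, all three utilization strategies plus the
#' count-based baseline. Any field can be overridden (tests and desk-scale
#' runs shrink `dim`, `windows`, `n_trees` and the synthetic corpus).
#'
#' @param windows context window sizes for the space grid
#' @param dim embedding dimensionality
#' @param strategies strategies to evaluate (`"COUNT"` = baseline)
#' @param n_trees trees per forest
#' @param folds cross-validation folds
#' @param n_datasets synthetic datasets in the benchmark
#' @param pool_sizes pool sizes for the sweep, `NULL` to skip it
#' @param seed master seed
#' @param synth a [synth_config()] for the corpus generator
#' @param embedding extra [skipgram_config()] fields (epochs, negatives, ...)
#' @return a list of class `experiment_config`
#' @export
experiment_config <- function(windows = seq(2, 20, by = 2), dim = 200,
                              strategies = c(STRATEGIES, "COUNT"),
                              n_trees = 500, folds = 10, n_datasets = 5,
                              pool_sizes = NULL, seed = 1,
                              synth = synth_config(seed = seed),
                              embedding = list()) {
  for (st in setdiff(strategies, "COUNT")) match_strategy(st)
  stopifnot(length(windows) >= 1, !anyDuplicated(windows))
  structure(
    list(windows = as.integer(windows), dim = as.integer(dim),
         strategies = strategies, n_trees = as.integer(n_trees),
         folds = as.integer(folds), n_datasets = as.integer(n_datasets),
         pool_sizes = pool_sizes, seed = as.integer(seed), synth = synth,
         embedding = embedding),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a JSON file
#'
#' Top-level keys mirror the [experiment_config()] arguments; `synth` and
#' `embedding` are nested sections. Omitted keys keep their defaults.
#'
#' @param path JSON file path
#' @return an `experiment_config`
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- raw[setdiff(names(raw), c("synth", "embedding"))]
  if (!is.null(raw$synth)) {
    args$synth <- do.call(synth_config, as.list(raw$synth))
  } else if (!is.null(args$seed)) {
    args$synth <- synth_config(seed = args$seed)
  }
  if (!is.null(raw$embedding)) args$embedding <- as.list(raw$embedding)
  do.call(experiment_config, args)
}

config_hash <- function(config) rlang::hash(unclass(config))

experiment_skipgram <- function(config) {
  args <- c(list(dim = config$dim, seed = config$seed), config$embedding)
  do.call(skipgram_config, args)
}

#' Run the full experiment pipeline
#'
#' Generates the synthetic corpus and benchmark datasets, pretrains the
#' semantic-space grid, cross-validates every strategy on every dataset,
#' compares strategies with a Friedman test and Bergmann-Hommel post-hoc
#' analysis, optionally sweeps the semantic-space pool size, and writes CSV
#' report tables plus a JSON summary stamped with the configuration hash and
#' master seed. Reruns with the same configuration reproduce every number.
#'
#' @param config an [experiment_config()]
#' @param out_dir output directory (created if needed)
#' @param dry_run if `TRUE`, print the stage plan and exit without computing
#' @return invisibly, the summary list
#' @export
run_experiment <- function(config, out_dir = "results", dry_run = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  stages <- c("generate", "train-spaces", "evaluate", "compare",
              if (!is.null(config$pool_sizes)) "pool-sweep")
  if (dry_run) {
    message("plan: ", paste(stages, collapse = " -> "),
            " (seed ", config$seed, ", hash ", config_hash(config), ")")
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  msg <- function(...) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0, units = "secs")), ...)

  msg("generate: synthetic corpus + ", config$n_datasets, " datasets")
  bench <- make_benchmark(config$synth, n_datasets = config$n_datasets,
                          seed = config$seed)
  write_corpus(bench$corpus, file.path(out_dir, "corpus.jsonl"))

  msg("train-spaces: ", length(DATA_TYPES), " x ", length(config$windows),
      " grid, dim ", config$dim)
  sg <- experiment_skipgram(config)
  base_grid <- build_space_grid(bench$corpus, config$windows, sg)

  msg("evaluate: ", length(config$strategies), " methods x ",
      config$n_datasets, " datasets, ", config$folds, "-fold CV")
  eval_seeds <- derive_seeds(config$seed,
                             length(bench$datasets) * length(config$strategies))
  k <- 0L
  results <- purrr::map_dfr(bench$datasets, function(ds) {
    ens <- exclude_target_spaces(base_grid, bench$corpus, ds$target_code, sg)
    purrr::map_dfr(config$strategies, function(st) {
      k <<- k + 1L
      glance(cross_validate(ds, ens, strategy = st, n_trees = config$n_trees,
                            folds = config$folds, seed = eval_seeds[k]))
    })
  })
  utils::write.csv(results, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  perf <- score_matrix(results, "accuracy")
  ranks <- t(apply(perf, 1, function(r) rank(-r, ties.method = "average")))
  table3 <- cbind(as.data.frame(perf),
                  stats::setNames(as.data.frame(ranks),
                                  paste0(colnames(ranks), "_rank")))
  utils::write.csv(cbind(dataset = rownames(perf), table3),
                   file.path(out_dir, "table_accuracy_ranks.csv"),
                   row.names = FALSE)
  inspect <- results |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(avg_tree_accuracy = mean(.data$avg_tree_accuracy),
                     diversity = mean(.data$diversity), .groups = "drop")
  utils::write.csv(inspect, file.path(out_dir, "table_tree_diversity.csv"),
                   row.names = FALSE)

  msg("compare: Friedman + Bergmann-Hommel")
  embed_cols <- intersect(colnames(perf), STRATEGIES)
  fr <- friedman_test(perf[, embed_cols, drop = FALSE])
  ph <- posthoc_pairwise(perf[, embed_cols, drop = FALSE],
                         method = if (length(embed_cols) <= 4) "bergmann_hommel" else "holm")
  utils::write.csv(ph, file.path(out_dir, "posthoc.csv"), row.names = FALSE)

  pool <- NULL
  if (!is.null(config$pool_sizes)) {
    msg("pool-sweep: sizes ", paste(config$pool_sizes, collapse = ","))
    ds1 <- bench$datasets[[1]]
    ens1 <- exclude_target_spaces(base_grid, bench$corpus, ds1$target_code, sg)
    pool <- pool_size_experiment(ds1, ens1, sizes = config$pool_sizes,
                                 n_trees = config$n_trees,
                                 seed = config$seed)
    utils::write.csv(pool, file.path(out_dir, "table_pool_size.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    mean_scores = as.list(colMeans(perf)),
    friedman = list(chi2 = fr$chi2, p_value = fr$p_value),
    posthoc = ph,
    pool = pool
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg("done; reports in ", normalizePath(out_dir))
  invisible(summary)
}
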
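#' Retrain the diagnosis spaces of an ensemble with a target code excluded
#'
#' The target ADE code must never enter representation learning: its
#' occurrences are deleted from the diagnosis sequences before training (so
#' surrounding events become adjacent) and a fresh diagnosis space is trained
#' per window. Word, drug and measurement spaces are shared unchanged — the
#' exclusion only concerns the diagnosis vocabulary.
#'
#' @param ensemble a `space_ensemble` trained on `corpus`
#' @param corpus the background `ade_corpus`
#' @param exclude_code target diagnosis token
#' @param config the [skipgram_config()] used for the grid (its seed keys the
#'   retrained cells)
#' @return a `space_ensemble` whose diagnosis spaces exclude the code
#' @export
exclude_target_spaces <- function(ensemble, corpus, exclude_code, config) {
  seqs <- extract_sequences(corpus, "diagnosis", exclude_code = exclude_code)
  cell_seeds <- derive_seeds(config$seed + sum(utf8ToInt(exclude_code)),
                             length(ensemble$windows))
  spaces <- ensemble$spaces
  for (i in seq_along(ensemble$windows)) {
    w <- ensemble$windows[i]
    cfg <- config
    cfg$window <- w
    cfg$seed <- cell_seeds[i]
    spaces[[space_key("diagnosis", w)]] <- train_semantic_space(seqs, cfg)
  }
  new_space_ensemble(spaces, ensemble$data_types, ensemble$windows,
                     ensemble$dim)
}

#' Run the strategy-comparison benchmark on synthetic data
#'
#' For each replicate seed: generate a fresh background corpus and its
#' balanced ADE datasets, pretrain the semantic-space grid, and evaluate every
#' strategy (plus the count-based baseline) on each dataset with one
#' stratified 70/30 train-test split. Diagnosis spaces are retrained per
#' dataset with the dataset's target code excluded.
#'
#' @param config a [synth_config()]
#' @param n_datasets datasets per replicate
#' @param seeds integer vector of replicate seeds
#' @param strategies strategies to evaluate; `"COUNT"` adds the baseline
#' @param windows context window sizes of the space grid
#' @param dim embedding dimensionality
#' @param n_trees trees per forest
#' @param split training fraction
#' @return tibble with one row per (seed, dataset, strategy): accuracy, AUC,
#'   average tree accuracy, diversity
#' @export
run_benchmark <- function(config = synth_config(), n_datasets = 5,
                          seeds = 1:10,
                          strategies = c(STRATEGIES, "COUNT"),
                          windows = c(2, 5, 8), dim = 25, n_trees = 50,
                          split = 0.7) {
  purrr::map_dfr(seeds, function(seed) {
    bench <- make_benchmark(config, n_datasets = n_datasets, seed = seed)
    sg <- skipgram_config(dim = dim, seed = seed)
    base_grid <- build_space_grid(bench$corpus, windows, sg)
    run_seeds <- derive_seeds(seed, length(bench$datasets) * (length(strategies) + 1))
    k <- 0L
    purrr::map_dfr(bench$datasets, function(ds) {
      ens <- exclude_target_spaces(base_grid, bench$corpus, ds$target_code, sg)
      k <<- k + 1L
      idx_train <- stratified_split(ds$labels, split, run_seeds[k])
      train <- dataset_slice(ds, idx_train)
      test <- dataset_slice(ds, setdiff(seq_along(ds$labels), idx_train))
      purrr::map_dfr(strategies, function(st) {
        k <<- k + 1L
        model <- if (identical(st, "COUNT")) {
          fit_count_forest(train, n_trees = n_trees, seed = run_seeds[k])
        } else {
          fit_forest(train, ens, strategy = st, n_trees = n_trees,
                     seed = run_seeds[k])
        }
        dplyr::bind_cols(
          tibble::tibble(seed = seed, dataset = ds$name, strategy = st),
          inspect_ensemble(model, test, test$labels)
        )
      })
    })
  })
}

#' Reshape benchmark results into a dataset-by-method score matrix
#'
#' @param results tibble from [run_benchmark()] (or any tibble with `dataset`,
#'   `strategy` and a score column); replicate seeds are averaged first
#' @param metric name of the score column
#' @return numeric matrix, datasets x methods, ready for [friedman_test()]
#' @export
score_matrix <- function(results, metric = "ensemble_accuracy") {
  agg <- results |>
    dplyr::group_by(.data$dataset, .data$strategy) |>
    dplyr::summarise(score = mean(.data[[metric]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "strategy", values_from = "score")
  m <- as.matrix(agg[, -1])
  rownames(m) <- agg$dataset
  if (anyNA(m)) stop("score matrix has missing entries", call. = FALSE)
  m
}
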
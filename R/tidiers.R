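#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted forest: one row per tree
#'
#' @param x an `ade_forest`
#' @param ... unused
#' @return tibble with `tree`, `window_tag`, `n_features`, `bootstrap_seed`
#' @method tidy ade_forest
#' @export
tidy.ade_forest <- function(x, ...) {
  tibble::tibble(
    tree = seq_along(x$trees),
    window_tag = purrr::map_chr(x$trees, "window_tag"),
    n_features = purrr::map_int(x$trees, function(tr) {
      if (is.null(tr$feature_subset)) {
        length(x$ensemble$data_types) * x$ensemble$dim
      } else {
        length(tr$feature_subset)
      }
    }),
    bootstrap_seed = purrr::map_int(x$trees, "bootstrap_seed")
  )
}

#' One-row summary of a fitted forest
#'
#' @inheritParams tidy.ade_forest
#' @return tibble with strategy, counts and the per-tree feature budget
#' @method glance ade_forest
#' @export
glance.ade_forest <- function(x, ...) {
  budget <- feature_budget(x$strategy, x$ensemble$dim,
                           length(x$ensemble$data_types),
                           length(x$ensemble$windows))
  tibble::tibble(
    strategy = x$strategy, n_trees = x$n_trees, dim = x$ensemble$dim,
    n_windows = length(x$ensemble$windows),
    ensemble_features = budget$ensemble_features,
    tree_features = budget$tree_features,
    target_code = x$target_code, seed = x$seed
  )
}

#' Per-fold results of a cross-validated evaluation
#'
#' @param x an `ade_eval`
#' @param ... unused
#' @method tidy ade_eval
#' @export
tidy.ade_eval <- function(x, ...) x$folds

#' Aggregate row of a cross-validated evaluation
#'
#' @inheritParams tidy.ade_eval
#' @method glance ade_eval
#' @export
glance.ade_eval <- function(x, ...) x$summary

#' Per-fold accuracy and AUC of a cross-validated evaluation
#'
#' @param object an `ade_eval`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot ade_eval
#' @export
autoplot.ade_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$folds[, c("fold", "ensemble_accuracy", "avg_tree_accuracy")],
    -"fold", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = paste(object$summary$strategy, "on",
                                object$summary$dataset)) +
    ggplot2::theme_minimal()
}

#' Strategy comparison plot for benchmark results
#'
#' @param results tibble from [run_benchmark()]
#' @param metric column to plot
#' @return a ggplot object
#' @export
plot_strategy_comparison <- function(results, metric = "ensemble_accuracy") {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$strategy,
                                        y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Pool-size sweep plot
#'
#' @param pool tibble from [pool_size_experiment()]
#' @return a ggplot object
#' @export
plot_pool_size <- function(pool) {
  df <- tidyr::pivot_longer(pool, c("accuracy", "auc"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pool_size, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "semantic-space pool size", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
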
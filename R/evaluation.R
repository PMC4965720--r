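#' Classification accuracy in percent
#'
#' @param y_true,y_pred equal-length binary vectors
#' @return percentage of correctly classified instances
#' @export
accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  100 * mean(y_true == y_pred)
}

#' Area under the ROC curve (pairwise ranking probability)
#'
#' The probability that a randomly chosen positive instance is scored ahead of
#' a randomly chosen negative one, ties counting one half. Computed through
#' the midrank (Mann-Whitney) identity, which equals the mean over all
#' positive-negative pairs of 1 / 0.5 / 0 for higher / tied / lower scores.
#'
#' @param y_true binary labels containing both classes
#' @param scores numeric scores, higher = more positive
#' @return AUC in \[0, 1\]
#' @export
auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Ambiguity decomposition of an averaging ensemble
#'
#' For base predictions averaged into an ensemble prediction, the squared
#' ensemble error E equals the average squared base error A minus the
#' diversity D (the average squared deviation of each base prediction from the
#' ensemble prediction): E = A - D. Diversity can only help, and the identity
#' is exact.
#'
#' @param base_predictions numeric vector of base-model predictions
#' @param target the true numeric target
#' @return tibble with columns `E`, `A`, `D`
#' @export
ambiguity_decomposition <- function(base_predictions, target) {
  stopifnot(length(base_predictions) >= 1, length(target) == 1)
  f_bar <- mean(base_predictions)
  E <- (f_bar - target)^2
  A <- mean((base_predictions - target)^2)
  D <- mean((base_predictions - f_bar)^2)
  tibble::tibble(E = E, A = A, D = D)
}

#' Inspect an ensemble: accuracy, average tree accuracy, diversity
#'
#' Average tree accuracy is the mean over trees of each tree's own accuracy on
#' the test episodes (each tree classifying through its own representation and
#' feature subset); diversity is crudely estimated as ensemble accuracy minus
#' average tree accuracy, reported on the fraction scale.
#'
#' @param model an `ade_forest` or `count_forest`
#' @param newdata test episodes (`ade_corpus` or `ade_dataset`)
#' @param y_true true binary labels for `newdata`
#' @return tibble with `ensemble_accuracy` (%), `avg_tree_accuracy` (%),
#'   `diversity` (fraction), `auc`
#' @export
inspect_ensemble <- function(model, newdata, y_true) {
  dataset <- as_prediction_dataset(model, newdata)
  if (inherits(model, "count_forest")) {
    scores <- predict_scores(model, dataset)
    counts <- bag_of_events(dataset)
    X <- matrix(0, nrow = nrow(counts$matrix), ncol = length(model$vocab))
    shared <- intersect(model$vocab, counts$vocab)
    X[, match(shared, model$vocab)] <-
      as.matrix(counts$matrix[, shared, drop = FALSE])
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    reps <- list(COUNT = X)
  } else {
    reps <- forest_test_reps(model, dataset)
    scores <- NULL
  }
  votes <- purrr::map(model$trees, function(tr) {
    tree_votes(tr$tree, reps[[tr$window_tag]], tr$feature_subset)
  })
  if (is.null(scores)) scores <- Reduce(`+`, votes) / length(votes)
  ens_acc <- accuracy(y_true, as.integer(scores > 0.5))
  tree_accs <- purrr::map_dbl(votes, function(v) accuracy(y_true, v))
  avg_tree <- mean(tree_accs)
  tibble::tibble(
    ensemble_accuracy = ens_acc,
    avg_tree_accuracy = avg_tree,
    diversity = (ens_acc - avg_tree) / 100,
    auc = auc(y_true, scores)
  )
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so per-class fold sizes differ by at most one.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validated evaluation of one strategy on one dataset
#'
#' Stratified k-fold cross-validation. Semantic spaces are pretrained once on
#' the background corpus (an unsupervised step independent of the labels) and
#' shared across folds; only the forests are refit per fold.
#'
#' @param dataset an `ade_dataset`
#' @param ensemble a pretrained `space_ensemble`
#' @param strategy utilization strategy, or `"COUNT"` for the count baseline
#' @param n_trees trees per forest
#' @param folds number of folds (each class must have at least `folds`
#'   members)
#' @param seed master seed (fold shuffling and per-fold forests)
#' @return an object of class `ade_eval`: list with per-fold tibble `folds`
#'   and one-row `summary` tibble
#' @export
cross_validate <- function(dataset, ensemble, strategy = "RDR-ALL",
                           n_trees = 500, folds = 10, seed = 1) {
  counts <- table(dataset$labels)
  if (any(counts < folds)) {
    stop("smallest class has ", min(counts), " episodes; use at most ",
         min(counts), " folds", call. = FALSE)
  }
  fold_of <- stratified_folds(dataset$labels, folds, seed)
  fold_seeds <- derive_seeds(seed, folds)
  per_fold <- purrr::map_dfr(seq_len(folds), function(f) {
    train <- dataset_slice(dataset, which(fold_of != f))
    test <- dataset_slice(dataset, which(fold_of == f))
    model <- if (identical(strategy, "COUNT")) {
      fit_count_forest(train, n_trees = n_trees, seed = fold_seeds[f])
    } else {
      fit_forest(train, ensemble, strategy = strategy, n_trees = n_trees,
                 seed = fold_seeds[f])
    }
    dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = length(test$labels)),
      inspect_ensemble(model, test, test$labels)
    )
  })
  summary <- tibble::tibble(
    dataset = dataset$name,
    strategy = if (identical(strategy, "COUNT")) "COUNT" else match_strategy(strategy),
    folds = folds,
    accuracy = mean(per_fold$ensemble_accuracy),
    auc = mean(per_fold$auc),
    avg_tree_accuracy = mean(per_fold$avg_tree_accuracy),
    diversity = mean(per_fold$diversity),
    seed = as.integer(seed)
  )
  structure(list(folds = per_fold, summary = summary), class = "ade_eval")
}

#' @export
print.ade_eval <- function(x, ...) {
  cat("<ade_eval> ", x$summary$strategy, " on '", x$summary$dataset, "': ",
      sprintf("accuracy %.2f%%, AUC %.3f, avg tree %.2f%%, diversity %.3f",
              x$summary$accuracy, x$summary$auc, x$summary$avg_tree_accuracy,
              x$summary$diversity), "\n", sep = "")
  invisible(x)
}

#' Friedman rank test over a score matrix
#'
#' Rows are datasets, columns are methods. Scores are ranked within each
#' dataset (rank 1 = best, i.e. highest score; ties receive average ranks) and
#' the chi-squared Friedman statistic
#' `12n / (k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2` is referred to a chi-squared
#' law with k - 1 degrees of freedom.
#'
#' @param scores numeric matrix or data frame, n datasets x k methods
#' @return tibble with `chi2`, `df`, `p_value`, `mean_ranks` (list column)
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  stopifnot(n >= 2, k >= 2)
  ranks <- t(apply(scores, 1, function(row) rank(-row, ties.method = "average")))
  rbar <- colMeans(ranks)
  chi2 <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  tibble::tibble(
    chi2 = chi2, df = k - 1, p_value = p,
    mean_ranks = list(stats::setNames(rbar, colnames(scores)))
  )
}

# All exhaustive hypothesis sets over k methods: a hypothesis set is
# exhaustive iff it is exactly the set of within-block equalities of some
# partition of the methods. Enumerated from all set partitions (k <= 4).
exhaustive_sets <- function(k) {
  partitions <- list(list(1L))
  for (el in seq_len(k)[-1]) {
    nxt <- list()
    for (p in partitions) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], el)
        nxt[[length(nxt) + 1]] <- q
      }
      nxt[[length(nxt) + 1]] <- c(p, list(el))
    }
    partitions <- nxt
  }
  pair_id <- function(i, j) paste(min(i, j), max(i, j), sep = "-")
  sets <- purrr::map(partitions, function(p) {
    unlist(purrr::map(p, function(block) {
      if (length(block) < 2) return(character(0))
      combs <- utils::combn(sort(block), 2)
      apply(combs, 2, function(ij) pair_id(ij[1], ij[2]))
    }))
  })
  sets <- purrr::keep(sets, function(s) length(s) > 0)
  unique(purrr::map(sets, sort))
}

#' Pairwise post-hoc comparison after a Friedman test
#'
#' Pairwise statistics are `z = (Rbar_i - Rbar_j) / sqrt(k(k+1) / (6n))` with
#' two-sided normal p-values, adjusted either by the Bergmann-Hommel procedure
#' (exhaustive enumeration of simultaneously satisfiable hypothesis sets,
#' feasible for k <= 4) or by Holm's step-down. Adjusted p-values are capped
#' at 1.
#'
#' @inheritParams friedman_test
#' @param method `"bergmann_hommel"` or `"holm"`
#' @return tibble with one row per method pair: `method_a`, `method_b`, `z`,
#'   `p_raw`, `p_adjusted`
#' @export
posthoc_pairwise <- function(scores, method = c("bergmann_hommel", "holm")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  stopifnot(k >= 2)
  if (method == "bergmann_hommel" && k > 4) {
    stop("bergmann_hommel is implemented for k <= 4 methods; use holm",
         call. = FALSE)
  }
  nm <- colnames(scores)
  if (is.null(nm)) nm <- paste0("method", seq_len(k))
  ranks <- t(apply(scores, 1, function(row) rank(-row, ties.method = "average")))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  res <- tibble::tibble(
    method_a = nm[pairs[1, ]],
    method_b = nm[pairs[2, ]],
    z = unname(rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se,
    p_raw = 2 * stats::pnorm(-abs(unname(rbar[pairs[1, ]] - rbar[pairs[2, ]])) / se)
  )
  pair_key <- paste(pairs[1, ], pairs[2, ], sep = "-")
  if (method == "holm") {
    res$p_adjusted <- stats::p.adjust(res$p_raw, method = "holm")
  } else {
    sets <- exhaustive_sets(k)
    p_by_key <- stats::setNames(res$p_raw, pair_key)
    res$p_adjusted <- purrr::map_dbl(pair_key, function(key) {
      vals <- purrr::map_dbl(
        purrr::keep(sets, function(s) key %in% s),
        function(s) length(s) * min(p_by_key[s])
      )
      min(1, max(vals))
    })
  }
  res
}

#' Semantic-space pool-size experiment
#'
#' How does the number of window sizes available to the forest affect
#' performance? For each pool size s, every one of the choose(P, s) window
#' subsets is evaluated with a stratified 70/30 train-test split and the
#' scores are averaged per size.
#'
#' @param dataset an `ade_dataset`
#' @param ensemble the full `space_ensemble` (pool of P windows)
#' @param sizes pool sizes to evaluate, each in `1..P`
#' @param strategy utilization strategy (the best-performing RDR-ALL by
#'   default)
#' @param split training fraction
#' @param n_trees trees per forest
#' @param seed master seed
#' @return tibble with one row per pool size: `pool_size`, `n_combinations`,
#'   `accuracy`, `auc`
#' @export
pool_size_experiment <- function(dataset, ensemble, sizes = NULL,
                                 strategy = "RDR-ALL", split = 0.7,
                                 n_trees = 50, seed = 1) {
  P <- length(ensemble$windows)
  if (is.null(sizes)) sizes <- seq_len(P)
  stopifnot(all(sizes >= 1), all(sizes <= P))
  purrr::map_dfr(sizes, function(s) {
    combos <- purrr::map(utils::combn(seq_along(ensemble$windows), s,
                                      simplify = FALSE),
                         function(ix) ensemble$windows[ix])
    runs <- purrr::map_dfr(combos, function(ws) {
      sub_ens <- subset_windows(ensemble, ws)
      # seed keyed by the window subset itself, so a run on {w} reproduces the
      # corresponding single-window member of a larger sweep
      part_seed <- derive_seeds(seed + 7919 * sum(ws) + length(ws), 2)
      idx_train <- stratified_split(dataset$labels, split, part_seed[1])
      train <- dataset_slice(dataset, idx_train)
      test <- dataset_slice(dataset, setdiff(seq_along(dataset$labels), idx_train))
      model <- fit_forest(train, sub_ens, strategy = strategy,
                          n_trees = n_trees, seed = part_seed[2])
      scores <- predict_scores(model, test)
      tibble::tibble(accuracy = accuracy(test$labels, as.integer(scores > 0.5)),
                     auc = auc(test$labels, scores))
    })
    tibble::tibble(pool_size = s, n_combinations = length(combos),
                   accuracy = mean(runs$accuracy), auc = mean(runs$auc))
  })
}

# Stratified train indices for a split fraction.
stratified_split <- function(labels, split, seed) {
  withr::with_seed(seed, {
    unlist(purrr::map(unique(labels), function(cls) {
      idx <- sample(which(labels == cls))
      idx[seq_len(max(1, round(split * length(idx))))]
    }))
  })
}
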
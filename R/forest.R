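#' Bootstrap replicate indices
#'
#' Draws `n` indices uniformly with replacement from `1..n` (a bagging
#' replicate of a training set of `n` examples), reproducibly under `seed`.
#'
#' @param n training-set size
#' @param seed integer seed
#' @return integer vector of length `n`
#' @export
bootstrap_replicate <- function(n, seed) {
  if (n < 1) stop("cannot bootstrap an empty training set", call. = FALSE)
  withr::with_seed(seed, sample.int(n, n, replace = TRUE))
}

#' Random feature subset of size floor(sqrt(N))
#'
#' @param N number of available features
#' @param seed integer seed
#' @return sorted integer vector of `floor(sqrt(N))` distinct indices in `1..N`
#' @export
sample_feature_subset <- function(N, seed) {
  stopifnot(N >= 1)
  k <- floor(sqrt(N))
  withr::with_seed(seed, sort(sample.int(N, k)))
}

fit_one_tree <- function(X, y, rows, feature_subset = NULL) {
  cols <- if (is.null(feature_subset)) seq_len(ncol(X)) else feature_subset
  df <- as.data.frame(X[rows, cols, drop = FALSE])
  df$.y <- factor(y[rows], levels = c(0L, 1L))
  rpart::rpart(
    .y ~ ., data = df, method = "class",
    control = rpart::rpart.control(
      minsplit = 2, minbucket = 1, cp = 0, xval = 0,
      maxcompete = 0, maxsurrogate = 0, usesurrogate = 0, maxdepth = 30
    )
  )
}

tree_votes <- function(tree, X, feature_subset = NULL) {
  cols <- if (is.null(feature_subset)) seq_len(ncol(X)) else feature_subset
  df <- as.data.frame(X[, cols, drop = FALSE])
  as.integer(as.character(predict(tree, newdata = df, type = "class")))
}

#' Fit a forest of randomized trees under a utilization strategy
#'
#' Each of the three strategies gives every tree a bootstrap replicate of the
#' training episodes; they differ in which distributed representation the tree
#' sees and whether random subspacing is applied:
#' \describe{
#'   \item{FDR}{the per-window representations are concatenated (width
#'     V x T x P) and each tree inspects a random floor(sqrt(VTP))-feature
#'     subset.}
#'   \item{RDR-FS}{each tree draws one window size uniformly (with
#'     replacement across trees), is trained on that window's V x T
#'     representation, and inspects a random floor(sqrt(VT))-feature subset.}
#'   \item{RDR-ALL}{as RDR-FS but without subspacing: the tree uses all V x T
#'     features of its sampled representation.}
#' }
#' Trees are fully grown impurity-based (Gini) classification trees. Random
#' subspacing is applied once per tree, not per node: the method combines
#' bagging with the random subspace method rather than re-sampling features at
#' every split as the classical random forest does.
#'
#' @param dataset an `ade_dataset` with both classes present
#' @param ensemble a `space_ensemble`
#' @param strategy `"FDR"`, `"RDR-FS"` or `"RDR-ALL"`
#' @param n_trees number of trees
#' @param seed master seed; per-tree seeds are derived so any tree is
#'   reproducible in isolation
#' @return an object of class `ade_forest`
#' @export
fit_forest <- function(dataset, ensemble, strategy = "RDR-ALL",
                       n_trees = 500, seed = 1) {
  strategy <- match_strategy(strategy)
  n <- nrow(dataset$episodes)
  if (n == 0) stop("empty dataset", call. = FALSE)
  if (length(unique(dataset$labels)) < 2) {
    stop("both classes must be present to fit a forest", call. = FALSE)
  }
  windows <- ensemble$windows
  P <- length(windows)
  V <- ensemble$dim
  T_ <- length(ensemble$data_types)

  # cache representations: per window for RDR-*, fused for FDR
  if (strategy == "FDR") {
    fused <- concat_windows(dataset, ensemble, windows)
    reps <- list(ALL = fused$matrix)
  } else {
    reps <- purrr::map(windows, function(w)
      transform_dataset(dataset, ensemble, w)$matrix)
    names(reps) <- as.character(windows)
  }

  subset_size <- switch(strategy,
    "FDR" = floor(sqrt(V * T_ * P)),
    "RDR-FS" = floor(sqrt(V * T_)),
    "RDR-ALL" = NA_integer_
  )

  tree_seeds <- derive_seeds(seed, n_trees)
  trees <- purrr::map(tree_seeds, function(ts) {
    sub <- derive_seeds(ts, 3)
    if (strategy == "FDR") {
      tag <- "ALL"
    } else {
      tag <- as.character(windows[withr::with_seed(
        sub[1], sample.int(length(windows), 1))])
    }
    X <- reps[[tag]]
    rows <- bootstrap_replicate(n, sub[2])
    fs <- if (is.na(subset_size)) NULL else sample_feature_subset(ncol(X), sub[3])
    list(tree = fit_one_tree(X, dataset$labels, rows, fs),
         window_tag = tag, feature_subset = fs, bootstrap_seed = sub[2])
  })

  structure(
    list(strategy = strategy, trees = trees, ensemble = ensemble,
         target_code = dataset$target_code, n_trees = as.integer(n_trees),
         seed = as.integer(seed)),
    class = "ade_forest"
  )
}

#' @export
print.ade_forest <- function(x, ...) {
  cat("<ade_forest> ", x$strategy, ", ", x$n_trees, " trees, windows ",
      paste(x$ensemble$windows, collapse = ", "), ", dim ", x$ensemble$dim,
      "\n", sep = "")
  invisible(x)
}

# Representations of new episodes under every window tag the forest uses.
forest_test_reps <- function(model, dataset) {
  tags <- unique(purrr::map_chr(model$trees, "window_tag"))
  reps <- purrr::map(tags, function(tag) {
    if (tag == "ALL") {
      concat_windows(dataset, model$ensemble, model$ensemble$windows)$matrix
    } else {
      transform_dataset(dataset, model$ensemble, as.integer(tag))$matrix
    }
  })
  names(reps) <- tags
  reps
}

as_prediction_dataset <- function(model, newdata) {
  if (inherits(newdata, "ade_dataset")) return(newdata)
  labeled_dataset(newdata, rep(0L, nrow(newdata)), model$target_code)
}

#' Forest vote scores
#'
#' Fraction of trees voting positive per episode; each tree sees the episode
#' transformed under its own window tag and restricted to its feature subset.
#'
#' @param model an `ade_forest`
#' @param newdata an `ade_corpus` or `ade_dataset` of episodes to score
#' @return numeric vector of scores in \[0, 1\]
#' @export
predict_scores <- function(model, newdata) {
  UseMethod("predict_scores")
}

#' @export
predict_scores.ade_forest <- function(model, newdata) {
  dataset <- as_prediction_dataset(model, newdata)
  reps <- forest_test_reps(model, dataset)
  votes <- purrr::map(model$trees, function(tr) {
    tree_votes(tr$tree, reps[[tr$window_tag]], tr$feature_subset)
  })
  Reduce(`+`, votes) / length(votes)
}

#' Majority-vote labels
#'
#' Label 1 when the vote score strictly exceeds `threshold`; an exact tie
#' (score equal to the threshold) yields label 0.
#'
#' @inheritParams predict_scores
#' @param threshold vote-fraction cutoff
#' @return integer vector of 0/1 labels
#' @export
predict_labels <- function(model, newdata, threshold = 0.5) {
  as.integer(predict_scores(model, newdata) > threshold)
}

#' Fit the count-based baseline forest
#'
#' Bagging plus random subspacing (floor(sqrt(N)) token-count features per
#' tree) over the shallow bag-of-clinical-events representation — the
#' reference representation the distributed strategies are compared against.
#'
#' @param dataset an `ade_dataset`
#' @param n_trees number of trees
#' @param seed master seed
#' @return an object of class `count_forest`
#' @export
fit_count_forest <- function(dataset, n_trees = 500, seed = 1) {
  counts <- bag_of_events(dataset)
  X <- as.matrix(counts$matrix)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (length(unique(dataset$labels)) < 2) {
    stop("both classes must be present to fit a forest", call. = FALSE)
  }
  n <- nrow(X)
  tree_seeds <- derive_seeds(seed, n_trees)
  trees <- purrr::map(tree_seeds, function(ts) {
    sub <- derive_seeds(ts, 3)
    rows <- bootstrap_replicate(n, sub[2])
    fs <- sample_feature_subset(ncol(X), sub[3])
    list(tree = fit_one_tree(X, dataset$labels, rows, fs),
         window_tag = "COUNT", feature_subset = fs, bootstrap_seed = sub[2])
  })
  structure(
    list(trees = trees, vocab = counts$vocab,
         target_code = dataset$target_code, n_trees = as.integer(n_trees),
         seed = as.integer(seed)),
    class = "count_forest"
  )
}

#' @export
predict_scores.count_forest <- function(model, newdata) {
  dataset <- if (inherits(newdata, "ade_dataset")) newdata else
    labeled_dataset(newdata, rep(0L, nrow(newdata)), model$target_code)
  counts <- bag_of_events(dataset)
  X <- matrix(0, nrow = nrow(counts$matrix), ncol = length(model$vocab))
  shared <- intersect(model$vocab, counts$vocab)
  X[, match(shared, model$vocab)] <- as.matrix(counts$matrix[, shared, drop = FALSE])
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  votes <- purrr::map(model$trees, function(tr) {
    tree_votes(tr$tree, X, tr$feature_subset)
  })
  Reduce(`+`, votes) / length(votes)
}
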
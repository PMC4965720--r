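test_that("bootstrap replicates have the right size, range and expectation", {
  b <- bootstrap_replicate(5, seed = 1)
  expect_length(b, 5)
  expect_true(all(b >= 1 & b <= 5))
  expect_identical(b, bootstrap_replicate(5, seed = 1))
  expect_error(bootstrap_replicate(0, seed = 1), "empty")

  # fraction of distinct indices over many replicates ~ 1 - (1 - 1/n)^n
  n <- 100
  fracs <- vapply(1:10000, function(s)
    length(unique(bootstrap_replicate(n, seed = s))) / n, numeric(1))
  expect_equal(mean(fracs), 1 - (1 - 1 / n)^n, tolerance = 0.01 / 0.634)
})

test_that("feature subsets have floor(sqrt(N)) sorted distinct indices", {
  expect_length(sample_feature_subset(8000, 1), 89)
  expect_length(sample_feature_subset(800, 1), 28)
  expect_equal(sample_feature_subset(1, 1), 1L)
  s <- sample_feature_subset(300, 7)
  expect_false(is.unsorted(s, strictly = TRUE))
  expect_true(all(s >= 1 & s <= 300))
})

test_that("each strategy gives its trees the specified budget and tags", {
  ds <- separable_dataset(12)
  ens <- random_ensemble(dim = 4, windows = c(2, 5, 8))
  V <- 4; T_ <- 4; P <- 3
  for (st in c("FDR", "RDR-FS", "RDR-ALL")) {
    m <- fit_forest(ds, ens, strategy = st, n_trees = 12, seed = 2)
    info <- tidy(m)
    budget <- feature_budget(st, V, T_, P)$tree_features
    expect_true(all(info$n_features == budget), info = st)
    if (st == "FDR") {
      expect_true(all(info$window_tag == "ALL"))
    } else {
      expect_true(all(info$window_tag %in% c("2", "5", "8")))
    }
  }

  # RDR-ALL with a 200-dim ensemble trains every tree on 800 features
  big <- random_ensemble(dim = 200, windows = 2)
  m <- fit_forest(ds, big, strategy = "RDR-ALL", n_trees = 2, seed = 1)
  expect_true(all(tidy(m)$n_features == 800))

  # with P = 1, FDR and RDR-FS share the same tree-feature budget
  expect_equal(feature_budget("FDR", 4, 4, 1)$tree_features,
               feature_budget("RDR-FS", 4, 4, 1)$tree_features)

  expect_error(fit_forest(labeled_dataset(ds$episodes, rep(1, 24), "T78"),
                          ens, n_trees = 2, seed = 1), "both classes")
})

test_that("forests are reproducible and vote by tree fraction", {
  ds <- separable_dataset(12)
  ens <- random_ensemble(dim = 4, windows = c(2, 5))
  m1 <- fit_forest(ds, ens, strategy = "RDR-FS", n_trees = 20, seed = 9)
  m2 <- fit_forest(ds, ens, strategy = "RDR-FS", n_trees = 20, seed = 9)
  expect_identical(predict_scores(m1, ds), predict_scores(m2, ds))

  s <- predict_scores(m1, ds)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(s * 20 == round(s * 20)))  # multiples of 1/n_trees

  # a single-tree forest predicts exactly its tree's vote
  m3 <- fit_forest(ds, ens, strategy = "RDR-ALL", n_trees = 1, seed = 4)
  expect_true(all(predict_scores(m3, ds) %in% c(0, 1)))
  expect_equal(predict_labels(m3, ds), as.integer(predict_scores(m3, ds) > 0.5))
})

test_that("exact vote ties resolve to the negative label", {
  expect_equal(as.integer(0.6 > 0.5), 1L)
  ds <- separable_dataset(6)
  ens <- random_ensemble(dim = 3, windows = 2)
  m <- fit_forest(ds, ens, strategy = "RDR-ALL", n_trees = 2, seed = 1)
  scores <- predict_scores(m, ds)
  labels <- predict_labels(m, ds, threshold = 0.5)
  expect_true(all(labels[scores == 0.5] == 0))
  expect_true(all(labels[scores > 0.5] == 1))
  expect_equal(predict_labels(m, ds, threshold = 0),
               as.integer(scores > 0))
})

test_that("the ensemble beats its average tree on separable data", {
  ens <- random_ensemble(dim = 4, windows = c(2, 5))
  deltas <- purrr::map_dbl(1:10, function(seed) {
    ds <- separable_dataset(15, seed = seed)
    test <- separable_dataset(10, seed = seed + 100)
    m <- fit_forest(ds, ens, strategy = "RDR-FS", n_trees = 25, seed = seed)
    r <- inspect_ensemble(m, test, test$labels)
    r$ensemble_accuracy - r$avg_tree_accuracy
  })
  expect_gt(mean(deltas), 0)
})

test_that("the count-baseline forest learns and is reproducible", {
  ds <- separable_dataset(15)
  m1 <- fit_count_forest(ds, n_trees = 30, seed = 3)
  m2 <- fit_count_forest(ds, n_trees = 30, seed = 3)
  test <- separable_dataset(10, seed = 77)
  expect_identical(predict_scores(m1, test), predict_scores(m2, test))
  expect_gt(accuracy(test$labels, predict_labels(m1, test)), 60)
})
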
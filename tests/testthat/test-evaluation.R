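# Brute-force pairwise AUC oracle: mean over positive-negative pairs.
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  vals <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(vals)
}

test_that("accuracy is the percentage of matches", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 100)
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 1, 0, 0)), 50)
  withr::with_seed(1, {
    y <- rbinom(50, 1, 0.5); p <- rbinom(50, 1, 0.5)
    perm <- sample(50)
    expect_equal(accuracy(y, p), accuracy(y[perm], p[perm]))
  })
  expect_error(accuracy(numeric(), numeric()), "empty")
})

test_that("auc equals the pairwise ranking probability", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_equal(auc(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), sample(1:3, 1))  # rounding induces ties
      expect_identical(auc(y, s), auc_oracle(y, s))
    }
  })
})

test_that("the ambiguity decomposition E = A - D is exact", {
  expect_equal(ambiguity_decomposition(c(0, 2), 1),
               tibble::tibble(E = 0, A = 1, D = 1))
  same <- ambiguity_decomposition(rep(0.3, 7), 1)
  expect_equal(same$D, 0)
  expect_equal(same$E, same$A)
  withr::with_seed(3, {
    worst <- 0
    for (i in 1:1000) {
      d <- ambiguity_decomposition(rnorm(sample(1:20, 1), sd = 5), rnorm(1))
      worst <- max(worst, abs(d$E - (d$A - d$D)))
      expect_true(d$D >= 0)
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("ensemble inspection reports the diversity identity", {
  ds <- separable_dataset(10)
  ens <- random_ensemble(dim = 4, windows = 2)
  m <- fit_forest(ds, ens, strategy = "RDR-ALL", n_trees = 10, seed = 2)
  r <- inspect_ensemble(m, ds, ds$labels)
  expect_equal(r$diversity,
               r$ensemble_accuracy / 100 - r$avg_tree_accuracy / 100,
               tolerance = 1e-12)
  # a single-tree ensemble has zero diversity
  m1 <- fit_forest(ds, ens, strategy = "RDR-ALL", n_trees = 1, seed = 2)
  expect_equal(inspect_ensemble(m1, ds, ds$labels)$diversity, 0)
})

test_that("cross-validation stratifies, partitions, and averages folds", {
  ds <- separable_dataset(15)  # 15 per class
  ens <- random_ensemble(dim = 4, windows = c(2, 5))
  ev <- cross_validate(ds, ens, strategy = "RDR-ALL", n_trees = 10,
                       folds = 5, seed = 3)
  expect_equal(sum(ev$folds$n_test), 30)
  fold_of <- adeforest:::stratified_folds(ds$labels, 5, 3)
  for (cls in 0:1) {
    sizes <- table(fold_of[ds$labels == cls])
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_equal(sort(unique(fold_of)), 1:5)
  expect_equal(ev$summary$accuracy, mean(ev$folds$ensemble_accuracy))
  expect_equal(ev$summary$diversity,
               ev$summary$accuracy / 100 - ev$summary$avg_tree_accuracy / 100,
               tolerance = 1e-12)
  expect_error(cross_validate(ds, ens, folds = 20, seed = 1), "folds")
})

test_that("friedman statistic matches the rank formula and the reference", {
  # one method always best, one always second, one always third
  m <- matrix(c(3, 3, 3, 3, 2, 2, 2, 2, 1, 1, 1, 1), nrow = 4)
  colnames(m) <- c("A", "B", "C")
  fr <- friedman_test(m)
  expect_equal(fr$chi2, 8)
  expect_equal(fr$df, 2)

  same <- matrix(1, nrow = 3, ncol = 3)
  expect_equal(friedman_test(same)$chi2, 0)
  expect_equal(friedman_test(same)$p_value, 1)

  # rank-based: invariant under monotone transformation
  withr::with_seed(8, {
    x <- matrix(runif(15), nrow = 5)
    expect_equal(friedman_test(x)$chi2, friedman_test(exp(2 * x))$chi2)
  })

  # agreement with stats::friedman.test on random matrices
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(3:10, 1); k <- sample(2:5, 1)
      x <- matrix(rnorm(n * k), nrow = n)
      ref <- stats::friedman.test(x)
      expect_equal(friedman_test(x)$chi2, unname(ref$statistic),
                   tolerance = 1e-8)
      expect_equal(friedman_test(x)$p_value, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("post-hoc adjustment behaves across procedures", {
  withr::with_seed(4, {
    two <- matrix(rnorm(12), nrow = 6, ncol = 2,
                  dimnames = list(NULL, c("A", "B")))
    bh <- posthoc_pairwise(two, "bergmann_hommel")
    expect_equal(bh$p_adjusted, bh$p_raw)
  })

  same <- matrix(1, nrow = 4, ncol = 3)
  expect_true(all(posthoc_pairwise(same, "bergmann_hommel")$p_adjusted == 1))

  # Bergmann-Hommel is uniformly at least as powerful as Holm for k = 3
  withr::with_seed(12, {
    for (i in 1:100) {
      x <- matrix(rnorm(3 * sample(4:12, 1)), ncol = 3,
                  dimnames = list(NULL, c("A", "B", "C")))
      bh <- posthoc_pairwise(x, "bergmann_hommel")
      hm <- posthoc_pairwise(x, "holm")
      expect_true(all(bh$p_adjusted <= hm$p_adjusted + 1e-12))
      expect_true(all(bh$p_adjusted >= bh$p_raw - 1e-12))
      expect_true(all(bh$p_adjusted <= 1))
    }
  })

  big <- matrix(rnorm(25), nrow = 5)
  expect_error(posthoc_pairwise(big, "bergmann_hommel"), "holm")
  expect_length(posthoc_pairwise(big, "holm")$p_adjusted, 10)
})

test_that("pool-size sweep enumerates window combinations", {
  ds <- separable_dataset(12)
  ens <- random_ensemble(dim = 3, windows = c(2, 5, 8))
  pool <- pool_size_experiment(ds, ens, sizes = c(1, 3), n_trees = 5, seed = 2)
  expect_equal(pool$n_combinations, c(3L, 1L))
  expect_equal(choose(10, 3), 120)  # the full-design combination count
  expect_true(all(pool$accuracy >= 0 & pool$accuracy <= 100))

  # size-1 mean is the mean over single-window runs by definition
  singles <- purrr::map_dbl(c(2, 5, 8), function(w) {
    pool_size_experiment(ds, subset_windows(ens, w), sizes = 1,
                         n_trees = 5, seed = 2)$accuracy
  })
  expect_equal(pool$accuracy[1], mean(singles))
})
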
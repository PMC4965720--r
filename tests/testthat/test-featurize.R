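test_that("feature budgets match the three-strategy accounting", {
  expect_equal(unlist(feature_budget("FDR", 200, 4, 10)[, -1]),
               c(ensemble_features = 8000L, tree_features = 89L))
  expect_equal(unlist(feature_budget("RDR-FS", 200, 4, 10)[, -1]),
               c(ensemble_features = 8000L, tree_features = 28L))
  expect_equal(unlist(feature_budget("RDR-ALL", 200, 4, 10)[, -1]),
               c(ensemble_features = 8000L, tree_features = 800L))
  expect_equal(feature_budget("RDR-FS", 1, 1, 1)$tree_features, 1L)
})

test_that("episode embedding is the count-weighted sum of event vectors", {
  ens <- random_ensemble(dim = 3, windows = c(2, 5))
  corpus <- care_corpus(
    patient_id = "p", episode_id = "e",
    sentences = list(list()),
    diagnoses = list(events(c("D1", "D1"), c(0, 1))),
    drugs = list(events(c("R1", "R2", "R2", "R2"), c(0, 0, 1, 2))),
    measurements = list(events(character(), integer()))
  )
  v <- embed_episode(corpus[1, ], ens, window = 2)
  d <- ens$dim
  sp_diag <- get_space(ens, "diagnosis", 2)$vectors
  sp_drug <- get_space(ens, "drug", 2)$vectors
  expect_equal(v[1:d], rep(0, d))                      # word block empty
  expect_equal(v[(d + 1):(2 * d)], unname(2 * sp_diag["D1", ]))
  expect_equal(v[(2 * d + 1):(3 * d)],
               unname(sp_drug["R1", ] + 3 * sp_drug["R2", ]))
  expect_equal(v[(3 * d + 1):(4 * d)], rep(0, d))      # measurement block empty

  # out-of-vocabulary events contribute zero
  corpus$drugs[[1]] <- events("UNSEEN", 0)
  corpus$diagnoses[[1]] <- events("UNSEEN2", 0)
  expect_equal(embed_episode(corpus[1, ], ens, 2), rep(0, 4 * d))

  expect_error(embed_episode(corpus[1, ], ens, window = 99), "not in ensemble")
})

test_that("target-code occurrences never reach the features (leakage guard)", {
  ens <- random_ensemble(dim = 3, windows = c(2, 5))
  base <- tiny_dataset("T78")          # episode 1 carries T78 once
  boosted <- base
  boosted$episodes$diagnoses[[1]] <- events(c("D1", "T78", "T78", "T78", "D1"),
                                            c(0, 1, 1, 1, 2))
  for (w in c(2, 5)) {
    expect_equal(transform_dataset(base, ens, w)$matrix,
                 transform_dataset(boosted, ens, w)$matrix)
  }
  cb <- bag_of_events(base)
  cb2 <- bag_of_events(boosted)
  expect_false(any(grepl("T78$", cb$vocab)))
  expect_equal(as.matrix(cb$matrix), as.matrix(cb2$matrix))
})

test_that("transformation shapes, block bookkeeping and linearity hold", {
  ens <- random_ensemble(dim = 2, windows = c(2, 5))
  ds <- tiny_dataset()
  td <- transform_dataset(ds, ens, 2)
  expect_equal(dim(td$matrix), c(3, 2 * 4))
  expect_equal(td$block_index$data_type, c("word", "diagnosis", "drug", "measurement"))

  empty <- labeled_dataset(ds$episodes[0, ], integer(), "T78")
  expect_equal(dim(transform_dataset(empty, ens, 2)$matrix), c(0, 8))

  cw <- concat_windows(ds, ens, c(2, 5))
  expect_equal(ncol(cw$matrix), 2 * 4 * 2)
  expect_equal(nrow(cw$block_index), 8)
  # block ranges partition the columns in order
  expect_equal(cw$block_index$start, seq(1, 15, by = 2))
  expect_equal(cw$block_index$end, seq(2, 16, by = 2))
  # slicing by block and re-concatenating reproduces the matrix
  rebuilt <- do.call(cbind, purrr::map2(cw$block_index$start, cw$block_index$end,
                                        function(s, e) cw$matrix[, s:e, drop = FALSE]))
  expect_equal(unname(rebuilt), unname(cw$matrix))
  # per-window blocks agree with the single-window transform
  expect_equal(unname(cw$matrix[, 1:8]), unname(transform_dataset(ds, ens, 2)$matrix))
  expect_equal(unname(cw$matrix[, 9:16]), unname(transform_dataset(ds, ens, 5)$matrix))

  expect_error(concat_windows(ds, ens, integer()), "empty window")

  # a 200-dimensional ensemble yields the 800-column per-window representation
  big <- random_ensemble(dim = 200, windows = 2)
  expect_equal(ncol(transform_dataset(ds, big, 2)$matrix), 800)
})

test_that("episode embeddings are additive over event multisets", {
  ens <- random_ensemble(dim = 3, windows = c(2, 5))
  a <- tiny_corpus()[1, ]
  b <- tiny_corpus()[2, ]
  merged <- a
  merged$sentences[[1]] <- c(a$sentences[[1]], b$sentences[[1]])
  for (col in c("diagnoses", "drugs", "measurements")) {
    merged[[col]][[1]] <- dplyr::arrange(
      dplyr::bind_rows(a[[col]][[1]], b[[col]][[1]]), .data$day)
  }
  expect_equal(embed_episode(merged, ens, 2),
               embed_episode(a, ens, 2) + embed_episode(b, ens, 2))
})

test_that("bag of events counts tokens per stream and conserves totals", {
  ds <- tiny_dataset("T78")
  cb <- bag_of_events(ds)
  m <- as.matrix(cb$matrix)
  expect_equal(unname(m[2, "word:pain"]), 2)
  expect_equal(unname(m[1, "diagnosis:D1"]), 2)
  expect_true(all(m >= 0))
  # row sums = total retained events (T78 removed from episode 1)
  totals <- purrr::pmap_dbl(
    list(ds$episodes$sentences, ds$episodes$diagnoses, ds$episodes$drugs,
         ds$episodes$measurements),
    function(s, dg, dr, ms) sum(lengths(s)) + sum(dg$code != "T78") +
      nrow(dr) + nrow(ms)
  )
  expect_equal(unname(rowSums(m)), totals)
})
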
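# Sequence sets built directly (bypassing a corpus) for training tests.
seqset <- function(sequences, data_type = "diagnosis") {
  structure(list(data_type = data_type, sequences = sequences),
            class = "sequence_set")
}

# Two token cliques that never co-occur: {a, b} vs {c, d}.
clique_corpus <- function(n = 250, seed = 5) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      if (i %% 2 == 0) sample(c("a", "b", "a", "b")) else sample(c("c", "d", "c", "d"))
    })
  })
}

test_that("skip-gram places co-occurring tokens closer than non-co-occurring ones", {
  sp <- train_semantic_space(seqset(clique_corpus()),
                             skipgram_config(dim = 16, window = 3, seed = 9))
  expect_gt(space_similarity(sp, "a", "b"), space_similarity(sp, "a", "c"))
  expect_gt(space_similarity(sp, "c", "d"), space_similarity(sp, "b", "d"))
})

test_that("training is deterministic and respects dim and min_count", {
  seqs <- seqset(clique_corpus(n = 60))
  cfg <- skipgram_config(dim = 8, window = 2, seed = 3)
  s1 <- train_semantic_space(seqs, cfg)
  s2 <- train_semantic_space(seqs, cfg)
  expect_identical(s1$vectors, s2$vectors)
  expect_equal(ncol(s1$vectors), 8)
  expect_true(all(is.finite(s1$vectors)))

  # a token below min_count is dropped from the vocabulary
  seqs2 <- seqset(c(clique_corpus(n = 60), list(c("rare", "a"))))
  sp <- train_semantic_space(seqs2, skipgram_config(dim = 4, min_count = 2, seed = 1))
  expect_false("rare" %in% rownames(sp$vectors))
  expect_true("a" %in% rownames(sp$vectors))

  expect_error(
    train_semantic_space(seqset(list(c("x", "y"))),
                         skipgram_config(dim = 4, min_count = 5, seed = 1)),
    "empty vocabulary"
  )
})

test_that("context window gates which co-occurrences carry training signal", {
  # x and y always sit at distance exactly 5; the two fillers next to x come
  # from pool A and the two next to y from pool B, so with window 2 the pair
  # is never trained together and shares no context tokens, while window 5
  # delivers a direct positive update in every sequence
  withr::with_seed(11, {
    poolA <- sprintf("a%02d", 1:15)
    poolB <- sprintf("b%02d", 1:15)
    seqs <- purrr::map(1:300, function(i)
      c("x", sample(poolA, 2), sample(poolB, 2), "y"))
  })
  near <- train_semantic_space(seqset(seqs), skipgram_config(dim = 12, window = 5, seed = 2))
  far <- train_semantic_space(seqset(seqs), skipgram_config(dim = 12, window = 2, seed = 2))
  expect_gt(space_similarity(near, "x", "y"), space_similarity(far, "x", "y"))
  expect_gt(space_similarity(near, "x", "y"), 0)
  expect_lt(space_similarity(far, "x", "y"), 0.05)
})

test_that("the space grid is complete, shares dim, and honours exclusion", {
  corpus <- tiny_corpus()
  cfg <- skipgram_config(dim = 4, seed = 1)
  grid <- build_space_grid(corpus, windows = c(2, 4, 6), cfg)
  expect_length(grid$spaces, 4 * 3)
  expect_true(all(purrr::map_int(grid$spaces, "dim") == 4))
  expect_equal(grid$windows, c(2L, 4L, 6L))

  single <- build_space_grid(corpus, windows = 2, cfg)
  expect_length(single$spaces, 4)

  excl <- build_space_grid(corpus, windows = c(2, 4), cfg, exclude_code = "T78")
  for (w in c(2, 4)) {
    expect_false("T78" %in% rownames(get_space(excl, "diagnosis", w)$vectors))
    expect_true("T78" %in% rownames(get_space(grid, "diagnosis", 2)$vectors))
  }

  expect_error(build_space_grid(corpus, windows = c(2, 2), cfg), "duplicate")
})

test_that("word2vec text persistence round-trips", {
  sp <- random_space("drug", 2, 5, c("R1", "R2", "R3"), seed = 4)
  path <- withr::local_tempfile(fileext = ".txt")
  save_space(sp, path)
  expect_equal(strsplit(readLines(path)[1], " ")[[1]], c("3", "5"))
  back <- load_space(path, data_type = "drug", window = 2)
  expect_equal(rownames(back$vectors), rownames(sp$vectors))
  expect_equal(back$vectors, sp$vectors, tolerance = 1e-6, ignore_attr = TRUE)

  # arity mismatch is reported with its line
  lines <- readLines(path)
  lines[3] <- paste(strsplit(lines[3], " ")[[1]][1:5], collapse = " ")
  writeLines(lines, path)
  expect_error(load_space(path), "line 3")

  # empty-vocabulary space: header only
  empty <- adeforest:::new_semantic_space("word", 1, 7, matrix(0, 0, 7))
  save_space(empty, path)
  expect_equal(readLines(path), "0 7")
  expect_equal(nrow(load_space(path)$vectors), 0)
})

test_that("window restriction produces a valid sub-ensemble", {
  ens <- random_ensemble(dim = 3, windows = c(2, 5, 8))
  sub <- subset_windows(ens, c(2, 8))
  expect_equal(sub$windows, c(2L, 8L))
  expect_length(sub$spaces, 8)
  expect_error(subset_windows(ens, 4), "not all present")
})
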
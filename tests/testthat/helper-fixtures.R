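# Fixtures are built in code: a tiny hand-written corpus for exact-value
# tests, and ensembles with known (random but seeded) vectors so featurization
# and forests can be tested without training embeddings.

events <- function(codes, days) tibble::tibble(code = codes, day = as.integer(days))

tiny_corpus <- function() {
  care_corpus(
    patient_id = c("p1", "p1", "p2"),
    episode_id = c("e1", "e2", "e3"),
    sentences = list(
      list(c("fever", "cough"), c("rash")),
      list(c("pain", "pain", "nausea")),
      list(c("dizzy"))
    ),
    diagnoses = list(
      events(c("D1", "T78", "D1"), c(0, 1, 2)),
      events(c("D2"), 0),
      events(c("D1", "D3"), c(0, 3))
    ),
    drugs = list(
      events(c("R1", "R2"), c(0, 1)),
      events(c("R1"), 0),
      events(c("R3"), 1)
    ),
    measurements = list(
      events("M1", 0),
      events(c("M1", "M2"), c(0, 1)),
      events("M2", 2)
    )
  )
}

# A semantic space whose vectors are seeded standard normals.
random_space <- function(data_type, window, dim, vocab, seed = 1) {
  vec <- withr::with_seed(seed, matrix(rnorm(length(vocab) * dim),
                                       nrow = length(vocab)))
  rownames(vec) <- vocab
  adeforest:::new_semantic_space(data_type, window, dim, vec)
}

# Complete ensemble over the tiny corpus's vocabulary with random vectors.
random_ensemble <- function(dim = 3, windows = c(2, 5), seed = 1) {
  vocabs <- list(
    word = c("fever", "cough", "rash", "pain", "nausea", "dizzy"),
    diagnosis = c("D1", "D2", "D3"),
    drug = c("R1", "R2", "R3"),
    measurement = c("M1", "M2")
  )
  spaces <- list()
  k <- 0
  for (w in windows) {
    for (dt in names(vocabs)) {
      k <- k + 1
      spaces[[adeforest:::space_key(dt, w)]] <-
        random_space(dt, w, dim, vocabs[[dt]], seed = seed + k)
    }
  }
  adeforest:::new_space_ensemble(spaces, names(vocabs), windows, dim)
}

tiny_dataset <- function(target_code = "T78") {
  labeled_dataset(tiny_corpus(), c(1, 0, 0), target_code)
}

# A linearly separable labeled dataset over the tiny vocabulary: positives
# carry drug R2 heavily, negatives R3. Episodes satisfy the retention filter.
separable_dataset <- function(n_per_class = 20, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c(1L, 0L), each = n_per_class)
    mk <- function(lab, i) {
      drug <- if (lab == 1) "R2" else "R3"
      list(
        sentences = list(list(sample(c("fever", "cough", "pain"), 3, replace = TRUE))),
        diagnoses = events(sample(c("D1", "D2", "D3"), 2, replace = TRUE), c(0, 1)),
        drugs = events(rep(drug, 3), 0:2),
        measurements = events(sample(c("M1", "M2"), 1), 0)
      )
    }
    eps <- purrr::map2(labels, seq_len(n), mk)
    corpus <- care_corpus(
      patient_id = sprintf("p%d", seq_len(n)),
      episode_id = sprintf("e%d", seq_len(n)),
      sentences = purrr::map(eps, "sentences"),
      diagnoses = purrr::map(eps, "diagnoses"),
      drugs = purrr::map(eps, "drugs"),
      measurements = purrr::map(eps, "measurements")
    )
    labeled_dataset(corpus, labels, "T78")
  })
}

# Small synthetic setup shared by property tests: corpus, grid and one
# balanced dataset, at reduced dimensionality for speed.
small_synth_setup <- function(seed, signal_strength = 0.8, dim = 16,
                              windows = c(2, 5), n_pos = 30) {
  cfg <- synth_config(seed = seed, signal_strength = signal_strength)
  corpus <- generate_corpus(cfg)
  sg <- skipgram_config(dim = dim, seed = seed)
  grid <- build_space_grid(corpus, windows, sg, exclude_code = "ADE01")
  ds <- generate_ade_dataset(corpus, "ADE01", n_pos, seed = seed)
  list(corpus = corpus, grid = grid, dataset = ds, sg = sg)
}
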
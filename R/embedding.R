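#' Skip-gram training configuration
#'
#' Hyperparameters for learning one semantic space with the skip-gram
#' architecture and negative sampling. `window` is the one-sided symmetric
#' context size: a window of 2 ("2+2") considers two items on each side of the
#' focus item. Training is single-threaded with its own seeded generator, so a
#' given configuration always yields bit-identical vectors.
#'
#' @param dim vector dimensionality
#' @param window one-sided symmetric context window size
#' @param min_count minimum token frequency for vocabulary inclusion
#' @param epochs training passes over the sequences
#' @param negatives negative samples per positive (item, context) pair
#' @param learning_rate initial step size, decayed linearly to 1e-4 of itself
#' @param seed integer seed for initialization and negative sampling
#' @return a list of class `skipgram_config`
#' @export
skipgram_config <- function(dim = 200, window = 2, min_count = 1, epochs = 5,
                            negatives = 5, learning_rate = 0.025, seed = 1) {
  stopifnot(dim >= 1, window >= 1, min_count >= 1, epochs >= 1,
            negatives >= 1, learning_rate > 0)
  structure(
    list(dim = as.integer(dim), window = as.integer(window),
         min_count = as.integer(min_count), epochs = as.integer(epochs),
         negatives = as.integer(negatives), learning_rate = learning_rate,
         seed = as.integer(seed)),
    class = "skipgram_config"
  )
}

#' Train one semantic space from a sequence set
#'
#' Learns a dense vector per token by maximizing the probability of observed
#' (item, context) pairs under the skip-gram objective with negative sampling;
#' context is any item within `config$window` positions on either side. The
#' input-layer parameters are the semantic vectors.
#'
#' @param sequences a `sequence_set` from [extract_sequences()]
#' @param config a [skipgram_config()]
#' @return an object of class `semantic_space`: list with `data_type`,
#'   `window`, `dim`, and `vectors` (token-by-dim matrix with token rownames)
#' @export
train_semantic_space <- function(sequences, config = skipgram_config()) {
  stopifnot(inherits(sequences, "sequence_set"),
            inherits(config, "skipgram_config"))
  toks <- unlist(sequences$sequences, use.names = FALSE)
  if (length(toks) == 0) stop("no training sequences", call. = FALSE)
  # vocabulary: frequency >= min_count, ordered by frequency then first
  # appearance for determinism
  tab <- table(factor(toks, levels = unique(toks)))
  keep <- tab[tab >= config$min_count]
  if (length(keep) == 0) {
    stop("empty vocabulary: no token reaches min_count = ", config$min_count,
         call. = FALSE)
  }
  vocab <- names(keep)[order(-as.integer(keep))]
  counts <- as.numeric(keep[vocab])
  ids <- stats::setNames(seq_along(vocab) - 1L, vocab)
  seqs <- purrr::map(sequences$sequences, function(s) {
    unname(ids[s[s %in% vocab]])
  })
  seqs <- seqs[lengths(seqs) > 0]
  vec <- sgns_train(seqs, length(vocab), counts, config$dim, config$window,
                    config$negatives, config$epochs, config$learning_rate,
                    as.numeric(config$seed))
  rownames(vec) <- vocab
  new_semantic_space(sequences$data_type, config$window, config$dim, vec)
}

new_semantic_space <- function(data_type, window, dim, vectors) {
  stopifnot(ncol(vectors) == dim, all(is.finite(vectors)))
  structure(
    list(data_type = data_type, window = as.integer(window),
         dim = as.integer(dim), vectors = vectors),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat("<semantic_space> ", x$data_type, " window=", x$window,
      " dim=", x$dim, " vocab=", nrow(x$vectors), "\n", sep = "")
  invisible(x)
}

#' Cosine similarity between two tokens of a semantic space
#' @param space a `semantic_space`
#' @param a,b tokens in the space's vocabulary
#' @return cosine similarity in \[-1, 1\]
#' @export
space_similarity <- function(space, a, b) {
  v <- space$vectors[a, ]
  w <- space$vectors[b, ]
  sum(v * w) / sqrt(sum(v^2) * sum(w^2))
}

#' Train the full grid of semantic spaces
#'
#' One space per (data type, context window size): with all four clinical data
#' types and ten window sizes this yields the full 40-space ensemble. The
#' target ADE diagnosis code, if given, is deleted from diagnosis sequences
#' before training so neighbouring events become adjacent and the code never
#' enters any vocabulary.
#'
#' @param corpus an `ade_corpus` tibble (the unlabeled background corpus)
#' @param windows distinct context window sizes, ascending
#' @param config a [skipgram_config()]; its `window` field is overridden per
#'   grid cell and its `seed` is the master seed for the grid
#' @param exclude_code optional target diagnosis code to exclude
#' @return an object of class `space_ensemble`
#' @export
build_space_grid <- function(corpus, windows, config = skipgram_config(),
                             exclude_code = NULL) {
  stopifnot(length(windows) >= 1)
  if (anyDuplicated(windows)) stop("duplicate window sizes", call. = FALSE)
  windows <- sort(as.integer(windows))
  seqs <- purrr::map(DATA_TYPES, function(dt) {
    extract_sequences(corpus, dt,
                      exclude_code = if (dt == "diagnosis") exclude_code)
  })
  names(seqs) <- DATA_TYPES
  cell_seeds <- derive_seeds(config$seed, length(DATA_TYPES) * length(windows))
  spaces <- list()
  k <- 0L
  for (w in windows) {
    for (dt in DATA_TYPES) {
      k <- k + 1L
      cfg <- config
      cfg$window <- w
      cfg$seed <- cell_seeds[k]
      spaces[[space_key(dt, w)]] <- train_semantic_space(seqs[[dt]], cfg)
    }
  }
  new_space_ensemble(spaces, DATA_TYPES, windows, config$dim)
}

space_key <- function(data_type, window) paste0(data_type, "@", window)

new_space_ensemble <- function(spaces, data_types, windows, dim) {
  stopifnot(length(spaces) == length(data_types) * length(windows))
  dims <- vapply(spaces, function(s) s$dim, integer(1))
  stopifnot(all(dims == dim))
  structure(
    list(spaces = spaces, data_types = data_types,
         windows = as.integer(windows), dim = as.integer(dim)),
    class = "space_ensemble"
  )
}

#' @export
print.space_ensemble <- function(x, ...) {
  cat("<space_ensemble> ", length(x$spaces), " spaces: ",
      length(x$data_types), " data types x ", length(x$windows),
      " windows (", paste(x$windows, collapse = ", "), "), dim=", x$dim,
      "\n", sep = "")
  invisible(x)
}

#' Look up one space of an ensemble
#' @param ensemble a `space_ensemble`
#' @param data_type,window grid coordinates
#' @return a `semantic_space`
#' @export
get_space <- function(ensemble, data_type, window) {
  key <- space_key(match_data_type(data_type), window)
  sp <- ensemble$spaces[[key]]
  if (is.null(sp)) {
    stop("ensemble has no space for ", key, call. = FALSE)
  }
  sp
}

#' Restrict an ensemble to a subset of its windows
#' @param ensemble a `space_ensemble`
#' @param windows subset of `ensemble$windows`
#' @return a `space_ensemble` over the selected windows
#' @export
subset_windows <- function(ensemble, windows) {
  windows <- sort(as.integer(windows))
  if (!all(windows %in% ensemble$windows)) {
    stop("requested windows not all present in ensemble", call. = FALSE)
  }
  keys <- as.vector(outer(ensemble$data_types, windows, space_key))
  new_space_ensemble(ensemble$spaces[keys], ensemble$data_types, windows,
                     ensemble$dim)
}

#' Persist a semantic space in word2vec text format
#'
#' Header line "vocab_count dim", then one "token v1 ... vV" row per token.
#'
#' @param space a `semantic_space`
#' @param path file path
#' @export
save_space <- function(space, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(nrow(space$vectors), space$dim), con)
  if (nrow(space$vectors) > 0) {
    rows <- apply(space$vectors, 1, function(v)
      paste(format(v, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = " "))
    writeLines(paste(rownames(space$vectors), rows), con)
  }
  invisible(path)
}

#' @rdname save_space
#' @param data_type,window grid coordinates to stamp on the loaded space (the
#'   text format does not carry them)
#' @export
load_space <- function(path, data_type = "word", window = 1L) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("line 1: malformed word2vec header", call. = FALSE)
  }
  n <- hdr[1]; dim <- hdr[2]
  if (length(lines) - 1 != n) {
    stop("header declares ", n, " rows but file has ", length(lines) - 1,
         call. = FALSE)
  }
  vec <- matrix(0, nrow = n, ncol = dim)
  toks <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) != dim + 1) {
      stop("line ", i + 1, ": expected ", dim + 1, " fields, found ",
           length(parts), call. = FALSE)
    }
    toks[i] <- parts[1]
    vec[i, ] <- as.numeric(parts[-1])
  }
  rownames(vec) <- toks
  new_semantic_space(match_data_type(data_type), window, dim, vec)
}
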
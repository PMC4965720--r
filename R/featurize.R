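#' Per-strategy feature accounting
#'
#' All three utilization strategies expose the same V x T x P features to the
#' ensemble as a whole (V = vector dimensionality, T = number of data types,
#' P = number of context window sizes); they differ in how many features each
#' tree may inspect: floor(sqrt(VTP)) for FDR, floor(sqrt(VT)) for RDR-FS and
#' the full VT for RDR-ALL. Square roots are floored.
#'
#' @param strategy `"FDR"`, `"RDR-FS"` or `"RDR-ALL"`
#' @param V,T,P positive integers
#' @return tibble with columns `strategy`, `ensemble_features`, `tree_features`
#' @export
feature_budget <- function(strategy, V, T, P) {
  strategy <- match_strategy(strategy)
  stopifnot(V >= 1, T >= 1, P >= 1)
  ensemble_features <- as.integer(V * T * P)
  tree_features <- switch(strategy,
    "FDR" = floor(sqrt(V * T * P)),
    "RDR-FS" = floor(sqrt(V * T)),
    "RDR-ALL" = V * T
  )
  tibble::tibble(strategy = strategy,
                 ensemble_features = ensemble_features,
                 tree_features = as.integer(tree_features))
}

# Token counts of one episode's stream for a given data type, with the target
# code stripped from the diagnosis stream.
episode_token_counts <- function(episode_row, data_type, target_code = NULL) {
  if (data_type == "word") {
    toks <- unlist(episode_row$sentences[[1]], use.names = FALSE)
  } else {
    toks <- episode_row[[stream_column(data_type)]][[1]]$code
  }
  if (data_type == "diagnosis" && !is.null(target_code)) {
    toks <- toks[toks != target_code]
  }
  if (length(toks) == 0) return(integer(0))
  table(toks)
}

#' Embed one care episode at one window size
#'
#' For each data type, every event's vector is multiplied by the event's count
#' in the episode and summed (count-weighted bag of embeddings); the four
#' per-type vectors are concatenated in canonical order (word, diagnosis,
#' drug, measurement). Occurrences of `target_code` in the diagnosis stream
#' are removed first; events absent from a space's vocabulary contribute zero.
#'
#' @param episode_row one-row slice of an `ade_corpus`
#' @param ensemble a `space_ensemble` holding all four data types at `window`
#' @param window context window size to use
#' @param target_code optional diagnosis token excluded from featurization
#' @return numeric vector of length `ensemble$dim * length(data_types)`
#' @export
embed_episode <- function(episode_row, ensemble, window, target_code = NULL) {
  if (!window %in% ensemble$windows) {
    stop("window ", window, " not in ensemble", call. = FALSE)
  }
  blocks <- purrr::map(ensemble$data_types, function(dt) {
    sp <- get_space(ensemble, dt, window)
    cnt <- episode_token_counts(episode_row, dt, target_code)
    out <- numeric(sp$dim)
    if (length(cnt) > 0) {
      known <- intersect(names(cnt), rownames(sp$vectors))
      if (length(known) > 0) {
        out <- as.numeric(as.numeric(cnt[known]) %*%
                            sp$vectors[known, , drop = FALSE])
      }
    }
    out
  })
  unlist(blocks, use.names = FALSE)
}

# Sparse episode-by-token count matrix for one data type over a given
# vocabulary (columns = vocab order); tokens outside vocab are dropped.
count_matrix <- function(corpus, data_type, vocab, target_code = NULL) {
  n <- nrow(corpus)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  vid <- stats::setNames(seq_along(vocab), vocab)
  for (i in seq_len(n)) {
    cnt <- episode_token_counts(corpus[i, , drop = FALSE], data_type,
                                target_code)
    if (length(cnt) == 0) next
    known <- names(cnt)[names(cnt) %in% vocab]
    if (length(known) == 0) next
    ii <- c(ii, rep.int(i, length(known)))
    jj <- c(jj, unname(vid[known]))
    xx <- c(xx, as.numeric(cnt[known]))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)))
}

#' Transform a labeled dataset into dense features at one window size
#'
#' Row i is [embed_episode()] of episode i; the block index records which
#' columns belong to which (window, data type) pair.
#'
#' @param dataset an `ade_dataset`
#' @param ensemble a `space_ensemble`
#' @param window context window size
#' @return an object of class `transformed_dataset`: list with `matrix`
#'   (n x V*T), `block_index` tibble (`window`, `data_type`, `start`, `end`),
#'   `labels`, `windows`
#' @export
transform_dataset <- function(dataset, ensemble, window) {
  if (!window %in% ensemble$windows) {
    stop("window ", window, " not in ensemble", call. = FALSE)
  }
  V <- ensemble$dim
  blocks <- purrr::map(ensemble$data_types, function(dt) {
    sp <- get_space(ensemble, dt, window)
    vocab <- rownames(sp$vectors)
    if (length(vocab) == 0 || nrow(dataset$episodes) == 0) {
      return(matrix(0, nrow = nrow(dataset$episodes), ncol = V))
    }
    cm <- count_matrix(dataset$episodes, dt, vocab, dataset$target_code)
    as.matrix(cm %*% sp$vectors)
  })
  mat <- do.call(cbind, blocks)
  if (nrow(dataset$episodes) == 0) mat <- matrix(0, nrow = 0, ncol = V * length(blocks))
  block_index <- tibble::tibble(
    window = as.integer(window),
    data_type = ensemble$data_types,
    start = seq(1L, by = V, length.out = length(blocks)),
    end = seq(V, by = V, length.out = length(blocks))
  )
  new_transformed_dataset(mat, block_index, dataset$labels, window)
}

new_transformed_dataset <- function(mat, block_index, labels, windows) {
  colnames(mat) <- paste0("f", seq_len(ncol(mat)))
  structure(
    list(matrix = mat, block_index = block_index, labels = labels,
         windows = as.integer(windows)),
    class = "transformed_dataset"
  )
}

#' @export
print.transformed_dataset <- function(x, ...) {
  cat("<transformed_dataset> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (windows ", paste(x$windows, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Concatenate per-window transformations (fused representation)
#'
#' Horizontal concatenation of [transform_dataset()] over every requested
#' window, ascending window order — the representation the FDR strategy hands
#' to each tree's feature sampler.
#'
#' @inheritParams transform_dataset
#' @param windows windows to include (all must be in the ensemble)
#' @return a `transformed_dataset` with `V * T * length(windows)` columns
#' @export
concat_windows <- function(dataset, ensemble, windows = ensemble$windows) {
  if (length(windows) == 0) stop("empty window list", call. = FALSE)
  windows <- sort(as.integer(windows))
  parts <- purrr::map(windows, function(w) transform_dataset(dataset, ensemble, w))
  mat <- do.call(cbind, purrr::map(parts, "matrix"))
  offsets <- cumsum(c(0L, purrr::map_int(parts, function(p) ncol(p$matrix))))
  block_index <- purrr::imap_dfr(parts, function(p, i) {
    dplyr::mutate(p$block_index,
                  start = .data$start + offsets[i],
                  end = .data$end + offsets[i])
  })
  new_transformed_dataset(mat, block_index, dataset$labels, windows)
}

#' Count-based baseline representation (bag of clinical events)
#'
#' One sparse column per token observed anywhere in the dataset across the
#' four streams (columns are namespaced by data type); entries are occurrence
#' counts per episode. The target diagnosis code is removed.
#'
#' @param dataset an `ade_dataset`
#' @return list of class `count_dataset`: sparse `matrix`, `labels`, `vocab`
#' @export
bag_of_events <- function(dataset) {
  per_type <- purrr::map(DATA_TYPES, function(dt) {
    counts <- purrr::map(seq_len(nrow(dataset$episodes)), function(i) {
      episode_token_counts(dataset$episodes[i, , drop = FALSE], dt,
                           dataset$target_code)
    })
    vocab <- sort(unique(unlist(purrr::map(counts, names))))
    if (length(vocab) == 0) {
      return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                  dims = c(nrow(dataset$episodes), 0)))
    }
    vid <- stats::setNames(seq_along(vocab), vocab)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (i in seq_along(counts)) {
      cnt <- counts[[i]]
      if (length(cnt) == 0) next
      ii <- c(ii, rep.int(i, length(cnt)))
      jj <- c(jj, unname(vid[names(cnt)]))
      xx <- c(xx, as.numeric(cnt))
    }
    m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nrow(dataset$episodes), length(vocab)))
    colnames(m) <- paste0(dt, ":", vocab)
    m
  })
  mat <- do.call(cbind, per_type)
  structure(
    list(matrix = mat, labels = dataset$labels, vocab = colnames(mat)),
    class = "count_dataset"
  )
}
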
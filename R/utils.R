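#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib adeforest, .registration = TRUE
NULL

# Canonical order of the four clinical data types; every concatenation in the
# package follows it.
DATA_TYPES <- c("word", "diagnosis", "drug", "measurement")

STRATEGIES <- c("FDR", "RDR-FS", "RDR-ALL")

#' Derive a stream of reproducible sub-seeds from a master seed
#'
#' Stages of the pipeline (corpus generation, space training, per-tree
#' bootstraps, fold shuffling) each consume their own seed so that any stage is
#' reproducible in isolation. Seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed
#' @param n number of sub-seeds
#' @return integer vector of length `n`
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  # splitmix-style multiplicative hop, kept in double precision; modulus is
  # prime 2^31 - 1 so seeds never hit .Machine$integer.max
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271) %% m
    out[i] <- as.integer(s)
  }
  out
}

match_strategy <- function(strategy) {
  s <- toupper(gsub("_", "-", strategy))
  if (!s %in% STRATEGIES) {
    stop("unknown strategy '", strategy, "'; must be one of ",
         paste(STRATEGIES, collapse = ", "), call. = FALSE)
  }
  s
}

match_data_type <- function(data_type) {
  match.arg(data_type, DATA_TYPES)
}

stream_column <- function(data_type) {
  switch(data_type,
    diagnosis = "diagnoses",
    drug = "drugs",
    measurement = "measurements",
    word = "sentences"
  )
}
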
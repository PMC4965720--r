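#' Configuration for the synthetic care-episode generator
#'
#' The generator emulates the structure of heterogeneous EHR data at desk
#' scale. Each episode is drawn from a latent clinical state with its own
#' categorical distributions over latent "meanings" for each of the four data
#' types; an emission picks a meaning and then one of the episode's admissible
#' surface tokens for that meaning. Admissible tokens are re-drawn per episode
#' (`variants_per_episode` members of the meaning's synonym cluster),
#' emulating clinician- and coder-specific lexical habits: distinct surface
#' tokens of a cluster share distributional profiles across the corpus —
#' learnable by embeddings — while any individual surface token appears in at
#' most `variants_per_episode / synonym_cluster_size` of the episodes
#' expressing its meaning, which starves per-token count features.
#' ADE-positive episodes additionally enter a hidden ADE state that inserts
#' the target diagnosis code and shifts emissions of all four streams toward
#' the code's own emission profile with strength `signal_strength`.
#'
#' @param n_patients number of patients
#' @param episodes_per_patient inclusive range, episodes drawn per patient
#' @param vocab_sizes named sizes of the four surface vocabularies
#' @param n_latent_states number of non-ADE latent clinical states
#' @param synonym_cluster_size surface tokens per latent meaning; a single
#'   number or a named per-type vector
#' @param variants_per_episode cluster members admissible within one episode
#' @param sentences_per_episode,words_per_sentence inclusive ranges for notes
#' @param events_per_episode named list of inclusive ranges for the three
#'   structured streams
#' @param episode_span_days inclusive range of an episode's day span
#' @param ade_codes reserved target diagnosis tokens (never members of any
#'   synonym cluster); one is assigned per positive episode
#' @param signal_strength in \[0, 1\]: 0 = positives are distributionally
#'   identical to negatives apart from the (leakage-removed) target code,
#'   1 = positives emit purely from the ADE profile
#' @param ade_prevalence overall probability that an episode is ADE-positive
#' @param n_pos_range inclusive range of positives per benchmark dataset
#' @param seed integer seed
#' @return a list of class `synth_config`
#' @export
synth_config <- function(n_patients = 300,
                         episodes_per_patient = c(1, 3),
                         vocab_sizes = c(word = 400, diagnosis = 60,
                                         drug = 40, measurement = 30),
                         n_latent_states = 4,
                         synonym_cluster_size = c(word = 20, diagnosis = 10,
                                                  drug = 8, measurement = 6),
                         variants_per_episode = 2,
                         sentences_per_episode = c(4, 8),
                         words_per_sentence = c(8, 15),
                         events_per_episode = list(diagnosis = c(4, 10),
                                                   drug = c(3, 8),
                                                   measurement = c(3, 8)),
                         episode_span_days = c(1, 10),
                         ade_codes = "ADE01",
                         signal_strength = 0.9,
                         ade_prevalence = 0.3,
                         n_pos_range = c(25, 40),
                         seed = 1) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            ade_prevalence > 0, ade_prevalence < 1,
            n_latent_states >= 1, all(synonym_cluster_size >= 1),
            variants_per_episode >= 1)
  if (length(synonym_cluster_size) == 1) {
    synonym_cluster_size <- stats::setNames(rep(synonym_cluster_size, 4),
                                            DATA_TYPES)
  }
  if (!all(DATA_TYPES %in% names(synonym_cluster_size))) {
    stop("synonym_cluster_size must name all four data types", call. = FALSE)
  }
  n_meanings <- floor(vocab_sizes[DATA_TYPES] /
                        synonym_cluster_size[DATA_TYPES])
  if (any(n_meanings < 2)) {
    stop("infeasible config: vocab sizes ", paste(vocab_sizes, collapse = "/"),
         " cannot be partitioned into at least 2 synonym clusters of size ",
         paste(synonym_cluster_size, collapse = "/"), call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, episodes_per_patient = episodes_per_patient,
         vocab_sizes = vocab_sizes, n_latent_states = n_latent_states,
         synonym_cluster_size = synonym_cluster_size,
         variants_per_episode = as.integer(variants_per_episode),
         sentences_per_episode = sentences_per_episode,
         words_per_sentence = words_per_sentence,
         events_per_episode = events_per_episode,
         episode_span_days = episode_span_days,
         ade_codes = as.character(ade_codes),
         signal_strength = signal_strength, ade_prevalence = ade_prevalence,
         n_pos_range = n_pos_range, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# Surface vocabularies, partitioned into synonym clusters per data type.
synth_vocab <- function(config) {
  prefixes <- c(word = "w", diagnosis = "Dg", drug = "Rx", measurement = "Mx")
  purrr::imap(prefixes, function(pfx, dt) {
    size <- config$vocab_sizes[[dt]]
    cs <- config$synonym_cluster_size[[dt]]
    n_meanings <- floor(size / cs)
    tokens <- sprintf("%s%03d", pfx, seq_len(n_meanings * cs))
    list(tokens = tokens, cluster = rep(seq_len(n_meanings), each = cs),
         cluster_size = cs, n_meanings = n_meanings)
  })
}

# Sparse categorical distribution over meanings (gamma-normalized Dirichlet
# draw); low concentration makes each state/profile prefer a few meanings.
rcat_profile <- function(n, concentration = 0.25) {
  w <- stats::rgamma(n, shape = concentration) + 1e-8
  w / sum(w)
}

# The full generative parameter set (the manifest ground truth).
synth_params <- function(config) {
  vocab <- synth_vocab(config)
  states <- purrr::map(seq_len(config$n_latent_states), function(k) {
    purrr::map(vocab, function(v) rcat_profile(v$n_meanings))
  })
  ade_profiles <- purrr::map(config$ade_codes, function(code) {
    purrr::map(vocab, function(v) rcat_profile(v$n_meanings))
  })
  names(ade_profiles) <- config$ade_codes
  list(vocab = vocab, states = states, ade_profiles = ade_profiles)
}

rint <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

# Draw n tokens: a latent meaning per token, then one of the episode's
# admissible surface variants of that meaning (columns of `variants`).
emit_tokens <- function(n, probs, vocab_entry, variants) {
  meanings <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  pick <- sample.int(ncol(variants), n, replace = TRUE)
  member <- variants[cbind(meanings, pick)]
  vocab_entry$tokens[(meanings - 1L) * vocab_entry$cluster_size + member]
}

#' Generate a synthetic care-episode corpus
#'
#' Draws episodes from the latent-state emission model described in
#' [synth_config()]. Every emitted episode carries all four data types (so the
#' whole corpus passes [retain_complete_episodes()]); structured events get
#' sorted day stamps within the episode span; words are grouped into
#' sentences. Positive episodes carry their target code in the diagnosis
#' stream. Fully reproducible under the config seed.
#'
#' @param config a [synth_config()]
#' @return an `ade_corpus` tibble with an extra `ade_code` column (`NA` for
#'   negatives) recording the generator's ground truth
#' @export
generate_corpus <- function(config) {
  withr::with_seed(config$seed, {
    params <- synth_params(config)
    rows <- list()
    for (p in seq_len(config$n_patients)) {
      n_ep <- rint(config$episodes_per_patient)
      for (e in seq_len(n_ep)) {
        state <- params$states[[sample.int(config$n_latent_states, 1)]]
        is_pos <- stats::runif(1) < config$ade_prevalence
        ade_code <- NA_character_
        if (is_pos) {
          ade_code <- config$ade_codes[sample.int(length(config$ade_codes), 1)]
          prof <- params$ade_profiles[[ade_code]]
          sig <- config$signal_strength
          state <- purrr::map2(state, prof, function(s, a) (1 - sig) * s + sig * a)
        }
        # the episode's lexical habit: admissible variants per meaning
        variants <- purrr::map(params$vocab, function(v) {
          matrix(sample.int(v$cluster_size,
                            v$n_meanings * config$variants_per_episode,
                            replace = TRUE),
                 ncol = config$variants_per_episode)
        })
        span <- rint(config$episode_span_days)
        draw_stream <- function(dt) {
          n_ev <- rint(config$events_per_episode[[dt]])
          toks <- emit_tokens(n_ev, state[[dt]], params$vocab[[dt]],
                              variants[[dt]])
          days <- sort(sample.int(span, n_ev, replace = TRUE)) - 1L
          tibble::tibble(code = toks, day = days)
        }
        diagnoses <- draw_stream("diagnosis")
        if (is_pos) {
          at <- sample.int(span, 1) - 1L
          diagnoses <- dplyr::arrange(
            dplyr::bind_rows(diagnoses, tibble::tibble(code = ade_code, day = at)),
            .data$day
          )
        }
        n_sent <- rint(config$sentences_per_episode)
        sentences <- purrr::map(seq_len(n_sent), function(s) {
          emit_tokens(rint(config$words_per_sentence), state$word,
                      params$vocab$word, variants$word)
        })
        rows[[length(rows) + 1]] <- list(
          patient_id = sprintf("P%04d", p),
          episode_id = sprintf("P%04d-E%d", p, e),
          sentences = sentences,
          diagnoses = diagnoses,
          drugs = draw_stream("drug"),
          measurements = draw_stream("measurement"),
          ade_code = ade_code
        )
      }
    }
    corpus <- care_corpus(
      patient_id = purrr::map_chr(rows, "patient_id"),
      episode_id = purrr::map_chr(rows, "episode_id"),
      sentences = purrr::map(rows, "sentences"),
      diagnoses = purrr::map(rows, "diagnoses"),
      drugs = purrr::map(rows, "drugs"),
      measurements = purrr::map(rows, "measurements")
    )
    corpus$ade_code <- purrr::map_chr(rows, "ade_code")
    corpus
  })
}

episode_has_code <- function(corpus, code) {
  purrr::map_lgl(corpus$diagnoses, function(d) code %in% d$code)
}

#' Build a balanced labeled dataset from a corpus
#'
#' Positives are episodes whose diagnosis stream contains `ade_code`;
#' negatives are an equal number of episodes sampled uniformly from those in
#' which the code was never assigned.
#'
#' @param corpus an `ade_corpus`
#' @param ade_code the target diagnosis token
#' @param n_pos positives (= negatives) to sample
#' @param seed integer seed
#' @return an `ade_dataset` with shuffled rows
#' @export
generate_ade_dataset <- function(corpus, ade_code, n_pos, seed = 1) {
  has <- episode_has_code(corpus, ade_code)
  if (sum(has) < n_pos || sum(!has) < n_pos) {
    stop("need ", n_pos, " episodes of each class; corpus has ", sum(has),
         " with and ", sum(!has), " without code ", ade_code, call. = FALSE)
  }
  withr::with_seed(seed, {
    pos <- sample(which(has), n_pos)
    neg <- sample(which(!has), n_pos)
    idx <- sample(c(pos, neg))
  })
  labeled_dataset(corpus[idx, , drop = FALSE], as.integer(idx %in% pos),
                  ade_code)
}

#' Generate a multi-dataset benchmark from one shared background corpus
#'
#' Emulates the design of many balanced ADE datasets drawn from a single EHR
#' corpus: `n_datasets` distinct target codes, dataset sizes varied across
#' `config$n_pos_range` (capped by availability).
#'
#' @param config a [synth_config()]; its `ade_codes` are replaced by
#'   `n_datasets` fresh codes
#' @param n_datasets number of datasets
#' @param seed master seed (overrides `config$seed`)
#' @return list of class `ade_benchmark` with elements `corpus` (the shared
#'   background corpus) and `datasets` (list of `ade_dataset`)
#' @export
make_benchmark <- function(config, n_datasets = 5, seed = config$seed) {
  stopifnot(n_datasets >= 1)
  config$ade_codes <- sprintf("ADE%02d", seq_len(n_datasets))
  config$seed <- as.integer(seed)
  corpus <- generate_corpus(config)
  ds_seeds <- derive_seeds(seed, n_datasets * 2)
  datasets <- purrr::imap(config$ade_codes, function(code, j) {
    avail <- min(sum(episode_has_code(corpus, code)),
                 sum(!episode_has_code(corpus, code)))
    want <- withr::with_seed(ds_seeds[2 * j - 1], rint(config$n_pos_range))
    n_pos <- min(want, avail)
    if (n_pos < 10) {
      stop("dataset ", code, ": only ", avail,
           " positives available; increase corpus size or prevalence",
           call. = FALSE)
    }
    generate_ade_dataset(corpus, code, n_pos, seed = ds_seeds[2 * j])
  })
  structure(list(corpus = corpus, datasets = datasets),
            class = "ade_benchmark")
}

#' @export
print.ade_benchmark <- function(x, ...) {
  cat("<ade_benchmark> ", length(x$datasets), " datasets over a corpus of ",
      nrow(x$corpus), " episodes\n", sep = "")
  invisible(x)
}
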
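#' Build a care-episode corpus tibble
#'
#' A corpus is a tibble with one row per care episode. Structured event
#' streams (`diagnoses`, `drugs`, `measurements`) are list-columns of tibbles
#' with columns `code` (token) and `day` (non-negative integer, sorted
#' non-decreasing); `sentences` is a list-column of lists of character vectors,
#' one vector per sentence of the episode's notes. Measurement values are not
#' represented: measurements enter as types only.
#'
#' @param patient_id,episode_id character vectors, one entry per episode
#' @param sentences list of lists of character vectors
#' @param diagnoses,drugs,measurements lists of data frames with columns
#'   `code`, `day`
#' @return a tibble of class `ade_corpus`
#' @export
care_corpus <- function(patient_id, episode_id, sentences,
                        diagnoses, drugs, measurements) {
  corpus <- tibble::tibble(
    patient_id = as.character(patient_id),
    episode_id = as.character(episode_id),
    sentences = as.list(sentences),
    diagnoses = lapply(diagnoses, as_event_stream),
    drugs = lapply(drugs, as_event_stream),
    measurements = lapply(measurements, as_event_stream)
  )
  validate_corpus(corpus)
}

as_event_stream <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0) || length(x) == 0) {
    return(tibble::tibble(code = character(), day = integer()))
  }
  x <- tibble::as_tibble(x)
  tibble::tibble(code = as.character(x$code), day = as.integer(x$day))
}

validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  needed <- c("patient_id", "episode_id", "sentences",
              "diagnoses", "drugs", "measurements")
  missing <- setdiff(needed, names(corpus))
  if (length(missing) > 0) {
    stop("corpus is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("diagnoses", "drugs", "measurements")) {
    for (i in seq_len(nrow(corpus))) {
      ev <- corpus[[col]][[i]]
      if (nrow(ev) > 0) {
        if (any(!nzchar(ev$code)) || any(grepl("\\s", ev$code))) {
          stop("episode ", corpus$episode_id[i], ": ", col,
               " codes must be non-empty and whitespace-free", call. = FALSE)
        }
        if (any(ev$day < 0)) {
          stop("episode ", corpus$episode_id[i], ": negative day in ", col,
               call. = FALSE)
        }
        if (is.unsorted(ev$day)) {
          stop("episode ", corpus$episode_id[i], ": ", col,
               " not sorted by day", call. = FALSE)
        }
      }
    }
  }
  class(corpus) <- unique(c("ade_corpus", class(corpus)))
  corpus
}

#' Segment one patient's event record into care episodes
#'
#' A care episode is delimited by at least three days without any registered
#' activity: consecutive events stay in the same episode when fewer than three
#' whole inactive days separate them, i.e. the record is split between events
#' at days d1 < d2 exactly when d2 - d1 >= `gap_days` + 1 (default split at a
#' gap of 4, leaving days d1+1..d2-1 >= 3 inactive days).
#'
#' @param events data frame with columns `code`, `day`, sorted by `day`
#' @param gap_days minimum number of whole inactive days that ends an episode
#' @return list of event data frames, one per episode, order preserved
#' @export
segment_care_episodes <- function(events, gap_days = 3) {
  events <- as_event_stream(events)
  if (nrow(events) == 0) return(list())
  if (is.unsorted(events$day)) stop("events must be sorted by day", call. = FALSE)
  gaps <- diff(events$day)
  # gap in inactive days between events at d1 < d2 is d2 - d1 - 1
  breaks <- which(gaps - 1 >= gap_days)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nrow(events))
  purrr::map2(starts, ends, function(s, e) events[s:e, , drop = FALSE])
}

#' Keep only care episodes carrying all four data types
#'
#' Episodes missing any of words, diagnoses, drugs or measurements are dropped;
#' order is preserved.
#'
#' @param corpus an `ade_corpus` tibble
#' @return the filtered corpus
#' @export
retain_complete_episodes <- function(corpus) {
  keep <- purrr::pmap_lgl(
    list(corpus$sentences, corpus$diagnoses, corpus$drugs, corpus$measurements),
    function(sent, dg, dr, ms) {
      length(sent) > 0 && sum(lengths(sent)) > 0 &&
        nrow(dg) > 0 && nrow(dr) > 0 && nrow(ms) > 0
    }
  )
  corpus[keep, , drop = FALSE]
}

#' Extract training sequences for one data type
#'
#' Structured data types yield one time-ordered token sequence per episode
#' (stable within-day order = input order); words yield one sequence per
#' sentence. For diagnosis sequences an `exclude_code` (the target ADE code)
#' may be removed so that representation learning never sees the label-defining
#' token.
#'
#' @param corpus an `ade_corpus` tibble
#' @param data_type one of `"word"`, `"diagnosis"`, `"drug"`, `"measurement"`
#' @param exclude_code optional diagnosis token to delete from every sequence
#' @return an object of class `sequence_set`: list with `data_type` and
#'   `sequences` (list of character vectors)
#' @export
extract_sequences <- function(corpus, data_type, exclude_code = NULL) {
  data_type <- match_data_type(data_type)
  if (!is.null(exclude_code) && data_type != "diagnosis") {
    stop("exclude_code only applies to diagnosis sequences", call. = FALSE)
  }
  if (data_type == "word") {
    seqs <- purrr::flatten(corpus$sentences)
    seqs <- purrr::map(seqs, as.character)
  } else {
    col <- stream_column(data_type)
    seqs <- purrr::map(corpus[[col]], function(ev) {
      # event streams are stored day-sorted; keep stable input order within day
      ev$code
    })
    if (!is.null(exclude_code)) {
      seqs <- purrr::map(seqs, function(s) s[s != exclude_code])
    }
  }
  seqs <- seqs[lengths(seqs) > 0]
  structure(list(data_type = data_type, sequences = seqs),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("<sequence_set> ", x$data_type, ": ", length(x$sequences),
      " sequences, ", sum(lengths(x$sequences)), " tokens\n", sep = "")
  invisible(x)
}

#' Read and write a care-episode corpus as JSON Lines
#'
#' One episode per line with keys `patient_id`, `episode_id`, `sentences`
#' (array of token arrays), `diagnoses`, `drugs`, `measurements` (arrays of
#' `{code, day}` objects). Writing then reading reproduces every field.
#'
#' @param path file path
#' @return `read_corpus()` returns an `ade_corpus` tibble
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(care_corpus(character(), character(), list(), list(), list(), list()))
  }
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = FALSE),
      error = function(e) stop("line ", i, ": malformed JSON record: ",
                               conditionMessage(e), call. = FALSE)
    )
    for (field in c("patient_id", "episode_id", "sentences",
                    "diagnoses", "drugs", "measurements")) {
      if (is.null(rec[[field]])) {
        stop("line ", i, ": missing field '", field, "'", call. = FALSE)
      }
    }
    rec
  })
  stream <- function(rec, field) {
    evs <- rec[[field]]
    tibble::tibble(
      code = purrr::map_chr(evs, function(e) as.character(e$code)),
      day = purrr::map_int(evs, function(e) as.integer(e$day))
    )
  }
  care_corpus(
    patient_id = purrr::map_chr(recs, "patient_id"),
    episode_id = purrr::map_chr(recs, "episode_id"),
    sentences = purrr::map(recs, function(r)
      purrr::map(r$sentences, function(s) as.character(unlist(s)))),
    diagnoses = purrr::map(recs, stream, field = "diagnoses"),
    drugs = purrr::map(recs, stream, field = "drugs"),
    measurements = purrr::map(recs, stream, field = "measurements")
  )
}

#' @rdname read_corpus
#' @param corpus an `ade_corpus` tibble
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    rec <- list(
      patient_id = corpus$patient_id[i],
      episode_id = corpus$episode_id[i],
      sentences = corpus$sentences[[i]],
      diagnoses = stream_records(corpus$diagnoses[[i]]),
      drugs = stream_records(corpus$drugs[[i]]),
      measurements = stream_records(corpus$measurements[[i]])
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

stream_records <- function(ev) {
  purrr::map2(ev$code, ev$day, function(c, d) list(code = c, day = d))
}
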
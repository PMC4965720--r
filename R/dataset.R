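#' Construct a labeled ADE dataset
#'
#' Bundles care episodes with binary labels (1 = the target ADE diagnosis code
#' was assigned within the episode) and records the target code so that every
#' downstream featurization can remove it from the feature-visible diagnosis
#' stream (leakage removal).
#'
#' @param episodes an `ade_corpus` tibble
#' @param labels integer/logical vector, one per episode
#' @param target_code the diagnosis token defining the positive class
#' @param name optional dataset identifier
#' @return a list of class `ade_dataset`
#' @export
labeled_dataset <- function(episodes, labels, target_code, name = target_code) {
  labels <- as.integer(labels)
  if (nrow(episodes) != length(labels)) {
    stop("episodes (", nrow(episodes), ") and labels (", length(labels),
         ") differ in length", call. = FALSE)
  }
  stopifnot(all(labels %in% c(0L, 1L)))
  structure(
    list(episodes = episodes, labels = labels,
         target_code = as.character(target_code), name = name),
    class = "ade_dataset"
  )
}

#' @export
print.ade_dataset <- function(x, ...) {
  cat("<ade_dataset> '", x$name, "': ", nrow(x$episodes), " episodes (",
      sum(x$labels), " positive), target code ", x$target_code, "\n", sep = "")
  invisible(x)
}

# Row-subset a dataset (used for folds and bootstrap-free splits); balance is
# not re-imposed on subsets.
dataset_slice <- function(dataset, idx) {
  labeled_dataset(dataset$episodes[idx, , drop = FALSE], dataset$labels[idx],
                  dataset$target_code, name = dataset$name)
}
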
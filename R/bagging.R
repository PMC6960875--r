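# Bagged DTW classifier: one "weak" DTW template classifier per training
# subject, combined by plurality voting. Partitioning by subject keeps each
# member's templates free of cross-subject averaging, so user-specific
# movement styles survive into the ensemble.

#' Train a per-subject bagged DTW classifier
#'
#' For every training subject, fits a full set of class templates
#' ([dba_template()]) from that subject's recordings only. Every subject
#' must contribute at least one recording of every class.
#'
#' @param dataset A list of labeled [orientation_sequence] objects with
#'   subject ids.
#' @param max_iter,tol Passed to [dba_template()].
#' @return A `dtw_bagged` model: list with `members`, a named list
#'   (subject -> `dtw_model`).
#' @export
train_dtw_bagged <- function(dataset, max_iter = 10L, tol = 1e-4) {
  subjects <- dataset_subjects(dataset)
  labels <- dataset_labels(dataset)
  classes <- sort(unique(labels))
  subj_ids <- sort(unique(subjects))
  members <- lapply(subj_ids, function(sb) {
    keep <- subjects == sb
    missing <- setdiff(classes, unique(labels[keep]))
    if (length(missing))
      stop(sprintf("subject %s has no recordings of class(es): %s",
                   sb, paste(missing, collapse = ", ")))
    train_dtw(dataset[keep], max_iter = max_iter, tol = tol)
  })
  names(members) <- subj_ids
  structure(list(members = members), class = "dtw_bagged")
}

#' Classify by majority vote of per-subject DTW members
#'
#' Each member classifies the recording independently; the plurality label
#' wins. Ties are broken by the smallest mean normalized DTW distance to
#' the tied class among the members that voted for it (a deterministic
#' rule reusing the distances the members already computed).
#'
#' @param seq An [orientation_sequence].
#' @param model A `dtw_bagged` model.
#' @return List with `label`, `tally` (votes per label), and `votes`
#'   (per-member label).
#' @export
vote_bagged <- function(seq, model) {
  if (!inherits(model, "dtw_bagged") || length(model$members) < 1L)
    stop("'model' must be a non-empty dtw_bagged model")
  results <- lapply(model$members, function(m) classify_dtw(seq, m))
  votes <- vapply(results, function(r) r$label, character(1))
  tally <- table(votes)
  top <- names(tally)[tally == max(tally)]
  if (length(top) > 1L) {
    mean_dist <- vapply(top, function(lb) {
      mean(vapply(results[votes == lb], function(r) r$distances[[lb]], numeric(1)))
    }, numeric(1))
    top <- top[order(mean_dist, top)][1L]
  }
  list(label = top, tally = tally, votes = votes)
}

#' @export
predict.dtw_bagged <- function(object, newdata, ...) {
  if (inherits(newdata, "orientation_sequence"))
    return(vote_bagged(newdata, object)$label)
  vapply(newdata, function(s) vote_bagged(s, object)$label, character(1))
}

#' @export
print.dtw_bagged <- function(x, ...) {
  cat(sprintf("<dtw_bagged> %d members x %d classes\n", length(x$members),
              length(x$members[[1L]]$templates)))
  invisible(x)
}
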
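# A gesture dataset is a plain list of labeled orientation_sequence
# objects, each carrying $subject and $label.

#' Subject ids of a dataset
#' @param dataset List of [orientation_sequence] objects.
#' @return Character vector, one subject id per recording.
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset, function(s) {
    if (is.null(s$subject)) stop("recording without a subject id")
    s$subject
  }, character(1))
}

#' Class labels of a dataset
#' @param dataset List of [orientation_sequence] objects.
#' @return Character vector, one gesture-class label per recording.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(s) {
    if (is.null(s$label)) stop("recording without a class label")
    s$label
  }, character(1))
}

#' Per-subject, per-class recording counts
#' @param dataset List of labeled [orientation_sequence] objects.
#' @return A subject x class contingency table.
#' @export
dataset_summary <- function(dataset) {
  table(subject = dataset_subjects(dataset), class = dataset_labels(dataset))
}
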
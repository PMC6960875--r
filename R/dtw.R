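# DTW distances (quaternion and Euclidean local costs), template
# classification, and DBA template training with Markley averaging.

#' Quaternion DTW local cost
#'
#' `cost(q1, q2) = 1 - |q1 . q2|` where `.` is the 4-D dot product. The
#' absolute value makes the cost blind to the quaternion sign ambiguity
#' (`q` and `-q` encode the same rotation); identical rotations cost 0,
#' orthogonal quaternions cost 1.
#'
#' @param q1,q2 Unit quaternions `c(x, y, z, w)`.
#' @return Cost in `[0, 1]`.
#' @export
quaternion_cost <- function(q1, q2) {
  1 - abs(sum(q1 * q2))
}

#' Normalized dynamic time warping distance
#'
#' Standard DTW dynamic program with steps \{(1,0), (0,1), (1,1)\}. The
#' reported distance is the minimal accumulated path cost divided by the
#' warping-path length, which makes distances comparable across templates
#' of different lengths. `cost = "quaternion"` uses [quaternion_cost()] on
#' rows of n x 4 quaternion matrices; `cost = "euclidean"` uses the
#' Euclidean distance between rows (e.g. n x 3 spatial trajectories).
#'
#' @param a,b Numeric matrices (samples in rows) with matching column
#'   counts, or [orientation_sequence] objects (their quaternion matrices
#'   are used).
#' @param cost `"euclidean"` or `"quaternion"`.
#' @param return_path If `TRUE`, also return the warping path as a 2-column
#'   matrix of 1-based index pairs from `(1, 1)` to `(nrow(a), nrow(b))`.
#' @return A list with `distance` (normalized), `cost` (accumulated),
#'   `path_length`, and optionally `path`.
#' @export
dtw_distance <- function(a, b, cost = c("euclidean", "quaternion"),
                         return_path = FALSE) {
  cost <- match.arg(cost)
  a <- .seq_matrix(a); b <- .seq_matrix(b)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("DTW requires non-empty sequences")
  cpp_dtw(a, b, if (cost == "quaternion") 1L else 0L, return_path)
}

.seq_matrix <- function(x) {
  if (inherits(x, "orientation_sequence")) return(x$q)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  as.matrix(x)
}

#' Train a gesture template by quaternion-aware DTW barycenter averaging
#'
#' DBA adapted to unit-quaternion series: the template is initialized as
#' the medoid recording (minimal summed quaternion-cost DTW distance to
#' the others); each iteration aligns every recording to the template with
#' quaternion-cost DTW and replaces each template sample by the Markley
#' eigen-average ([quat_markley_mean()]) of the quaternions matched to it.
#' Iteration stops after `max_iter` averaging updates, when the relative
#' decrease of the objective (summed normalized DTW distance of the class
#' recordings to the template) falls below `tol`, or when an update fails
#' to decrease the objective (the update is then reverted), so the recorded
#' `objective_trace` is non-increasing.
#'
#' @param recordings Non-empty list of [orientation_sequence] objects of
#'   one gesture class.
#' @param label Class label stored on the template (defaults to the first
#'   recording's label).
#' @param max_iter Maximum number of averaging updates (default 10).
#' @param tol Relative objective-change tolerance (default 1e-4).
#' @return A `gesture_template`: list with `label`, `quat_template` (n x 4),
#'   `spatial_template` (n x 3, via the head-direction map), and
#'   `objective_trace`.
#' @export
dba_template <- function(recordings, label = NULL, max_iter = 10L, tol = 1e-4) {
  if (!is.list(recordings) || length(recordings) < 1L)
    stop("'recordings' must be a non-empty list of orientation sequences")
  mats <- lapply(recordings, .seq_matrix)
  if (is.null(label)) label <- recordings[[1L]]$label
  if (length(mats) == 1L) {
    return(.new_template(label, mats[[1L]], objective_trace = 0))
  }

  pair <- cpp_dtw_pairwise(mats, 1L)
  template <- mats[[which.min(rowSums(pair))]]

  objective_trace <- numeric(0)
  obj_prev <- Inf
  template_prev <- template
  iter <- 0L
  repeat {
    aligns <- lapply(mats, function(m) cpp_dtw(template, m, 1L, TRUE))
    obj <- sum(vapply(aligns, function(a) a$distance, numeric(1)))
    if (obj > obj_prev) {        # descent guard: revert and stop
      template <- template_prev
      break
    }
    objective_trace <- c(objective_trace, obj)
    if (iter >= max_iter || obj_prev - obj < tol * max(obj_prev, .Machine$double.eps))
      break
    template_prev <- template
    template <- .dba_update(template, mats, aligns)
    obj_prev <- obj
    iter <- iter + 1L
  }
  .new_template(label, template, objective_trace)
}

# One DBA averaging step: group the recording quaternions matched to each
# template row by the warping paths, Markley-average each group. The outer
# products q q^T of all matched quaternions are accumulated per template
# row with rowsum() (10 unique entries of the symmetric 4x4 matrix), so
# only one small eigen problem per template row remains.
.dba_update <- function(template, mats, aligns) {
  n <- nrow(template)
  idx <- do.call(c, lapply(aligns, function(a) a$path[, 1L]))
  Q <- do.call(rbind, lapply(seq_along(mats), function(r)
    mats[[r]][aligns[[r]]$path[, 2L], , drop = FALSE]))
  upper <- cbind(Q[, 1L] * Q, Q[, 2L] * Q[, 2:4], Q[, 3L] * Q[, 3:4],
                 Q[, 4L] * Q[, 4L])
  M10 <- rowsum(upper, idx)                     # n x 10, rows ordered by index
  pos <- as.integer(rownames(M10))
  out <- template
  ut <- upper.tri(matrix(0, 4, 4), diag = TRUE)
  for (k in seq_along(pos)) {
    M <- matrix(0, 4, 4)
    M[ut] <- M10[k, c(1L, 2L, 5L, 3L, 6L, 8L, 4L, 7L, 9L, 10L)]
    M <- M + t(M) - diag(diag(M))
    v <- eigen(M, symmetric = TRUE)$vectors[, 1L]
    out[pos[k], ] <- .quat_fix_sign(v / sqrt(sum(v^2)))
  }
  out
}

.new_template <- function(label, quat_template, objective_trace) {
  colnames(quat_template) <- c("x", "y", "z", "w")
  structure(list(label = label,
                 quat_template = quat_template,
                 spatial_template = spatial_representation(quat_template),
                 objective_trace = as.numeric(objective_trace)),
            class = "gesture_template")
}

#' @export
print.gesture_template <- function(x, ...) {
  cat(sprintf("<gesture_template> class %s, %d samples, final objective %.4g\n",
              x$label %||% "?", nrow(x$quat_template),
              if (length(x$objective_trace)) x$objective_trace[length(x$objective_trace)] else NA))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a DTW template classifier
#'
#' Fits one DBA template per gesture class (classes in sorted label order).
#'
#' @param dataset A list of labeled [orientation_sequence] objects.
#' @param max_iter,tol Passed to [dba_template()].
#' @return A `dtw_model`: list of `gesture_template`s named by class.
#' @export
train_dtw <- function(dataset, max_iter = 10L, tol = 1e-4) {
  labels <- dataset_labels(dataset)
  classes <- sort(unique(labels))
  templates <- lapply(classes, function(cl) {
    dba_template(dataset[labels == cl], label = cl,
                 max_iter = max_iter, tol = tol)
  })
  names(templates) <- classes
  structure(list(templates = templates), class = "dtw_model")
}

#' Classify a recording against gesture templates
#'
#' Converts the recording to its spatial representation (head-direction
#' trajectory) and computes the normalized Euclidean-cost DTW distance to
#' each template's spatial template; the predicted class is the argmin.
#' Ties are broken by template order (first listed wins).
#'
#' @param seq An [orientation_sequence].
#' @param templates A list of `gesture_template`s or a `dtw_model`.
#' @return List with `label` and `distances` (named per class).
#' @export
classify_dtw <- function(seq, templates) {
  if (inherits(templates, "dtw_model")) templates <- templates$templates
  if (length(templates) < 1L) stop("no templates to classify against")
  v <- spatial_representation(seq)
  spat <- lapply(templates, function(tp) tp$spatial_template)
  d <- as.numeric(cpp_dtw_to_templates(v, spat, 0L))
  labs <- vapply(templates, function(tp) tp$label, character(1))
  names(d) <- labs
  list(label = unname(labs[which.min(d)]), distances = d)
}

#' @export
predict.dtw_model <- function(object, newdata, ...) {
  if (inherits(newdata, "orientation_sequence"))
    return(classify_dtw(newdata, object)$label)
  vapply(newdata, function(s) classify_dtw(s, object)$label, character(1))
}
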
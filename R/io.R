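# Readers/writers for the recording CSV format, the dataset directory
# layout <root>/<subject>/<class>/<name>.csv, and JSON model serialization.
#
# Recording CSV dialects (header names are mandatory):
#   quaternion: timestamp_ms, x, y, z, w        (component order x,y,z,w!)
#   euler:      timestamp_ms, yaw_deg, pitch_deg, roll_deg
# Euler rows are converted on load using the intrinsic yaw (vertical axis),
# pitch (lateral axis, positive up), roll (forward axis) convention that
# direction_to_quaternion() uses for the zero-roll case.

#' Read a recording CSV
#'
#' Validates that timestamps are strictly increasing and that no quaternion
#' row has zero norm; rows deviating from unit norm by more than 1e-3 are
#' normalized with a warning (all rows are normalized on load).
#'
#' @param path CSV file path.
#' @param dialect `"quaternion"` or `"euler"`.
#' @param subject,label Optional metadata stored on the sequence.
#' @return An [orientation_sequence].
#' @export
read_recording <- function(path, dialect = c("quaternion", "euler"),
                           subject = NULL, label = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path)
  need <- if (dialect == "quaternion") c("timestamp_ms", "x", "y", "z", "w")
          else c("timestamp_ms", "yaw_deg", "pitch_deg", "roll_deg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  tt <- as.numeric(df$timestamp_ms)
  bad <- which(diff(tt) <= 0)
  if (length(bad))
    stop(sprintf("%s: timestamps not strictly increasing at row %d", path, bad[1L] + 1L))
  if (dialect == "euler") {
    q <- euler_to_quaternion(df$yaw_deg, df$pitch_deg, df$roll_deg)
  } else {
    q <- as.matrix(df[, c("x", "y", "z", "w")])
    norms <- sqrt(rowSums(q^2))
    zero <- which(norms <= 0)
    if (length(zero))
      stop(sprintf("%s: zero-norm quaternion at row %d", path, zero[1L]))
    off <- sum(abs(norms - 1) > 1e-4)
    if (off > 0)
      warning(sprintf("%s: %d row(s) deviate from unit norm by > 1e-4; normalized on load",
                      path, off))
  }
  orientation_sequence(q, t = tt, subject = subject, label = label)
}

#' Write a recording CSV (quaternion dialect)
#'
#' @param seq An [orientation_sequence]; if it has no timestamps, integer
#'   sample indices in ms are written.
#' @param path Output file path.
#' @export
write_recording <- function(seq, path) {
  seq <- as_orientation_sequence(seq)
  tt <- seq$t %||% (seq_len(nrow(seq$q)) - 1)
  df <- data.frame(timestamp_ms = tt, x = seq$q[, 1L], y = seq$q[, 2L],
                   z = seq$q[, 3L], w = seq$q[, 4L])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert intrinsic Euler angles to quaternions
#'
#' Composes yaw (vertical axis), then pitch (lateral axis, positive up),
#' then roll (forward axis): `R = R_yaw R_pitch R_roll` acting on the
#' reference direction `[0, 0, 1]`.
#'
#' @param yaw,pitch,roll Angles in degrees (equal-length vectors).
#' @return An n x 4 quaternion matrix.
#' @export
euler_to_quaternion <- function(yaw, pitch, roll = 0) {
  n <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(yaw, n); pitch <- rep_len(pitch, n); roll <- rep_len(roll, n)
  Q <- matrix(0, n, 4L, dimnames = list(NULL, c("x", "y", "z", "w")))
  for (i in seq_len(n)) {
    r2 <- roll[i] * pi / 360
    qroll <- c(0, 0, sin(r2), cos(r2))
    qyp <- direction_to_quaternion(yaw[i], pitch[i])
    # R(q) = R(qyp) R(qroll): with the printed product this is qroll . qyp
    Q[i, ] <- quat_multiply(qroll, qyp)
  }
  Q
}

#' Write a dataset to the directory layout
#'
#' Layout: `<root>/<subject>/<class>/<subject>_<class>_<rep>.csv`.
#'
#' @param dataset List of labeled [orientation_sequence] objects.
#' @param root Output directory (created if absent).
#' @return `root`, invisibly.
#' @export
write_dataset <- function(dataset, root) {
  counts <- new.env(parent = emptyenv())
  for (s in dataset) {
    if (is.null(s$subject) || is.null(s$label))
      stop("every recording needs subject and label metadata to be written")
    dir <- file.path(root, s$subject, s$label)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    key <- paste(s$subject, s$label, sep = "/")
    k <- (get0(key, envir = counts) %||% 0L) + 1L
    assign(key, k, envir = counts)
    write_recording(s, file.path(dir, sprintf("%s_%s_%03d.csv", s$subject, s$label, k)))
  }
  invisible(root)
}

#' Load a dataset from the directory layout
#'
#' Walks `<root>/<subject>/<class>/*.csv` in lexicographic order; subject
#' and class labels come from the path components. Non-CSV files are
#' skipped with a warning.
#'
#' @param root Dataset root directory.
#' @param dialect Recording dialect, see [read_recording()].
#' @return A list of labeled [orientation_sequence] objects.
#' @export
load_dataset <- function(root, dialect = "quaternion") {
  if (!dir.exists(root)) stop(sprintf("dataset root '%s' does not exist", root))
  files <- sort(list.files(root, recursive = TRUE, full.names = FALSE))
  if (!length(files)) stop(sprintf("dataset root '%s' is empty", root))
  keep <- grepl("\\.csv$", files, ignore.case = TRUE) &
    lengths(strsplit(files, "/", fixed = TRUE)) == 3L
  if (any(!keep))
    warning(sprintf("skipping %d non-recording file(s) under %s", sum(!keep), root))
  lapply(files[keep], function(f) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1L]]
    read_recording(file.path(root, f), dialect = dialect,
                   subject = parts[1L], label = parts[2L])
  })
}

# --- model serialization ----------------------------------------------------

#' Save a trained model as JSON
#'
#' Supports `dtw_model`, `dtw_bagged`, `pca_model`, and `pca2_model`.
#' Numeric precision is preserved (round-trips within 1e-12).
#'
#' @param model The model object.
#' @param path Output JSON path.
#' @export
save_model <- function(model, path) {
  kind <- intersect(class(model), c("dtw_model", "dtw_bagged", "pca_model", "pca2_model"))
  if (!length(kind)) stop("unsupported model class: ", paste(class(model), collapse = "/"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  payload <- list(kind = kind[1L], model = strip(model))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path JSON path.
#' @return The model object with its class restored.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- payload$kind
  m <- payload$model
  restore_template <- function(tp) {
    tp$quat_template <- .as_mat(tp$quat_template, c("x", "y", "z", "w"))
    tp$spatial_template <- .as_mat(tp$spatial_template, c("vx", "vy", "vz"))
    structure(tp, class = "gesture_template")
  }
  restore_dtw <- function(mm) {
    mm$templates <- lapply(mm$templates, restore_template)
    structure(mm, class = "dtw_model")
  }
  restore_proj <- function(p) {
    p$mean <- as.numeric(p$mean)
    p$eigenvectors <- .as_mat(p$eigenvectors)
    structure(p, class = "feature_projection")
  }
  switch(kind,
    dtw_model = restore_dtw(m),
    dtw_bagged = {
      m$members <- lapply(m$members, restore_dtw)
      structure(m, class = "dtw_bagged")
    },
    pca_model = {
      m$projection <- restore_proj(m$projection)
      m$features <- .as_mat(m$features)
      structure(m, class = "pca_model")
    },
    pca2_model = {
      m$stage1 <- restore_proj(m$stage1)
      m$projection <- restore_proj(m$projection)
      m$features <- .as_mat(m$features)
      structure(m, class = "pca2_model")
    },
    stop("unknown model kind in file: ", kind))
}

.as_mat <- function(x, cols = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(cols)) colnames(x) <- cols else dimnames(x) <- NULL
  x
}

#' Save an evaluation report as JSON
#' @param report A `loso_report`.
#' @param path Output JSON path.
#' @export
save_report <- function(report, path) {
  out <- list(folds = report$folds,
              classes = rownames(report$confusion),
              confusion = unname(as.matrix(report$confusion)),
              per_class_error = as.list(report$per_class_error),
              per_class_recognition = as.list(report$per_class_recognition),
              total_error = report$total_error,
              total_recognition = report$total_recognition)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
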
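# Gesture segmentation from a continuous quaternion stream: threshold the
# median-filtered inter-sample angular velocity and keep long-enough runs.

#' Inter-sample angular velocity of a recording
#'
#' Element `i` is the rotation angle between samples `i` and `i+1`
#' (see [quat_angle()]) converted to degrees, i.e. the angular speed in
#' degrees per sample.
#'
#' @param seq An [orientation_sequence] of length >= 2.
#' @return Numeric vector of length `length(seq) - 1`, in degrees.
#' @export
angular_velocity <- function(seq) {
  seq <- as_orientation_sequence(seq)
  n <- nrow(seq$q)
  if (n < 2L) stop("angular velocity needs at least 2 samples")
  # vectorized pairwise rotation angle: components of q_i * q_{i+1}^-1
  # under the printed product, evaluated in the stable atan2 form (the w
  # component is the 4-D dot product of the two rows)
  x1 <- seq$q[-n, 1L]; y1 <- seq$q[-n, 2L]; z1 <- seq$q[-n, 3L]; w1 <- seq$q[-n, 4L]
  x2 <- seq$q[-1L, 1L]; y2 <- seq$q[-1L, 2L]; z2 <- seq$q[-1L, 3L]; w2 <- seq$q[-1L, 4L]
  x3 <- w2 * x1 - x2 * w1 - y2 * z1 + z2 * y1
  y3 <- w2 * y1 - y2 * w1 - z2 * x1 + x2 * z1
  z3 <- w2 * z1 - z2 * w1 - x2 * y1 + y2 * x1
  w3 <- w2 * w1 + x2 * x1 + y2 * y1 + z2 * z1
  as.numeric(2 * atan2(sqrt(x3^2 + y3^2 + z3^2), abs(w3)) * 180 / pi)
}

#' Running median with truncated windows
#'
#' Replaces every element by the median of the window of width `mk` centered
#' on it. Windows are truncated at the series boundaries (no padding), so
#' the output has the same length as the input.
#'
#' @param x Numeric series.
#' @param mk Odd window width in samples (`mk = 1` is the identity).
#' @return Filtered series, same length as `x`.
#' @export
median_filter <- function(x, mk) {
  if (length(x) < 1L) stop("empty series")
  mk <- as.integer(mk)
  if (is.na(mk) || mk < 1L || mk %% 2L == 0L)
    stop("'mk' must be an odd integer >= 1")
  if (mk == 1L) return(as.numeric(x))
  h <- mk %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Segment gestures from a continuous orientation stream
#'
#' Computes the angular-velocity series ([angular_velocity()]), median-filters
#' it with window `mk`, finds maximal runs where the filtered velocity
#' strictly exceeds `t1` degrees per sample, and discards runs shorter than
#' `t2` samples. Each surviving run of velocity indices `i..j` is reported
#' as the stream segment `[i, j+1]` (1-based, inclusive), covering both
#' quaternions of every above-threshold velocity sample.
#'
#' The defaults `mk = 15`, `t1 = 1`, `t2 = 10` suit acquisition at roughly
#' 45 Hz; other frame rates may need retuning.
#'
#' @param seq An [orientation_sequence].
#' @param mk Odd median-filter window in samples.
#' @param t1 Angular-velocity threshold in degrees per sample (> 0).
#' @param t2 Minimal run length in samples (>= 1).
#' @return A data.frame with integer columns `start` and `end` (1-based,
#'   inclusive sample indices), sorted and non-overlapping; zero rows when
#'   nothing exceeds the threshold or the stream is too short.
#' @export
segment_gestures <- function(seq, mk = 15L, t1 = 1, t2 = 10L) {
  if (!is.numeric(t1) || length(t1) != 1L || t1 <= 0) stop("'t1' must be > 0")
  t2 <- as.integer(t2)
  if (is.na(t2) || t2 < 1L) stop("'t2' must be an integer >= 1")
  seq <- as_orientation_sequence(seq)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (nrow(seq$q) <= t2) return(empty)
  vel <- median_filter(angular_velocity(seq), mk)
  above <- vel > t1
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= t2
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep] + 1L)
}

#' Extract and re-reference segmented recordings
#'
#' Cuts each segment out of the stream and re-references it via
#' [rereference()] so every gesture starts at the identity rotation.
#'
#' @param seq The source [orientation_sequence].
#' @param segments A data.frame with `start`/`end` columns as produced by
#'   [segment_gestures()].
#' @return A list of [orientation_sequence] objects, one per segment.
#' @export
apply_segments <- function(seq, segments) {
  seq <- as_orientation_sequence(seq)
  n <- nrow(seq$q)
  lapply(seq_len(nrow(segments)), function(k) {
    s <- segments$start[k]; e <- segments$end[k]
    if (is.na(s) || is.na(e) || s < 1L || e > n || s >= e)
      stop(sprintf("segment %d [%s, %s] is out of range for a stream of %d samples",
                   k, s, e, n))
    rereference(orientation_sequence(seq$q[s:e, , drop = FALSE],
                                     t = if (is.null(seq$t)) NULL else seq$t[s:e],
                                     subject = seq$subject, label = seq$label,
                                     normalize = FALSE))
  })
}
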
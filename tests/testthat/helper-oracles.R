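# Independent oracles and small fixture builders shared across tests.

# Random unit quaternions, one per row.
rand_unit_quats <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

rand_unit_quat <- function() rand_unit_quats(1)[1, ]

# Standard quaternion -> rotation matrix map (independent of the package's
# product formula); for q = (x, y, z, w).
rotation_matrix <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Geodesic angle between two rotations via rotation matrices.
rotation_angle_oracle <- function(q1, q2) {
  tr <- sum(diag(crossprod(rotation_matrix(q1), rotation_matrix(q2))))
  acos(min(1, max(-1, (tr - 1) / 2)))
}

# Axis-angle unit quaternion (Hamilton convention), axis a unit 3-vector.
axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(axis * sin(angle / 2), cos(angle / 2))
}

# Exhaustive DTW oracle: enumerate every admissible warping path, find the
# minimal accumulated cost (forward summation, the same arithmetic as a
# dynamic program), and normalize by that path's length.
dtw_brute_force <- function(A, B, metric = c("euclidean", "quaternion")) {
  metric <- match.arg(metric)
  n <- nrow(A); m <- nrow(B)
  cost <- function(i, j) {
    if (metric == "quaternion") 1 - abs(sum(A[i, ] * B[j, ]))
    else sqrt(sum((A[i, ] - B[j, ])^2))
  }
  best <- Inf; best_len <- NA_integer_
  recurse <- function(i, j, acc, len) {
    acc <- acc + cost(i, j)
    len <- len + 1L
    if (i == n && j == m) {
      if (acc < best) { best <<- acc; best_len <<- len }
      return(invisible())
    }
    if (i < n) recurse(i + 1L, j, acc, len)
    if (j < m) recurse(i, j + 1L, acc, len)
    if (i < n && j < m) recurse(i + 1L, j + 1L, acc, len)
  }
  recurse(1L, 1L, 0, 0L)
  best / best_len
}

# Brute-force truncated-window running median.
median_brute_force <- function(x, mk) {
  h <- mk %/% 2
  n <- length(x)
  sapply(seq_len(n), function(i) median(x[max(1, i - h):min(n, i + h)]))
}

# Jaccard overlap of two 1-based inclusive index ranges.
range_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  union <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / union
}

# Random smooth unit-quaternion walk of length n (small incremental steps).
rand_quat_walk <- function(n, step_deg = 3) {
  q <- rand_unit_quat()
  out <- matrix(0, n, 4)
  out[1, ] <- q
  for (i in seq_len(n - 1)) {
    ax <- rnorm(3)
    dq <- axis_angle_quat(ax, step_deg * pi / 180 * runif(1))
    q <- quat_normalize(quat_multiply(q, dq))
    out[i + 1, ] <- q
  }
  out
}

# Time-resample an orientation sequence by a factor (componentwise linear
# interpolation + renormalization; adequate for densely sampled streams).
resample_recording <- function(seq, factor) {
  n <- nrow(seq$q)
  L <- max(2L, round(n * factor))
  tin <- seq(0, 1, length.out = n)
  tout <- seq(0, 1, length.out = L)
  q <- vapply(1:4, function(k) approx(tin, seq$q[, k], xout = tout)$y, numeric(L))
  orientation_sequence(matrix(q, ncol = 4), subject = seq$subject, label = seq$label)
}

# Small fast dataset configs for module tests.
tiny_config <- function(seed = 42, ...) {
  synthetic_config(subjects = 3L, reps_per_class = 3L, seed = seed, ...)
}

# Reference multiclass confusion matrix of a bagged DTW head-gesture
# classifier (published benchmark; true classes in rows) together with the
# error rates printed alongside it.
reference_confusion <- function() {
  cls <- c("clockwise", "counterclockwise", "left", "nod", "m_left",
           "m_right", "right")
  m <- matrix(c(146, 0, 0, 2, 0, 0, 1,
                0, 147, 1, 0, 0, 0, 0,
                0, 0, 144, 0, 0, 0, 0,
                0, 7, 0, 166, 0, 0, 0,
                0, 4, 0, 0, 145, 0, 0,
                5, 0, 0, 4, 0, 140, 0,
                0, 0, 2, 0, 0, 0, 141),
              7, 7, byrow = TRUE, dimnames = list(cls, cls))
  list(confusion = m,
       per_class_error = c(clockwise = 0.020, counterclockwise = 0.007,
                           left = 0.000, nod = 0.040, m_left = 0.027,
                           m_right = 0.060, right = 0.014),
       total_error = 0.025)
}
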
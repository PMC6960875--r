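#' @useDynLib hgr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cov median rnorm runif
NULL

# A quaternion is a numeric vector c(x, y, z, w); sequences store one
# quaternion per row of an n x 4 matrix with columns x, y, z, w.

.quat_check <- function(q, arg = "q") {
  if (!is.numeric(q) || length(q) != 4L || anyNA(q))
    stop(sprintf("'%s' must be a numeric vector of length 4 (x, y, z, w)", arg))
  invisible(q)
}

.quat_norm <- function(q) sqrt(sum(q^2))

#' Normalize a quaternion to unit length
#'
#' Divides each component by the Euclidean norm \eqn{\sqrt{x^2+y^2+z^2+w^2}}.
#'
#' @param q Numeric vector `c(x, y, z, w)`.
#' @param index Optional sample index used in the error message when the
#'   norm is zero (useful when normalizing rows of a recording).
#' @return A unit quaternion `c(x, y, z, w)`.
#' @export
#' @examples
#' quat_normalize(c(0, 0, 0, 2))
quat_normalize <- function(q, index = NULL) {
  .quat_check(q)
  n <- .quat_norm(q)
  if (n <= 0) {
    where <- if (is.null(index)) "" else sprintf(" (sample %d)", as.integer(index))
    stop("cannot normalize a zero-norm quaternion", where)
  }
  unname(q / n)
}

#' Quaternion product
#'
#' Multiplies two quaternions component-wise:
#' \deqn{q_1 \cdot q_2 = [w_2 x_1 + x_2 w_1 + y_2 z_1 - z_2 y_1,\;
#'   w_2 y_1 + y_2 w_1 + z_2 x_1 - x_2 z_1,\;
#'   w_2 z_1 + z_2 w_1 + x_2 y_1 - y_2 x_1,\;
#'   w_2 w_1 - x_2 x_1 - y_2 y_1 - z_2 z_1]}
#'
#' Under this convention the product composes rotations as
#' \eqn{R(q_1 \cdot q_2) = R(q_2)\,R(q_1)} where \eqn{R} is the standard
#' quaternion-to-rotation-matrix map (established by the rotation-matrix
#' oracle in the test suite). The norm of the product equals the product of
#' the norms.
#'
#' @param q1,q2 Numeric vectors `c(x, y, z, w)`.
#' @return The product quaternion.
#' @export
quat_multiply <- function(q1, q2) {
  .quat_check(q1, "q1"); .quat_check(q2, "q2")
  x1 <- q1[1L]; y1 <- q1[2L]; z1 <- q1[3L]; w1 <- q1[4L]
  x2 <- q2[1L]; y2 <- q2[2L]; z2 <- q2[3L]; w2 <- q2[4L]
  unname(c(w2 * x1 + x2 * w1 + y2 * z1 - z2 * y1,
           w2 * y1 + y2 * w1 + z2 * x1 - x2 * z1,
           w2 * z1 + z2 * w1 + x2 * y1 - y2 * x1,
           w2 * w1 - x2 * x1 - y2 * y1 - z2 * z1))
}

#' Quaternion inverse
#'
#' Returns \eqn{q^{-1} = [-x, -y, -z, w] / d} with \eqn{d = x^2+y^2+z^2+w^2},
#' so that `quat_multiply(q, quat_inverse(q))` is the identity quaternion.
#'
#' @param q Numeric vector `c(x, y, z, w)` with positive norm.
#' @return The inverse quaternion.
#' @export
quat_inverse <- function(q) {
  .quat_check(q)
  d <- sum(q^2)
  if (d <= 0) stop("cannot invert a zero-norm quaternion")
  unname(c(-q[1L], -q[2L], -q[3L], q[4L]) / d)
}

#' Angle between two rotations
#'
#' Computes the relative rotation `q3 = U(q1) * U(q2)^-1` (`U` denotes
#' normalization) and returns the rotation angle `alpha = 2*acos(w3)` mapped
#' into `[0, pi]`: values above pi are replaced by `2*pi - alpha`, the
#' equivalent rotation the other way around. The result is invariant under
#' sign flips of either argument.
#'
#' Numerically the angle is evaluated as `2*atan2(||(x3,y3,z3)||, |w3|)`,
#' which equals the acos form with the `[0, pi]` mapping but stays accurate
#' near zero angle, where `acos` loses half the significant digits.
#'
#' @param q1,q2 Numeric vectors `c(x, y, z, w)` with positive norm.
#' @return Angle in radians in `[0, pi]`.
#' @export
quat_angle <- function(q1, q2) {
  q3 <- quat_multiply(quat_normalize(q1), quat_inverse(quat_normalize(q2)))
  2 * atan2(sqrt(sum(q3[1:3]^2)), abs(q3[4L]))
}

#' Map a rotation to its head-direction vector
#'
#' The spatial representation of a head rotation is the image of the
#' reference vector `[0, 0, 1]` ("where the nose points") under the
#' rotation: with `q* = [-x, -y, -z, w]` and `qv = [0, 0, 1, 0]` the
#' product chain `qr = (q* . qv) . q` yields the pure quaternion whose
#' vector part `[xr, yr, zr]` is the rotated unit vector.
#'
#' @param q A unit quaternion `c(x, y, z, w)` (norm within 1e-6 of 1).
#' @return Unit direction vector `c(vx, vy, vz)`.
#' @export
quat_to_direction <- function(q) {
  .quat_check(q)
  if (abs(.quat_norm(q) - 1) > 1e-6)
    stop("quat_to_direction() requires a unit quaternion; normalize the input first")
  qc <- c(-q[1L], -q[2L], -q[3L], q[4L])
  qr <- quat_multiply(quat_multiply(qc, c(0, 0, 1, 0)), q)
  qr[1:3]
}

# Vectorized spatial map for an n x 4 quaternion matrix; same product chain
# as quat_to_direction(), expanded algebraically row-wise.
.spatial_rows <- function(Q) {
  x <- Q[, 1L]; y <- Q[, 2L]; z <- Q[, 3L]; w <- Q[, 4L]
  # inner product: a = (-x,-y,-z,w) . (0,0,1,0) under the printed formula
  ax <- y; ay <- -x; az <- w; aw <- z
  # outer product: (ax,ay,az,aw) . (x,y,z,w)
  cbind(vx = w * ax + x * aw + y * az - z * ay,
        vy = w * ay + y * aw + z * ax - x * az,
        vz = w * az + z * aw + x * ay - y * ax)
}

#' Markley eigen-average of unit quaternions
#'
#' Averages rotations by accumulating the (optionally weighted) outer-product
#' matrix \eqn{M = \sum_i w_i q_i q_i^T} and returning the unit eigenvector
#' of `M` with the largest eigenvalue. Because \eqn{q q^T} is blind to the
#' sign of `q`, the mean is invariant to sign flips of any input — the
#' property that makes this the right average for quaternions, where `q`
#' and `-q` encode the same rotation. The sign of the result is fixed so
#' that `w >= 0` (first nonzero coordinate positive if `w == 0`).
#'
#' @param Q An n x 4 matrix of unit quaternions (rows), or a single
#'   quaternion vector.
#' @param weights Optional non-negative weights, one per row; default all 1.
#' @return The average unit quaternion `c(x, y, z, w)`.
#' @export
quat_markley_mean <- function(Q, weights = NULL) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  if (!is.numeric(Q) || ncol(Q) != 4L || nrow(Q) < 1L)
    stop("'Q' must be a non-empty n x 4 matrix of quaternions")
  n <- nrow(Q)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("'weights' must be non-negative, match nrow(Q), and not all be zero")
  M <- crossprod(Q * sqrt(weights))  # sum_i w_i q_i q_i^T, 4 x 4 symmetric
  eig <- tryCatch(eigen(M, symmetric = TRUE),
                  error = function(e) stop(sprintf(
                    "eigen decomposition failed (matrix norm %.3g, condition: %s)",
                    norm(M, "F"), conditionMessage(e))))
  v <- eig$vectors[, 1L]
  .quat_fix_sign(v / sqrt(sum(v^2)))
}

.quat_fix_sign <- function(q) {
  if (q[4L] < 0) return(-q)
  if (q[4L] == 0) {
    nz <- which(q != 0)
    if (length(nz) && q[nz[1L]] < 0) return(-q)
  }
  q
}

#' Re-reference a recording to start at the identity rotation
#'
#' Left-composes every sample with the inverse of the first one,
#' `Qr[a] = Q[1]^-1 . Q[a]`, so the first rotation becomes the identity
#' `[0, 0, 0, 1]` and all consecutive inter-sample angles are preserved.
#' Gestures re-referenced this way are comparable regardless of the
#' absolute head pose at which they were performed.
#'
#' @param seq An [orientation_sequence].
#' @return The re-referenced [orientation_sequence].
#' @export
rereference <- function(seq) {
  seq <- as_orientation_sequence(seq)
  if (nrow(seq$q) < 1L) stop("cannot re-reference an empty sequence")
  q1inv <- quat_inverse(seq$q[1L, ])
  x1 <- q1inv[1L]; y1 <- q1inv[2L]; z1 <- q1inv[3L]; w1 <- q1inv[4L]
  x2 <- seq$q[, 1L]; y2 <- seq$q[, 2L]; z2 <- seq$q[, 3L]; w2 <- seq$q[, 4L]
  seq$q <- cbind(x = w2 * x1 + x2 * w1 + y2 * z1 - z2 * y1,
                 y = w2 * y1 + y2 * w1 + z2 * x1 - x2 * z1,
                 z = w2 * z1 + z2 * w1 + x2 * y1 - y2 * x1,
                 w = w2 * w1 - x2 * x1 - y2 * y1 - z2 * z1)
  seq
}

#' Orientation sequences
#'
#' An `orientation_sequence` is an ordered quaternion recording: an n x 4
#' matrix of unit quaternions (columns x, y, z, w), acquisition timestamps
#' in milliseconds, and optional subject and gesture-class labels.
#'
#' @param q An n x 4 numeric matrix (or a single quaternion vector).
#' @param t Optional numeric timestamps in ms, one per row.
#' @param subject Optional subject identifier.
#' @param label Optional gesture-class label.
#' @param normalize If `TRUE` (default), rows are normalized to unit length.
#' @return An object of class `orientation_sequence`.
#' @export
orientation_sequence <- function(q, t = NULL, subject = NULL, label = NULL,
                                 normalize = TRUE) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- as.matrix(q)
  if (!is.numeric(q) || ncol(q) != 4L)
    stop("'q' must be an n x 4 numeric matrix with columns x, y, z, w")
  if (anyNA(q)) stop("quaternion matrix contains missing values")
  norms <- sqrt(rowSums(q^2))
  if (any(norms <= 0))
    stop(sprintf("zero-norm quaternion at sample %d", which(norms <= 0)[1L]))
  if (normalize) q <- q / norms
  colnames(q) <- c("x", "y", "z", "w")
  if (!is.null(t)) {
    if (length(t) != nrow(q)) stop("'t' must have one timestamp per sample")
    t <- as.numeric(t)
  }
  structure(list(q = q, t = t,
                 subject = if (is.null(subject)) NULL else as.character(subject),
                 label = if (is.null(label)) NULL else as.character(label)),
            class = "orientation_sequence")
}

#' @export
as_orientation_sequence <- function(x, ...) UseMethod("as_orientation_sequence")

#' @export
as_orientation_sequence.orientation_sequence <- function(x, ...) x

#' @export
as_orientation_sequence.matrix <- function(x, ...) orientation_sequence(x, ...)

#' @export
length.orientation_sequence <- function(x) nrow(x$q)

#' @export
print.orientation_sequence <- function(x, ...) {
  cat(sprintf("<orientation_sequence> %d samples", nrow(x$q)))
  if (!is.null(x$subject)) cat(sprintf(", subject %s", x$subject))
  if (!is.null(x$label)) cat(sprintf(", class %s", x$label))
  cat("\n")
  if (!is.null(x$t))
    cat(sprintf("  time span %.1f ms\n", diff(range(x$t))))
  invisible(x)
}

#' Spatial representation of a recording
#'
#' Maps every quaternion sample to the head-direction unit vector via
#' [quat_to_direction()], yielding the 3-D trajectory "drawn by the nose".
#'
#' @param seq An [orientation_sequence] (or n x 4 quaternion matrix).
#' @return An n x 3 matrix with columns vx, vy, vz; rows have unit norm.
#' @export
spatial_representation <- function(seq) {
  Q <- if (inherits(seq, "orientation_sequence")) seq$q else as.matrix(seq)
  .spatial_rows(Q)
}
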
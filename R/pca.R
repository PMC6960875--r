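# PCA eigen-features over resampled, flattened head-direction trajectories,
# with exhaustive 1-NN classification, and the two-stage variant that first
# reduces the 3 spatial channels to 2 per time sample.

#' Resample a spatial trajectory to a fixed length
#'
#' Linear interpolation of each coordinate on normalized time `[0, 1]`
#' (uniform over sample index) at `L` equispaced points, followed by
#' renormalization of every interpolated point to unit length. Endpoints
#' are preserved exactly.
#'
#' @param v An n x 3 (or n x d) spatial trajectory, samples in rows.
#' @param L Target length (>= 2).
#' @return An L x d matrix, rows renormalized to unit vectors.
#' @export
resample_spatial <- function(v, L) {
  v <- as.matrix(v)
  if (nrow(v) < 2L) stop("resampling needs at least 2 samples")
  if (L < 2L) stop("'L' must be >= 2")
  tin <- seq(0, 1, length.out = nrow(v))
  tout <- seq(0, 1, length.out = L)
  out <- vapply(seq_len(ncol(v)),
                function(j) approx(tin, v[, j], xout = tout)$y,
                numeric(L))
  out <- matrix(out, nrow = L)
  out / sqrt(rowSums(out^2))
}

#' Flatten a fixed-length trajectory into a single feature vector
#'
#' Column-major concatenation: all `m` values of channel 1, then channel 2,
#' then channel 3 — a length `n * m` vector for an m x n trajectory.
#'
#' @param v An m x n matrix (m samples, n channels).
#' @return Numeric vector of length `n * m`.
#' @export
flatten_trajectory <- function(v) {
  as.numeric(as.matrix(v))
}

#' Undo [flatten_trajectory()]
#' @param x Flattened vector of length `n * m`.
#' @param channels Number of channels n (default 3).
#' @return An m x n matrix.
#' @export
unflatten_trajectory <- function(x, channels = 3L) {
  matrix(x, ncol = channels)
}

#' Fit a PCA feature projection
#'
#' Computes the mean vector `V` of the flattened training vectors, the
#' covariance matrix `C` of the centered data (1/(N-1) estimator), and the
#' top-`k` eigenvectors of `C` ordered by descending eigenvalue. Eigenvector
#' signs are fixed deterministically (largest-magnitude component positive).
#'
#' @param X An N x (n*m) matrix of flattened training vectors (rows), or a
#'   list of flattened vectors.
#' @param k Number of components, `1 <= k <= n*m`.
#' @return A `feature_projection`: list with `mean` (V), `eigenvectors`
#'   (k x (n*m), rows orthonormal), `eigenvalues` (length k), and `k`.
#' @export
fit_projection <- function(X, k) {
  if (is.list(X)) X <- do.call(rbind, X)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training vectors")
  if (k < 1L || k > ncol(X)) stop("'k' must be between 1 and ncol(X)")
  V <- colMeans(X)
  C <- cov(X)  # 1/(N-1) covariance of rows
  eig <- eigen(C, symmetric = TRUE)
  W <- t(eig$vectors[, seq_len(k), drop = FALSE])  # k x (n*m)
  for (i in seq_len(k)) {
    j <- which.max(abs(W[i, ]))
    if (W[i, j] < 0) W[i, ] <- -W[i, ]
  }
  structure(list(mean = V, eigenvectors = W,
                 eigenvalues = eig$values[seq_len(k)], k = as.integer(k)),
            class = "feature_projection")
}

#' Project a flattened vector onto PCA features
#'
#' `S[k] = X[k, n*m] %*% (S - V)`: the centered vector expressed in the
#' `k` leading principal directions.
#'
#' @param x Flattened vector (length must match the projection).
#' @param projection A `feature_projection` from [fit_projection()].
#' @return Numeric feature vector of length `k`.
#' @export
project_features <- function(x, projection) {
  if (length(x) != length(projection$mean))
    stop(sprintf("vector length %d does not match projection length %d",
                 length(x), length(projection$mean)))
  as.numeric(projection$eigenvectors %*% (x - projection$mean))
}

#' Exhaustive nearest-neighbour classification
#'
#' Returns the label of the Euclidean-nearest training vector, comparing
#' the query against every training row (no spatial index); ties go to the
#' earliest training row.
#'
#' @param x Query feature vector.
#' @param train N x k matrix of training feature vectors.
#' @param labels Character vector of N training labels.
#' @return The predicted label.
#' @export
nn_classify <- function(x, train, labels) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("empty training set")
  if (length(labels) != nrow(train)) stop("one label per training row required")
  d2 <- rowSums((train - rep(x, each = nrow(train)))^2)
  labels[which.min(d2)]
}

# Row-wise application of project_features() as one matrix product.
.project_rows <- function(X, projection) {
  sweep(as.matrix(X), 2L, projection$mean) %*% t(projection$eigenvectors)
}

.spatial_resampled <- function(dataset, L) {
  lapply(dataset, function(s) resample_spatial(spatial_representation(s), L))
}

#' Train the PCA-feature 1-NN classifier
#'
#' Pipeline: spatial representation -> resample to `L` samples -> flatten ->
#' fit a `k`-dimensional PCA projection on the training set -> store the
#' projected training features for 1-NN classification.
#'
#' @param dataset List of labeled [orientation_sequence] objects.
#' @param k Feature dimensionality (default 15).
#' @param L Resample length in samples (default 100).
#' @return A `pca_model`.
#' @export
train_pca <- function(dataset, k = 15L, L = 100L) {
  flat <- do.call(rbind, lapply(.spatial_resampled(dataset, L), flatten_trajectory))
  proj <- fit_projection(flat, k)
  feats <- .project_rows(flat, proj)
  structure(list(projection = proj, features = feats,
                 labels = dataset_labels(dataset), L = as.integer(L)),
            class = "pca_model")
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  one <- function(s) {
    x <- flatten_trajectory(resample_spatial(spatial_representation(s), object$L))
    nn_classify(project_features(x, object$projection),
                object$features, object$labels)
  }
  if (inherits(newdata, "orientation_sequence")) return(one(newdata))
  vapply(newdata, one, character(1))
}

#' Train the two-stage PCA classifier
#'
#' Stage 1 pools the individual 3-D trajectory points of all (resampled)
#' training recordings and fits a 2-dimensional projection of the spatial
#' channels, mapping every trajectory to a 2-channel series. Stage 2
#' flattens the reduced series and applies the ordinary PCA-feature 1-NN
#' pipeline with `k2` components.
#'
#' @param dataset List of labeled [orientation_sequence] objects.
#' @param k2 Second-stage feature dimensionality (default 15).
#' @param L Resample length in samples (default 100).
#' @return A `pca2_model`.
#' @export
train_pca_two_stage <- function(dataset, k2 = 15L, L = 100L) {
  resampled <- .spatial_resampled(dataset, L)
  stage1 <- fit_projection(do.call(rbind, resampled), 2L)
  flat <- do.call(rbind, lapply(resampled, function(v)
    flatten_trajectory(.project_rows(v, stage1))))
  proj <- fit_projection(flat, k2)
  feats <- .project_rows(flat, proj)
  structure(list(stage1 = stage1, projection = proj, features = feats,
                 labels = dataset_labels(dataset), L = as.integer(L)),
            class = "pca2_model")
}

#' @export
predict.pca2_model <- function(object, newdata, ...) {
  one <- function(s) {
    v <- resample_spatial(spatial_representation(s), object$L)
    r <- .project_rows(v, object$stage1)
    nn_classify(project_features(flatten_trajectory(r), object$projection),
                object$features, object$labels)
  }
  if (inherits(newdata, "orientation_sequence")) return(one(newdata))
  vapply(newdata, one, character(1))
}
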
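test_that("resampling preserves constants, endpoints and great-circle arcs", {
  const <- matrix(rep(c(0, 0, 1), each = 7), 7, 3)
  r <- resample_spatial(const, 20)
  expect_equal(r, matrix(rep(c(0, 0, 1), each = 20), 20, 3), ignore_attr = TRUE)
  # resampling to own length on the aligned grid is the identity
  set.seed(601)
  arc50 <- t(sapply(seq(0, 1, length.out = 50), function(t)
    c(sin(t * pi / 3), 0, cos(t * pi / 3))))
  expect_equal(resample_spatial(arc50, 50), arc50, tolerance = 1e-9, ignore_attr = TRUE)
  # great-circle arc densified: all points near the analytic arc
  r100 <- resample_spatial(arc50, 100)
  truth <- t(sapply(seq(0, 1, length.out = 100), function(t)
    c(sin(t * pi / 3), 0, cos(t * pi / 3))))
  expect_lt(max(abs(r100 - truth)), 1e-3)
  expect_equal(r100[1, ], arc50[1, ], ignore_attr = TRUE)
  expect_equal(r100[100, ], arc50[50, ], ignore_attr = TRUE)
  expect_equal(sqrt(rowSums(r100^2)), rep(1, 100), tolerance = 1e-12)
  expect_error(resample_spatial(const[1, , drop = FALSE], 10), "at least 2")
})

test_that("flattening is column-major and invertible", {
  v <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(flatten_trajectory(v), c(1, 0, 0, 1, 0, 0))
  set.seed(602)
  m <- matrix(rnorm(30), 10, 3)
  f <- flatten_trajectory(m)
  expect_length(f, 30)
  expect_equal(unflatten_trajectory(f), m)
})

test_that("projection centers, orders variance and preserves geometry at full rank", {
  set.seed(603)
  X <- matrix(rnorm(40 * 12), 40, 12) %*% diag(c(5:1, rep(0.3, 7)))
  p <- fit_projection(X, 12)
  # rows of the eigenvector matrix are orthonormal
  expect_equal(p$eigenvectors %*% t(p$eigenvectors), diag(12), tolerance = 1e-9)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  expect_true(all(p$eigenvalues >= -1e-9))
  # projecting the mean gives the zero vector
  expect_equal(project_features(p$mean, p), rep(0, 12), tolerance = 1e-12)
  # mean + eigenvector_i maps to the i-th unit vector
  for (i in c(1, 5)) {
    e <- project_features(p$mean + p$eigenvectors[i, ], p)
    expect_equal(e, as.numeric(diag(12)[i, ]), tolerance = 1e-9)
  }
  # full-rank projection is an isometry: pairwise distances preserved
  F <- t(apply(X, 1, project_features, projection = p))
  expect_equal(dist(F), dist(X), tolerance = 1e-8, ignore_attr = TRUE)
  # reconstruction at full rank reproduces the input
  s <- X[3, ]
  expect_equal(as.numeric(t(p$eigenvectors) %*% project_features(s, p) + p$mean),
               s, tolerance = 1e-8)
  # projected training variances are non-increasing across components
  vars <- apply(F, 2, var)
  expect_true(all(diff(vars) <= 1e-9))
  # training-set order does not change the fit
  perm <- sample(40)
  expect_equal(fit_projection(X[perm, ], 5), fit_projection(X, 5), tolerance = 1e-9)
  expect_error(fit_projection(X, 13), "between 1")
  expect_error(fit_projection(X[1, , drop = FALSE], 2), "at least 2")
})

test_that("1-NN finds exact matches, separated clusters, and breaks ties first-wins", {
  set.seed(604)
  train <- rbind(matrix(rnorm(50, mean = 0, sd = 0.5), 25, 2),
                 matrix(rnorm(50, mean = 10, sd = 0.5), 25, 2))
  labels <- rep(c("a", "b"), each = 25)
  expect_equal(nn_classify(train[3, ], train, labels), "a")
  expect_equal(nn_classify(train[30, ], train, labels), "b")
  for (i in 1:20) {
    expect_equal(nn_classify(rnorm(2, 0, 0.5), train, labels), "a")
    expect_equal(nn_classify(rnorm(2, 10, 0.5), train, labels), "b")
  }
  # single training item always answers its label
  expect_equal(nn_classify(c(99, 99), train[1, , drop = FALSE], "solo"), "solo")
  # equidistant query: earliest training row wins
  two <- rbind(c(0, 0), c(2, 0))
  expect_equal(nn_classify(c(1, 0), two, c("first", "second")), "first")
})

test_that("full-rank PCA + 1-NN equals 1-NN on raw flattened vectors", {
  set.seed(605)
  ds <- generate_dataset(synthetic_config(subjects = 2, reps_per_class = 4, seed = 605))
  L <- 40
  flat <- do.call(rbind, lapply(ds, function(s)
    flatten_trajectory(resample_spatial(spatial_representation(s), L))))
  labs <- dataset_labels(ds)
  p <- fit_projection(flat, ncol(flat))
  F <- t(apply(flat, 1, project_features, projection = p))
  for (i in seq_len(nrow(flat))) {
    raw_nn <- nn_classify(flat[i, ], flat[-i, ], labs[-i])
    pca_nn <- nn_classify(F[i, ], F[-i, ], labs[-i])
    expect_equal(pca_nn, raw_nn)
  }
})

test_that("the trained PCA pipeline classifies and the two-stage variant matches on planar data", {
  cfg <- synthetic_config(subjects = 3, reps_per_class = 4, seed = 606)
  ds <- generate_dataset(cfg)
  model <- train_pca(ds, k = 10, L = 60)
  expect_equal(dim(model$features), c(length(ds), 10))
  pred <- predict(model, ds)
  expect_gte(mean(pred == dataset_labels(ds)), 0.95)  # resubstitution sanity
  m2 <- train_pca_two_stage(ds, k2 = 10, L = 60)
  expect_equal(ncol(m2$stage1$eigenvectors), 3)
  expect_equal(nrow(m2$stage1$eigenvectors), 2)
  expect_equal(length(m2$projection$mean), 2 * 60)
  p2 <- predict(m2, ds[[5]])
  expect_true(p2 %in% gesture_classes())
  # trajectories confined to a plane: the 2-D first stage is lossless, so
  # both pipelines see the same geometry and agree label-for-label
  set.seed(607)
  planar <- lapply(1:40, function(i) {
    ang <- runif(1, 0.2, 1.2)
    t_grid <- seq(0, 1, length.out = 50)
    v <- t(sapply(t_grid, function(t) c(sin(ang * t), 0, cos(ang * t))))
    q <- direction_to_quaternion(asin(pmin(1, pmax(-1, v[, 1]))) * 180 / pi,
                                 rep(0, 50))
    orientation_sequence(q, subject = sprintf("s%02d", (i - 1) %% 4 + 1),
                         label = if (ang < 0.7) "short" else "long")
  })
  one <- train_pca(planar, k = 5, L = 50)
  two <- train_pca_two_stage(planar, k2 = 5, L = 50)
  expect_equal(predict(two, planar), predict(one, planar))
})
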
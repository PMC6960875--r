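test_that("dataset generation matches the configured design", {
  cfg <- synthetic_config(seed = 801)
  ds <- generate_dataset(cfg)
  expect_length(ds, 12 * 7 * 10)
  tab <- dataset_summary(ds)
  expect_true(all(tab == 10))
  labs <- dataset_labels(ds)
  expect_equal(unname(table(labs)), rep(120L, 7), ignore_attr = TRUE)
  lens <- sapply(ds, length)
  expect_true(all(lens >= cfg$length_bounds[1] & lens <= cfg$length_bounds[2]))
  # every emitted quaternion is unit norm; every first sample is identity
  for (s in ds[seq(1, length(ds), by = 40)]) {
    expect_equal(sqrt(rowSums(s$q^2)), rep(1, length(s)), tolerance = 1e-9)
    expect_equal(unname(s$q[1, ]), c(0, 0, 0, 1), tolerance = 1e-12)
    expect_true(all(diff(s$t) > 0))
  }
})

test_that("generation is deterministic under the seed and distinct across seeds", {
  cfg <- synthetic_config(subjects = 2, reps_per_class = 2, seed = 802)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- generate_dataset(synthetic_config(subjects = 2, reps_per_class = 2, seed = 803))
  expect_false(isTRUE(all.equal(d1[[1]]$q, d3[[1]]$q)))
  # generation restores the caller's RNG state
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(generate_dataset(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("directional class pairs share point sets but reverse time", {
  t_grid <- seq(0, 1, length.out = 101)
  pairs <- list(c("clockwise", "counterclockwise"),
                c("left", "right"),
                c("m_left", "m_right"))
  for (p in pairs) {
    a <- gesture_shape(p[1], t_grid)
    b <- gesture_shape(p[2], t_grid)
    # same point set (order on rounded keys so fp ties sort identically)...
    key <- function(m) order(round(m[, 1], 6), round(m[, 2], 6))
    expect_equal(a[key(a), ], b[key(b), ], tolerance = 1e-6, ignore_attr = TRUE)
    # ...traversed in reverse order, and not palindromic
    expect_equal(a, b[rev(seq_len(nrow(b))), ], tolerance = 1e-9, ignore_attr = TRUE)
    expect_gt(max(abs(a - b)), 1)
  }
  for (cl in gesture_classes()) {
    sh <- gesture_shape(cl, t_grid)
    expect_equal(unname(sh[1, ]), c(0, 0), tolerance = 1e-9)
    expect_true(all(abs(sh) <= 80))
  }
})

test_that("yaw/pitch to quaternion round-trips through the direction map", {
  expect_equal(unname(direction_to_quaternion(0, 0)), c(0, 0, 0, 1))
  q90 <- direction_to_quaternion(90, 0)
  expect_equal(abs(quat_to_direction(q90)[1]), 1, tolerance = 1e-12)
  set.seed(804)
  yaw <- runif(200, -85, 85); pitch <- runif(200, -85, 85)
  V <- spatial_representation(direction_to_quaternion(yaw, pitch))
  truth <- cbind(sin(yaw * pi / 180) * cos(pitch * pi / 180),
                 sin(pitch * pi / 180),
                 cos(yaw * pi / 180) * cos(pitch * pi / 180))
  expect_lt(max(abs(V - truth)), 1e-9)
  expect_error(direction_to_quaternion(0, 90), "gimbal")
})

test_that("sampling intervals follow the configured timing model", {
  cfg <- synthetic_config(seed = 805)
  set.seed(805)
  dts <- sample_intervals(1e4, cfg)
  expect_lt(abs(mean(dts) - cfg$dt_mean_ms), 0.5)
  expect_true(all(dts >= 1))
  expect_lt(abs(sd(dts) - cfg$dt_sd_ms), 0.5)
})

test_that("streams concatenate rest and gesture periods with true boundaries", {
  cfg <- synthetic_config(seed = 806)
  st <- generate_stream(cfg, gestures = c("clockwise", "left", "nod"),
                        rest_samples = 100)
  expect_equal(nrow(st$segments), 3)
  lens <- st$segments$end - st$segments$start + 1
  expect_equal(length(st$stream), 4 * 100 + sum(lens))
  expect_equal(st$segments$start[1], 101)
  # still periods stay below the segmentation threshold after filtering
  vel <- median_filter(angular_velocity(st$stream), 15)
  rest_idx <- setdiff(seq_along(vel),
                      unlist(Map(seq, st$segments$start - 8, st$segments$end + 8)))
  expect_lt(max(vel[rest_idx]), 1)
  expect_identical(st, generate_stream(cfg, gestures = c("clockwise", "left", "nod"),
                                       rest_samples = 100))
})

test_that("noise-free clockwise recordings trace the analytic circle", {
  cfg <- synthetic_config(noise_angle_deg = 0, tilt_sd_deg = 0,
                          amplitude_range = c(1, 1), speed_range = c(1, 1),
                          seed = 807)
  s <- hgr:::.with_seed(807, {
    style <- hgr:::.neutral_style()
    n <- 80
    yp <- hgr:::.gesture_curve("clockwise", style, cfg, n)
    orientation_sequence(direction_to_quaternion(yp[, 1], yp[, 2]))
  })
  v <- spatial_representation(s)
  truth <- t(sapply(seq(0, 1, length.out = 80), function(t) {
    yaw <- 25 * sin(2 * pi * t) * pi / 180
    pitch <- (-25 + 25 * cos(2 * pi * t)) * pi / 180
    c(sin(yaw) * cos(pitch), sin(pitch), cos(yaw) * cos(pitch))
  }))
  expect_lt(max(abs(v - truth)), 1e-6)
})
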
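test_that("normalization rescales to unit length and rejects zero norm", {
  expect_equal(quat_normalize(c(0, 0, 0, 2)), c(0, 0, 0, 1))
  expect_equal(quat_normalize(c(0.6, 0, 0.8, 0)), c(0.6, 0, 0.8, 0))
  expect_equal(quat_normalize(c(1, 1, 1, 1)), c(0.5, 0.5, 0.5, 0.5))
  expect_error(quat_normalize(c(0, 0, 0, 0)), "zero-norm")
  expect_error(quat_normalize(c(0, 0, 0, 0), index = 7), "sample 7")
})

test_that("quaternion product keeps the identity and multiplies norms", {
  set.seed(101)
  for (i in 1:20) {
    q <- rnorm(4)
    expect_equal(quat_multiply(q, c(0, 0, 0, 1)), q)
    expect_equal(quat_multiply(c(0, 0, 0, 1), q), q)
  }
  for (i in 1:1000) {
    q1 <- rnorm(4); q2 <- rnorm(4)
    expect_equal(sqrt(sum(quat_multiply(q1, q2)^2)),
                 sqrt(sum(q1^2)) * sqrt(sum(q2^2)), tolerance = 1e-9)
  }
})

test_that("product composes rotations as R(q1.q2) = R(q2) R(q1)", {
  # two 90-degree rotations about z compose to a 180-degree z-rotation
  qz90 <- axis_angle_quat(c(0, 0, 1), pi / 2)
  prod <- quat_multiply(qz90, qz90)
  expect_equal(rotation_matrix(prod), rotation_matrix(axis_angle_quat(c(0, 0, 1), pi)),
               tolerance = 1e-12)
  set.seed(102)
  for (i in 1:50) {
    q1 <- rand_unit_quat(); q2 <- rand_unit_quat()
    expect_equal(rotation_matrix(quat_multiply(q1, q2)),
                 rotation_matrix(q2) %*% rotation_matrix(q1), tolerance = 1e-9)
  }
})

test_that("inverse matches the printed form and annihilates its quaternion", {
  expect_equal(quat_inverse(c(0, 0, 0, 1)), c(0, 0, 0, 1))
  expect_equal(quat_inverse(c(0, 0, 0, 2)), c(0, 0, 0, 0.5))
  expect_error(quat_inverse(c(0, 0, 0, 0)), "zero-norm")
  set.seed(103)
  for (i in 1:100) {
    q <- rand_unit_quat()
    expect_equal(quat_multiply(q, quat_inverse(q)), c(0, 0, 0, 1), tolerance = 1e-12)
  }
})

test_that("rotation angle lies in [0, pi], is symmetric and sign-blind", {
  q90x <- c(sin(pi / 4), 0, 0, cos(pi / 4))
  expect_equal(quat_angle(c(0, 0, 0, 1), q90x), pi / 2)
  set.seed(104)
  for (i in 1:200) {
    q1 <- rand_unit_quat(); q2 <- rand_unit_quat()
    a <- quat_angle(q1, q2)
    expect_gte(a, 0); expect_lte(a, pi)
    expect_equal(quat_angle(q1, q1), 0)
    expect_equal(quat_angle(q2, q1), a, tolerance = 1e-12)
    expect_equal(quat_angle(-q1, q2), a, tolerance = 1e-12)
    expect_equal(quat_angle(q1, -q2), a, tolerance = 1e-12)
    expect_equal(a, rotation_angle_oracle(q1, q2), tolerance = 1e-9)
  }
})

test_that("head-direction map equals the rotation-matrix image of [0,0,1]", {
  expect_equal(quat_to_direction(c(0, 0, 0, 1)), c(0, 0, 1))
  q90x <- axis_angle_quat(c(1, 0, 0), pi / 2)
  expect_equal(quat_to_direction(q90x), as.numeric(rotation_matrix(q90x) %*% c(0, 0, 1)),
               tolerance = 1e-12)
  expect_error(quat_to_direction(c(0, 0, 0, 2)), "normalize")
  set.seed(105)
  Q <- rand_unit_quats(1000)
  V <- spatial_representation(Q)
  expect_equal(sqrt(rowSums(V^2)), rep(1, 1000), tolerance = 1e-9)
  for (i in seq_len(100)) {
    expect_equal(V[i, ], as.numeric(rotation_matrix(Q[i, ]) %*% c(0, 0, 1)),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(unname(V[i, ]), quat_to_direction(Q[i, ]))
  }
})

test_that("Markley mean recovers copies, respects signs and weights", {
  set.seed(106)
  q <- rand_unit_quat()
  m <- quat_markley_mean(rbind(q, q, q))
  expect_equal(abs(sum(m * q)), 1, tolerance = 1e-12)
  # sign invariance: {q, -q, q} and {q, q, q} give the same rotation
  m2 <- quat_markley_mean(rbind(q, -q, q))
  expect_equal(m, m2, tolerance = 1e-12)
  # perturbed copies stay within the noise level of the original
  for (i in 1:20) {
    q <- rand_unit_quat()
    noisy <- t(sapply(1:10, function(j)
      quat_multiply(q, axis_angle_quat(rnorm(3), runif(1, 0, 5 * pi / 180)))))
    expect_lte(quat_angle(quat_markley_mean(noisy), q), 5 * pi / 180)
  }
  # weights: duplicating a sample equals doubling its weight
  a <- rand_unit_quat(); b <- rand_unit_quat()
  expect_equal(quat_markley_mean(rbind(a, a, b)),
               quat_markley_mean(rbind(a, b), weights = c(2, 1)), tolerance = 1e-12)
  expect_error(quat_markley_mean(matrix(numeric(0), 0, 4)), "non-empty")
  expect_error(quat_markley_mean(rbind(a, b), weights = c(0, 0)), "weights")
})

test_that("re-referencing starts at identity and preserves local angles", {
  set.seed(107)
  Q <- rand_quat_walk(40)
  seq <- orientation_sequence(Q)
  r <- rereference(seq)
  expect_equal(unname(r$q[1, ]), c(0, 0, 0, 1), tolerance = 1e-12)
  const <- rereference(orientation_sequence(matrix(rep(rand_unit_quat(), 5), 5, 4, byrow = TRUE)))
  expect_equal(unname(const$q), matrix(rep(c(0, 0, 0, 1), 5), 5, 4, byrow = TRUE),
               tolerance = 1e-12)
  for (a in 1:(nrow(Q) - 1)) {
    expect_equal(quat_angle(Q[a, ], Q[a + 1, ]),
                 quat_angle(r$q[a, ], r$q[a + 1, ]), tolerance = 1e-9)
  }
})

test_that("orientation_sequence validates and normalizes its rows", {
  expect_error(orientation_sequence(matrix(0, 2, 4)), "zero-norm")
  expect_error(orientation_sequence(matrix(1, 2, 3)), "n x 4")
  s <- orientation_sequence(matrix(c(0, 0, 0, 2), 1, 4))
  expect_equal(unname(s$q[1, ]), c(0, 0, 0, 1))
})
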
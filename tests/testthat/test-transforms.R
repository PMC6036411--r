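test_that("patient shifts map to DICOM LPS with the documented signs", {
  s <- patient_shift(c(10, 5, 15), c("Lt", "Ant", "Sup"), "stationary")
  expect_equal(unname(patient_shift_to_dicom(s)), c(10, -5, 15))
  expect_equal(unname(patient_shift_to_dicom(
    patient_shift(c(0, 0, 0), c("Lt", "Ant", "Sup")))), c(0, 0, 0))
  # every direction label negates its partner
  expect_equal(unname(patient_shift_to_dicom(
    patient_shift(c(3, 5, 12), c("Rt", "Post", "Inf")))), c(-3, 5, -12))
  # labels arriving in a scrambled axis order land on the right axes
  expect_equal(unname(patient_shift_to_dicom(
    patient_shift(c(15, 10, 5), c("Sup", "Lt", "Ant")))), c(10, -5, 15))
  expect_error(patient_shift(c(1, 2, 3), c("Lt", "Rt", "Sup")), "exactly once")
  expect_error(patient_shift(c(1, 2, 3), c("Lt", "Ant", "Up")), "labels")
})

test_that("expected translation is oriented target-to-moving by shifted role", {
  s1 <- patient_shift(c(10, 5, 15), c("Lt", "Ant", "Sup"), "stationary")
  expect_equal(unname(expected_translation(s1)), c(-10, 5, -15))
  s6 <- patient_shift(c(3, 5, 12), c("Lt", "Ant", "Sup"), "moving")
  expect_equal(unname(expected_translation(s6)), c(3, -5, 12))
  expect_error(expected_translation(
    patient_shift(c(1, 1, 1), c("Lt", "Ant", "Sup"), "unspecified")), "role")
  # role swap flips the sign exactly
  set.seed(42)
  for (i in 1:25) {
    m <- stats::runif(3, -30, 30)
    a <- patient_shift(m, c("Lt", "Ant", "Sup"), "stationary")
    b <- patient_shift(m, c("Lt", "Ant", "Sup"), "moving")
    expect_identical(expected_translation(a), -expected_translation(b))
  }
})

test_that("single-axis rotations use the printed element layout", {
  expect_equal(rotation_about_axis("x", 0), diag(3))
  rz <- rotation_about_axis("z", 10)
  expect_equal(rz, matrix(c(0.9848, -0.1736, 0, 0.1736, 0.9848, 0, 0, 0, 1),
                          3, 3, byrow = TRUE), tolerance = 1e-4)
  # the Ry layout places -sin at row 1, col 3
  ry <- rotation_about_axis("y", 8)
  expect_equal(ry[1, 3], -sin(8 * pi / 180))
  expect_equal(ry[3, 1], sin(8 * pi / 180))
})

test_that("composed rotations are orthonormal proper rotations", {
  set.seed(7)
  for (i in 1:1000) {
    r <- compose_rotations(random_rotation_spec())
    expect_lt(max(abs(r %*% t(r) - diag(3))), 1e-9)
    expect_lt(abs(det(r) - 1), 1e-9)
  }
})

test_that("default composition order reproduces the worked forward matrix", {
  r <- compose_rotations(case10_spec())
  expect_equal(r[2, ], c(0.172, 0.983, 0.062), tolerance = 0.002)
  # and the inverse rotation block is its transpose
  inv <- invert_transform(build_nominal_transform(case10_spec(), case10_shift()))
  expect_equal(transform_rotation(inv), t(r), tolerance = 1e-12)
  # a different declared order gives a different matrix
  r_xyz <- compose_rotations(case10_spec(), order = "xyz")
  expect_gt(max(abs(r - r_xyz)), 1e-3)
})

test_that("nominal transform assembles rotation then translation", {
  nom <- build_nominal_transform(case10_spec(), case10_shift())
  expect_equal(unname(transform_translation(nom)), c(5, -15, 20))
  expect_identical(nom$direction, "moving_to_stationary")
  id <- build_nominal_transform(rotation_spec(),
                                patient_shift(c(0, 0, 0), c("Lt", "Ant", "Sup")))
  expect_equal(id$matrix, diag(4))
  pure <- build_nominal_transform(rotation_spec(),
    patient_shift(c(10, 5, 15), c("Lt", "Ant", "Sup")))
  expect_equal(unname(transform_translation(pure)), c(10, -5, 15))
  expect_equal(transform_rotation(pure), diag(3))
})

test_that("inversion is exact, involutive, and flips the direction tag", {
  id <- homogeneous_transform()
  expect_equal(invert_transform(id)$matrix, diag(4))
  pure <- homogeneous_transform(diag(3), c(3, -5, 12))
  expect_equal(unname(transform_translation(invert_transform(pure))),
               c(-3, 5, -12))
  set.seed(11)
  for (i in 1:50) {
    t1 <- random_transform()
    t2 <- invert_transform(invert_transform(t1))
    expect_lt(max(abs(t1$matrix - t2$matrix)), 1e-9)
    expect_identical(invert_transform(t1)$direction, "moving_to_stationary")
    p <- stats::runif(3, -100, 100)
    expect_lt(max(abs(transform_point(invert_transform(t1),
                                      transform_point(t1, p)) - p)), 1e-9)
  }
})

test_that("points map through R p + T, matrix input vectorized", {
  expect_equal(transform_point(homogeneous_transform(), c(1, 2, 3)), c(1, 2, 3))
  nom <- build_nominal_transform(case10_spec(), case10_shift())
  expect_equal(unname(transform_point(nom, c(0, 0, 0))), c(5, -15, 20))
  pts <- matrix(stats::runif(30, -50, 50), ncol = 3)
  one_by_one <- t(apply(pts, 1, function(p) transform_point(nom, p)))
  expect_equal(transform_point(nom, pts), one_by_one)
})

test_that("translation errors difference reported minus known per axis", {
  rep_t <- homogeneous_transform(diag(3), c(-10, 5, -15),
                                 direction = "target_to_moving")
  expect_equal(unname(translation_errors(rep_t, c(-10, 5, -15))), c(0, 0, 0))
  rep2 <- homogeneous_transform(diag(3), c(-8.7, 5, -15),
                                direction = "target_to_moving")
  expect_equal(unname(translation_errors(rep2, c(-10, 5, -15))), c(1.3, 0, 0))
  # direction mismatch refused
  wrong <- homogeneous_transform(diag(3), c(1, 2, 3),
                                 direction = "moving_to_stationary")
  expect_error(translation_errors(wrong, c(1, 2, 3)), "direction")
  # parameter recovery of a random injected perturbation
  set.seed(5)
  for (i in 1:25) {
    known <- stats::runif(3, -30, 30)
    delta <- stats::runif(3, -2, 2)
    rep3 <- homogeneous_transform(diag(3), known + delta,
                                  direction = "target_to_moving")
    expect_lt(max(abs(translation_errors(rep3, known) - delta)), 1e-12)
  }
})

test_that("rotation axis is the invariant line of the rotation", {
  expect_equal(rotation_axis(rotation_about_axis("z", 10)), c(0, 0, 1),
               tolerance = 1e-12)
  set.seed(13)
  for (i in 1:50) {
    r <- compose_rotations(rotation_spec(x = stats::runif(1, 0.5, 170),
                                         y = stats::runif(1, -170, 170),
                                         z = stats::runif(1, -170, 170)))
    u <- rotation_axis(r)
    expect_lt(max(abs(r %*% u - u)), 1e-9)
    expect_equal(sum(u^2), 1, tolerance = 1e-12)
    # canonical sign: largest-magnitude component positive
    expect_gt(u[which.max(abs(u))], 0)
    # agrees with the skew-part axis up to sign (rotation angle < 180 here)
    skew <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
    if (sqrt(sum(skew^2)) > 1e-6) {
      skew <- skew / sqrt(sum(skew^2))
      expect_lt(min(max(abs(u - skew)), max(abs(u + skew))), 1e-9)
    }
  }
})

test_that("identity rotation has a flagged degenerate axis", {
  ax <- rotation_axis(diag(3))
  expect_true(isTRUE(attr(ax, "degenerate")))
  expect_true(all(is.na(ax)))
  expect_warning(m <- axis_misalignment(ax, c(0, 0, 1)), "degenerate")
  expect_equal(m, 0)
})

test_that("axis misalignment is the sign-invariant angle between axes", {
  u <- c(0, 0, 1)
  expect_equal(axis_misalignment(u, u), 0)
  expect_equal(axis_misalignment(u, -u), 0)
  th <- 1 * pi / 180
  expect_equal(axis_misalignment(u, c(0, sin(th), cos(th))), 1,
               tolerance = 1e-9)
  expect_error(axis_misalignment(c(0, 0, 0), u), "zero length")
  # closed-form tilt recovery across magnitudes
  for (ang in c(0.01, 0.5, 5, 45, 89)) {
    v <- c(0, sin(ang * pi / 180), cos(ang * pi / 180))
    expect_equal(axis_misalignment(u, v), ang, tolerance = 1e-8)
  }
})

test_that("half-voxel criterion is per-axis and boundary-inclusive", {
  expect_true(all(half_voxel_check(c(0, 0, 0), c(1, 1, 1))))
  expect_equal(unname(half_voxel_check(c(1.3, 1.3, 0.1), c(0.7, 0.7, 3.0))),
               c(FALSE, FALSE, TRUE))
  expect_equal(unname(half_voxel_check(c(0.35, 0.35, 1.5), c(0.7, 0.7, 3.0))),
               c(TRUE, TRUE, TRUE))
  expect_error(half_voxel_check(c(0, 0, 0), c(1, 0, 1)), "positive")
})

test_that("flat 16-value round trip is lossless and validated", {
  set.seed(3)
  for (i in 1:25) {
    t1 <- random_transform()
    expect_identical(transform_from_flat(transform_to_flat(t1),
                                         direction = t1$direction)$matrix,
                     t1$matrix)
  }
  expect_error(transform_from_flat(rep(1, 15)), "16")
  bad <- transform_to_flat(homogeneous_transform())
  bad[16] <- 2
  expect_error(transform_from_flat(bad), "0/0/0/1")
})
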
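test_that("chaining follows the composition rule and its inverse", {
  set.seed(7)
  A <- rot_axis_angle(runif(3), 25)
  B <- rot_axis_angle(runif(3), -40)
  ch <- rotation_chain(list(A, B), reference_index = 1L)
  expect_equal(chain_rotations(ch, 2, 2), diag(3))
  expect_equal(chain_rotations(ch, 1, 3), B %*% A)
  expect_equal(chain_rotations(ch, 3, 1), t(B %*% A))
  expect_error(chain_rotations(ch, 0, 2), class = "spheromap_invalid_input")
  expect_error(chain_rotations(ch, 1, 4), class = "spheromap_invalid_input")

  # forward and backward products cancel
  expect_equal(chain_rotations(ch, 1, 3) %*% chain_rotations(ch, 3, 1), diag(3),
               tolerance = 1e-6)
})

test_that("orthonormality survives 16-link chains", {
  set.seed(11)
  Rs <- lapply(1:16, function(i) rot_axis_angle(rnorm(3), runif(1, 20, 40)))
  ch <- rotation_chain(Rs, 1L)
  for (j in c(5, 9, 17)) {
    R <- chain_rotations(ch, 1, j)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-6)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("frame propagation is exact at the reference and invertible", {
  b <- sphere_seq()
  ch <- rotation_chain(b$truth$pairwise, 1L)
  F1 <- diag(3)
  expect_equal(propagate_frame(F1, ch, 1), F1)
  F7 <- propagate_frame(F1, ch, 7)
  # back-propagation returns the original frame
  ch7 <- rotation_chain(b$truth$pairwise, 7L)
  expect_equal(propagate_frame(F7, ch7, 1), F1, tolerance = 1e-6)
  # propagated frames match the renderer's ground truth
  for (j in c(4, 10, 13)) {
    expect_lt(geodesic_angle(propagate_frame(F1, ch, j), b$truth$frames[[j]]), 1e-6)
  }
})

test_that("pairwise estimation recovers known rotations from texture", {
  b <- sphere_seq()
  m <- b$truth$model

  # identical views: identity within 1 degree
  est0 <- estimate_pairwise_rotation(b$views[[1]], b$views[[1]], m, diag(3), seed = 1)
  expect_true(est0$ok)
  expect_lt(geodesic_angle(est0$R), 1)

  # a true 30-degree step about the vertical axis: within 2 degrees geodesic
  est <- estimate_pairwise_rotation(b$views[[1]], b$views[[2]], m, diag(3), seed = 1)
  expect_true(est$ok)
  expect_gte(est$n_inliers, 6)
  expect_lt(geodesic_angle(est$R, b$truth$pairwise[[1]]), 2)
})

test_that("textureless views yield an estimation-failure signal", {
  flat <- make_texture("checker", params = list(cell_deg = 360))
  b <- generate_sequence(synthetic_scene(spheroid_model(40, 40, 40), flat,
                                         step_angles = rep(30, 2)))
  est <- estimate_pairwise_rotation(b$views[[1]], b$views[[2]],
                                    b$truth$model, diag(3), seed = 1)
  expect_false(est$ok)
  expect_null(est$R)
})

test_that("a failed pair is substituted from its neighbours and logged", {
  b <- sphere_seq()
  views <- b$views[1:6]
  # sabotage view 4: flat image kills texture for pairs 3 and 4
  views[[4]]$image <- array(0.5, dim(views[[4]]$image))
  res <- estimate_rotation_chain(views, b$truth$model, diag(3), seed = 2)
  expect_s3_class(res$chain, "rotation_chain")
  expect_true(any(res$qc$substituted))
  expect_identical(res$qc$substituted, !res$qc$ok)
  # substituted links are still close to the true 30-degree step
  for (k in which(res$qc$substituted)) {
    expect_lt(geodesic_angle(res$chain$pairwise[[k]], b$truth$pairwise[[k]]), 5)
  }
})

test_that("estimated chain keeps the propagated rotation axis near truth", {
  b <- sphere_seq()
  res <- estimate_rotation_chain(b$views, b$truth$model, diag(3), seed = 3)
  expect_true(all(res$qc$ok))
  for (j in seq_along(b$views)) {
    vy <- propagate_frame(diag(3), res$chain, j)[, 2]
    ang <- acos(pmin(1, sum(vy * b$truth$axis))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("rotation utilities: nearest rotation, geodesic mean", {
  set.seed(5)
  R <- rot_axis_angle(rnorm(3), 33)
  noisy <- R + matrix(rnorm(9, 0, 1e-4), 3, 3)
  Rn <- nearest_rotation(noisy)
  expect_lt(max(abs(crossprod(Rn) - diag(3))), 1e-12)
  expect_lt(geodesic_angle(Rn, R), 0.05)

  A <- rot_axis_angle(c(0, 1, 0), 20)
  B <- rot_axis_angle(c(0, 1, 0), 40)
  expect_lt(geodesic_angle(rotation_mean(list(A, B)),
                           rot_axis_angle(c(0, 1, 0), 30)), 1e-8)
})
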
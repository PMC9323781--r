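test_that("silhouette fitting recovers discs and rotated ellipses", {
  disc <- ellipse_mask(121, 50, 50)
  s <- fit_silhouette(disc)
  expect_equal(unname(s$centroid), c(61, 61), tolerance = 0.01)
  expect_equal(s$a, 50, tolerance = 1 / 50)
  expect_equal(s$b, 50, tolerance = 1 / 50)

  ell <- ellipse_mask(161, 60, 40, theta_deg = 30)
  s <- fit_silhouette(ell)
  expect_equal(s$a, 60, tolerance = 1 / 60)
  expect_equal(s$b, 40, tolerance = 1 / 40)
  expect_lt(abs(s$theta - 30), 2)
})

test_that("degenerate masks are rejected", {
  expect_error(fit_silhouette(matrix(0, 50, 50)), class = "spheromap_invalid_input")
  two <- matrix(0, 80, 160)
  two[20:60, 20:60] <- 1
  two[20:60, 100:140] <- 1
  expect_error(fit_silhouette(two), class = "spheromap_invalid_input")
  speck <- matrix(0, 50, 50); speck[25:26, 25:26] <- 1
  expect_error(fit_silhouette(speck), class = "spheromap_invalid_input")
})

test_that("geometry classification separates the three spheroid classes", {
  expect_error(classify_geometry(sphere_seq()$views[1:2]),
               class = "spheromap_invalid_input")
  expect_identical(classify_geometry(sphere_seq()$views), "spherical")
  expect_identical(classify_geometry(oblate_seq()$views), "oblate")
  expect_identical(classify_geometry(prolate_seq()$views), "prolate")
})

test_that("reference view selection follows the class-specific rule", {
  expect_identical(select_reference_view(sphere_seq()$views, "spherical"), 1L)

  # tie on the minor axis breaks toward the earlier view
  v <- sphere_seq()$views[[1]]
  expect_identical(select_reference_view(list(v, v, v), "oblate"), 1L)

  # wobbling oblate: the chosen view must have the revolution (y) axis
  # closest to the image plane, within 5 degrees
  wob <- oblate_wobble_seq()
  ref <- select_reference_view(wob$views, "oblate")
  tilt_out_of_plane <- vapply(wob$truth$frames, function(F)
    abs(asin(F[3, 2])) * 180 / pi, 0)
  expect_lte(tilt_out_of_plane[ref], 5)
  expect_identical(ref, which.min(tilt_out_of_plane))
})

test_that("radii estimation recovers the generating spheroid", {
  ob <- oblate_seq()
  ref <- select_reference_view(ob$views, "oblate")
  m <- estimate_radii(ob$views, "oblate", ref)
  expect_equal(m$rx, 125, tolerance = 0.02)
  expect_equal(m$ry, 95, tolerance = 0.02)
  expect_identical(m$geometry_class, "oblate")

  pr <- prolate_seq()
  ref <- select_reference_view(pr$views, "prolate")
  m <- estimate_radii(pr$views, "prolate", ref)
  expect_equal(m$rx, 95, tolerance = 0.02)
  expect_equal(m$ry, 125, tolerance = 0.02)
})

test_that("fruit frame initialisation is right-handed and tracks the silhouette", {
  expect_equal(init_fruit_frame(sphere_seq()$views[[1]], "spherical"), diag(3))

  # silhouette principal axes 10 degrees off vertical -> vy 10 deg off vertical
  fake <- structure(list(ellipse = list(a = 50, b = 38, theta = 80)),
                    class = "view_obs")
  F <- init_fruit_frame(fake, "oblate")
  expect_equal(acos(F[2, 2]) * 180 / pi, 10, tolerance = 1e-6)
  expect_equal(F[3, 1:2], c(0, 0))             # vx, vy in the image plane
  expect_equal(F[, 3], c(0, 0, 1))
  expect_equal(det(F), 1, tolerance = 1e-9)

  # near-circular reference for a non-spherical label falls back with warning
  circ <- structure(list(ellipse = list(a = 50, b = 49.8, theta = 10)),
                    class = "view_obs")
  expect_warning(Fc <- init_fruit_frame(circ, "oblate"), "circular")
  expect_equal(Fc, diag(3))

  # determinant is +1 for arbitrary orientations
  for (th in c(-80, -45, -10, 0, 30, 45, 89)) {
    fake$ellipse$theta <- th
    expect_equal(det(init_fruit_frame(fake, "oblate")), 1, tolerance = 1e-9)
  }
})

test_that("surface height matches apex/limb closed forms and a ray-march oracle", {
  sph <- spheroid_model(80, 80, 80)
  expect_equal(surface_height(0, 0, sph), 80)
  expect_equal(surface_height(80, 0, sph), 0, tolerance = 1e-6)
  expect_true(is.na(surface_height(81, 0, sph)))

  ob <- spheroid_model(125, 95, 125)
  z <- surface_height(50, 20, ob)
  expect_equal(z, raymarch_height(50, 20, ob), tolerance = 1e-6)

  # tilted frame agrees with the oracle too
  F <- rot_axis_angle(c(1, 2, 0.5), 35)
  for (pt in list(c(30, -40), c(-60, 10), c(0, 70))) {
    expect_equal(surface_height(pt[1], pt[2], ob, F),
                 raymarch_height(pt[1], pt[2], ob, F), tolerance = 1e-6)
  }
})

test_that("surface height back-projects onto the ellipsoid surface", {
  ob <- spheroid_model(125, 95, 125)
  F <- rot_axis_angle(c(0.1, 1, 0.2), 40)
  set.seed(42)
  x <- runif(500, -90, 90); y <- runif(500, -70, 70)
  z <- surface_height(x, y, ob, F)
  ok <- !is.na(z)
  XYZ <- cbind(x[ok], y[ok], z[ok]) %*% F
  resid <- (XYZ[, 1] / ob$rx)^2 + (XYZ[, 2] / ob$ry)^2 + (XYZ[, 3] / ob$rz)^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("spheroid model validates radii and infers the class", {
  expect_error(spheroid_model(-1, 5), class = "spheromap_error")
  expect_error(spheroid_model(100, 95, 80), class = "spheromap_error")
  expect_identical(spheroid_model(100, 100.5, 100)$geometry_class, "spherical")
  expect_identical(spheroid_model(100, 80, 100)$geometry_class, "oblate")
  expect_identical(spheroid_model(100, 130, 100)$geometry_class, "prolate")
})
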
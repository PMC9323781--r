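test_that("lonlat_to_surface matches the parametrisation at key points", {
  m <- spheroid_model(125, 95, 125)
  expect_equal(unname(lonlat_to_surface(0, 0, m)[1, ]), c(125, 0, 0))
  expect_equal(unname(lonlat_to_surface(90, 0, m)[1, ]), c(0, 0, 125),
               tolerance = 1e-12)
  expect_equal(unname(lonlat_to_surface(0, 90, m)[1, ]), c(0, 95, 0),
               tolerance = 1e-12)
  # points always satisfy the ellipsoid equation
  set.seed(1)
  S <- lonlat_to_surface(runif(200, -180, 180), runif(200, -90, 90), m)
  resid <- (S[, 1] / m$rx)^2 + (S[, 2] / m$ry)^2 + (S[, 3] / m$rz)^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("surface_to_view projects onto the axes and flags visibility", {
  S <- c(10, 20, 30)
  v <- surface_to_view(S, diag(3))
  expect_equal(unname(v[1, 1:3]), S)
  expect_equal(unname(v[1, "visible"]), 1)
  expect_equal(unname(surface_to_view(c(10, 20, -5), diag(3))[1, "visible"]), 0)

  # a frame rotated 90 deg about the view y-axis maps (rx,0,0) onto the z-axis
  F <- rot_axis_angle(c(0, 1, 0), 90)
  v <- surface_to_view(c(125, 0, 0), F)
  expect_equal(unname(v[1, 1:3]), c(0, 0, -125), tolerance = 1e-12)
})

test_that("view centre maps to longitude 90 and round trips are identities", {
  m <- spheroid_model(125, 95, 125)
  expect_equal(unname(view_to_lonlat(0, 0, m)[1, ]), c(90, 0))

  set.seed(2)
  F <- rot_axis_angle(c(0.2, 1, 0.1), 33)
  phi <- runif(2000, -180, 180); lam <- runif(2000, -89, 89)
  S <- lonlat_to_surface(phi, lam, m)
  v <- surface_to_view(S, F)
  ## visible = the camera-side ray intersection (z > 0 alone can still be
  ## limb-occluded on a tilted spheroid)
  zf <- surface_height(v[, "x"], v[, "y"], m, F)
  vis <- v[, "visible"] > 0 & !is.na(zf) & abs(zf - v[, "z"]) < 1e-6
  pl <- view_to_lonlat(v[vis, "x"], v[vis, "y"], m, F)
  dphi <- abs(((pl[, "phi"] - phi[vis] + 180) %% 360) - 180)
  expect_lt(max(dphi), 1e-6)
  expect_lt(max(abs(pl[, "lam"] - lam[vis])), 1e-6)
})

test_that("view_to_lonlat agrees with the renderer's ground truth", {
  b <- sphere_seq()
  ob <- b$views[[5]]
  gt_phi <- ob$gt_lonlat[, , 1]; gt_lam <- ob$gt_lonlat[, , 2]
  idx <- which(!is.na(gt_phi) & ob$mask == 1, arr.ind = TRUE)
  x <- idx[, 2] - ob$centroid["col"]; y <- ob$centroid["row"] - idx[, 1]
  interior <- sqrt(x^2 + y^2) < 0.9 * 60
  pl <- view_to_lonlat(x[interior], y[interior], b$truth$model,
                       b$truth$frames[[5]])
  dphi <- abs(((pl[, "phi"] - gt_phi[idx][interior] + 180) %% 360) - 180)
  dlam <- abs(pl[, "lam"] - gt_lam[idx][interior])
  expect_gte(mean(dphi < 0.5 & dlam < 0.5, na.rm = TRUE), 0.99)
})

test_that("longitude schedule unwraps to a strictly increasing sequence", {
  # wrap case: raw [170, -170] -> [170, 190]
  expect_equal(spheromap:::unwrap_longitudes(c(170, -170)), c(170, 190))
  # already monotone input is unchanged
  expect_equal(spheromap:::unwrap_longitudes(c(10, 40, 80)), c(10, 40, 80))
  # property: any raw sequence becomes strictly increasing
  set.seed(3)
  for (i in 1:20) {
    L <- spheromap:::unwrap_longitudes(runif(12, -180, 180))
    expect_true(all(diff(L) > 0))
  }
  # 13 synthetic views at exactly 30-degree steps
  b <- sphere_seq()
  sch <- compute_longitude_schedule(b$views, b$truth$model, b$truth$frames)
  expect_lt(max(abs(sch$L - (sch$L[1] + 30 * (0:12)))), 2)
  expect_error(compute_longitude_schedule(b$views, b$truth$model,
                                          b$truth$frames, preroll = -1),
               class = "spheromap_error")
})

test_that("blending weights are linear, conserved and bounded to two views", {
  sch <- structure(list(L = c(100, 130, 165), preroll = 45, postroll = 45),
                   class = "longitude_schedule")
  expect_equal(blend_weights(100, sch),
               data.frame(view = 1L, weight = 1))
  w <- blend_weights(115, sch)
  expect_equal(w$weight, c(0.5, 0.5))
  w <- blend_weights(110, sch)
  expect_equal(w$view, c(1L, 2L))
  expect_equal(w$weight, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # pre/post-roll: single view
  expect_equal(blend_weights(60, sch)$view, 1L)
  expect_equal(blend_weights(200, sch)$view, 3L)
  expect_error(blend_weights(54, sch), class = "spheromap_invalid_input")
  # conservation and the two-view contract at random longitudes
  set.seed(4)
  for (phi in runif(200, 55, 210)) {
    w <- blend_weights(phi, sch)
    expect_lte(nrow(w), 2)
    expect_identical(sum(w$weight), 1)
  }
})

test_that("angular step gives 1-pixel equator resolution and the map sizes", {
  expect_equal(angular_step(125), 0.008)
  expect_equal(angular_step(1), 1)
  expect_error(angular_step(0), class = "spheromap_error")
  expect_equal(unname(map_dimensions(0.008, 360, NULL)), c(393L, 785L))
  expect_equal(unname(map_dimensions(0.008, 360, 60)), c(262L, 785L))
})

test_that("a single-view map reproduces the source texture", {
  b <- sphere_seq()
  m <- b$truth$model
  sch <- compute_longitude_schedule(b$views[1], m, b$truth$frames[1])
  map <- fill_map(b$views[1], m, b$truth$frames[1], sch, angular_step(60))
  expect_equal(map$lon_end - map$lon_start, 90)   # pre + post roll only
  expect_true(all(map$coverage %in% 0:1))
  expect_lt(map_texture_mae(map, b$truth$texture, lam_lim = 30), 2 / 255)
})

test_that("blending two identical adjacent views is idempotent", {
  b <- sphere_seq()
  m <- b$truth$model
  v <- b$views[[1]]; F <- b$truth$frames[[1]]
  sch2 <- structure(list(L = c(80, 100), preroll = 10, postroll = 10),
                    class = "longitude_schedule")
  sch1 <- structure(list(L = 90, preroll = 20, postroll = 20),
                    class = "longitude_schedule")
  map2 <- fill_map(list(v, v), m, list(F, F), sch2, angular_step(60))
  map1 <- fill_map(list(v), m, list(F), sch1, angular_step(60))
  expect_equal(dim(map2$pixels), dim(map1$pixels))
  expect_lt(max(abs(map2$pixels - map1$pixels)), 1e-12)
  expect_true(all(map2$coverage[abs(map2$lat) < 60, ] <= 2))
})

test_that("the fused full-turn map recovers the texture and covers <= 2 views", {
  b <- sphere_seq()
  m <- b$truth$model
  sch <- compute_longitude_schedule(b$views, m, b$truth$frames)
  map <- fill_map(b$views, m, b$truth$frames, sch, angular_step(60))
  expect_lt(map_texture_mae(map, b$truth$texture, lam_lim = 45), 5 / 255)
  expect_true(all(map$coverage <= 2))
  # polar bands are background gray
  polar <- abs(map$lat) >= 60
  expect_true(all(map$pixels[polar, , 1] == 0.5))
  # longitude span invariant
  expect_equal(map$lon_end - map$lon_start,
               (sch$L[13] - sch$L[1]) + sch$preroll + sch$postroll)
})

test_that("pixel areas integrate to known spheroid surface areas", {
  # sphere: conservation against 4 pi r^2
  r <- 50
  sph <- spheroid_model(r, r, r)
  beta <- 0.02
  bdeg <- beta * 180 / pi
  lam <- seq(-90, 90 - bdeg / 2, by = bdeg)
  phi <- seq(-180, 180 - bdeg / 2, by = bdeg)
  grid <- expand.grid(lam = lam, phi = phi)
  tot <- sum(pixel_area(grid$lam, grid$phi, sph, beta))
  expect_equal(tot, 4 * pi * r^2, tolerance = 1e-3)

  # latitude weighting ~ cos(lam) in the small-step limit
  a60 <- pixel_area(60, 0, sph, 0.001)
  a0 <- pixel_area(0, 0, sph, 0.001)
  expect_equal(a60 / a0, cos(60 * pi / 180), tolerance = 1e-3)

  # oblate spheroid: closed-form surface area oracle
  a <- 125; c <- 95
  ob <- spheroid_model(a, c, a)
  e <- sqrt(1 - (c / a)^2)
  S_true <- 2 * pi * a^2 + pi * (c^2 / e) * log((1 + e) / (1 - e))
  tot <- sum(pixel_area(grid$lam, grid$phi, ob, beta))
  expect_equal(tot, S_true, tolerance = 5e-3)
})

test_that("surface fractions are area-weighted and handle trivial masks", {
  b <- sphere_seq()
  m <- b$truth$model
  sch <- compute_longitude_schedule(b$views, m, b$truth$frames)
  map <- fill_map(b$views, m, b$truth$frames, sch, angular_step(60))
  all_mask <- matrix(TRUE, nrow(map$coverage), ncol(map$coverage))
  expect_equal(surface_fraction(map, all_mask), 1)
  expect_equal(surface_fraction(map, !all_mask), 0)
  expect_error(surface_fraction(map, all_mask[, 1:10]), class = "spheromap_error")

  # half-painted sphere measured from the fused map (ground-truth rotations)
  hemi <- generate_sequence(synthetic_scene(
    spheroid_model(60, 60, 60), make_texture("hemi", seed = 13),
    step_angles = rep(30, 12)))
  sch <- compute_longitude_schedule(hemi$views, hemi$truth$model, hemi$truth$frames)
  map <- fill_map(hemi$views, hemi$truth$model, hemi$truth$frames, sch,
                  angular_step(60))
  green <- map$pixels[, , 2] > map$pixels[, , 1]
  expect_equal(surface_fraction(map, green), 0.5, tolerance = 0.02)
})

test_that("nearest-neighbour sampling is available and exact on flat fields", {
  flat <- make_texture("checker", params = list(cell_deg = 360))
  b <- generate_sequence(synthetic_scene(spheroid_model(40, 40, 40), flat,
                                         step_angles = rep(30, 2)))
  sch <- compute_longitude_schedule(b$views, b$truth$model, b$truth$frames)
  map <- fill_map(b$views, b$truth$model, b$truth$frames, sch,
                  angular_step(40), interp = "nearest")
  covered <- map$coverage > 0
  expect_lt(max(abs(map$pixels[, , 1][covered] - flat$raster[1, 1, 1])), 1e-12)
})
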
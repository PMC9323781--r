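# Shared synthetic fixtures, rendered once per test run and cached, plus
# independent numerical oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 13 views x 30 deg of a textured sphere, radius 60 px (fast workhorse)
sphere_seq <- function() fixture("sphere60", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(60, 60, 60), make_texture("noise", seed = 3),
    step_angles = rep(30, 12)
  ))
})

# oblate / prolate sequences, 10 views x 40 deg over a full turn
oblate_seq <- function() fixture("oblate", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(125, 95, 125), make_texture("noise", seed = 5),
    step_angles = rep(40, 9)
  ))
})

prolate_seq <- function() fixture("prolate", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(95, 125, 95), make_texture("noise", seed = 7),
    step_angles = rep(40, 9)
  ))
})

# oblate fruit whose revolution axis wobbles 12 deg off the rotation axis,
# so the silhouette varies across views and the reference view is distinctive
oblate_wobble_seq <- function() fixture("oblate_wobble", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(60, 45, 60), make_texture("noise", seed = 11),
    step_angles = rep(30, 12), misalign_deg = 12
  ))
})

# paper-scale sphere (R = 125 px, 13 views x 30 deg, moderate texture)
acc_sphere <- function() fixture("acc_sphere", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(125, 125, 125), make_texture("noise", seed = 3),
    step_angles = rep(30, 12)
  ))
})

# the fused map of acc_sphere built with ground-truth rotations
acc_gt_map <- function() fixture("acc_gt_map", function() {
  b <- acc_sphere()
  sch <- compute_longitude_schedule(b$views, b$truth$model, b$truth$frames)
  fill_map(b$views, b$truth$model, b$truth$frames, sch, angular_step(125))
})

# same geometry with countable dark spots, several deliberately on view
# boundaries (multiples of 30 deg) and one in the >360-degree overlap region
acc_spots <- function() fixture("acc_spots", function() {
  pos <- data.frame(
    phi = c(120, 60, -150, -90, -30, 25, 170),
    lam = c(10, -15, 25, -30, 0, 35, -35),
    diam_px = c(6, 5, 8, 5, 7, 6, 9)
  )
  tex <- make_texture("spots", seed = 2,
                      params = list(positions = pos, equator_radius_px = 125))
  generate_sequence(synthetic_scene(spheroid_model(125, 125, 125), tex,
                                    step_angles = rep(30, 12)))
})

# half-green sphere for the end-to-end surface-fraction measurement
acc_hemi <- function() fixture("acc_hemi", function() {
  generate_sequence(synthetic_scene(
    spheroid_model(125, 125, 125), make_texture("hemi", seed = 13),
    step_angles = rep(30, 12)
  ))
})

# rasterize a centred ellipse mask in view coordinates (y up)
ellipse_mask <- function(size, a, b, theta_deg = 0) {
  ctr <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size) - ctr, size, size)
  y <- matrix(ctr - rep(seq_len(size), times = size), size, size)
  th <- theta_deg * pi / 180
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  matrix(as.numeric((u / a)^2 + (v / b)^2 <= 1), size, size)
}

# independent ray-march + bisection oracle for the visible ray-quadric hit
raymarch_height <- function(x, y, model, frame = diag(3)) {
  r <- c(model$rx, model$ry, model$rz)
  f <- function(t) {
    X <- crossprod(frame, c(x, y, t))
    sum((X / r)^2) - 1
  }
  zmax <- max(r) * 1.5
  ts <- seq(zmax, -zmax, length.out = 6001)
  vals <- vapply(ts, f, 0)
  i <- which(vals[-length(ts)] > 0 & vals[-1] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  uniroot(f, c(ts[i + 1], ts[i]), tol = 1e-12)$root
}

# mean absolute error between a map and its source texture over |lat| < lam_lim
map_texture_mae <- function(map, texture, lam_lim = 45) {
  sel <- abs(map$lat) < lam_lim
  idx <- which(map$coverage > 0 & matrix(sel, nrow(map$coverage), ncol(map$coverage)),
               arr.ind = TRUE)
  tx <- texture_sample(texture, map$lon[idx[, 2]], map$lat[idx[, 1]])
  mp <- cbind(map$pixels[, , 1][idx], map$pixels[, , 2][idx], map$pixels[, , 3][idx])
  mean(abs(tx - mp))
}
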
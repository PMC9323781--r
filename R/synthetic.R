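## Synthetic module: textured-spheroid renderer with ground truth for every
## pipeline stage. Emulates the acquisition geometry of a roller inspection
## machine: orthographic views of a fruit spinning about a near-vertical axis
## in steps of roughly 20-40 degrees, a dozen-plus views per full turn.

## run expr with a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## bilinearly upsample a coarse grid to h x w, periodic in the column
## (longitude) direction, clamped in the row (latitude) direction
periodic_upsample <- function(G, h, w) {
  gh <- nrow(G); gw <- ncol(G)
  Gp <- cbind(G, G[, 1])                       # wrap a column for periodicity
  rows <- (seq_len(h) - 0.5) / h * (gh - 1) + 1
  cols <- (seq_len(w) - 0.5) / w * gw + 0.5
  cols[cols < 1] <- cols[cols < 1] + gw       # wrap into the padded column
  grid_c <- rep(cols, each = h)
  grid_r <- rep(rows, times = w)
  matrix(bilinear_sample(Gp, grid_c, grid_r), h, w)
}

#' Generate an equirectangular fruit texture
#'
#' Deterministic ground-truth textures on a longitude/latitude grid (column 1
#' at -180 degrees, row 1 at +90). Kinds:
#' `"checker"` — analytic two-colour checkerboard of `cell_deg` squares;
#' `"noise"` — smooth two-octave periodic colour noise ("moderate texture",
#' enough structure for keypoint matching);
#' `"spots"` — a textured base with countable dark circular defects at
#' recorded positions, for losslessness tests;
#' `"hemi"` — noise with a green tint on the longitude half `(0, 180)`
#' (the `Z > 0` half-space of the surface) and red elsewhere, so exactly half
#' the surface is "green".
#'
#' @param kind texture kind.
#' @param width,height raster size (pixels); longitude resolution
#'   `360/width` degrees.
#' @param seed integer RNG seed; equal seeds give identical rasters.
#' @param params list overriding kind-specific defaults: `cell_deg` (checker),
#'   `n_spots`, `spot_diam_px`, `equator_radius_px`, `lam_range` (spots).
#' @return an object of class `fruit_texture`: `raster` (`h x w x 3`),
#'   `kind`, `spots` (data.frame or `NULL`), `params`.
#' @export
make_texture <- function(kind = c("noise", "checker", "spots", "hemi"),
                         width = 720L, height = 360L, seed = 0L,
                         params = list()) {
  kind <- match.arg(kind)
  h <- height; w <- width
  phi <- -180 + (seq_len(w) - 0.5) * 360 / w
  lam <- 90 - (seq_len(h) - 0.5) * 180 / h
  PH <- matrix(phi, h, w, byrow = TRUE)
  LA <- matrix(lam, h, w)
  spots <- NULL
  noise_layers <- function() with_seed(seed, {
    lapply(1:3, function(k) {
      c1 <- periodic_upsample(matrix(runif(24 * 48), 24, 48), h, w)
      c2 <- periodic_upsample(matrix(runif(8 * 16), 8, 16), h, w)
      v <- 0.55 * c1 + 0.45 * c2
      0.08 + 0.84 * (v - min(v)) / (max(v) - min(v))
    })
  })
  if (kind == "checker") {
    p <- modifyList(list(cell_deg = 30), params)
    par_id <- (floor((PH + 180) / p$cell_deg) + floor((LA + 90) / p$cell_deg)) %% 2
    raster <- array(0, c(h, w, 3))
    cols <- rbind(c(0.95, 0.75, 0.15), c(0.25, 0.12, 0.05))
    for (k in 1:3) raster[, , k] <- ifelse(par_id == 0, cols[1, k], cols[2, k])
  } else if (kind == "noise") {
    ch <- noise_layers()
    raster <- array(0, c(h, w, 3))
    for (k in 1:3) raster[, , k] <- ch[[k]]
  } else if (kind == "hemi") {
    ch <- noise_layers()
    base <- 0.35 + 0.6 * (ch[[1]] - 0.08) / 0.84
    green <- sin(deg2rad(PH)) > 0
    raster <- array(0, c(h, w, 3))
    raster[, , 1] <- ifelse(green, 0.25 * base, base)
    raster[, , 2] <- ifelse(green, base, 0.25 * base)
    raster[, , 3] <- 0.15 * base
  } else { # spots
    p <- modifyList(list(n_spots = 7L, spot_diam_px = c(5, 9),
                         equator_radius_px = 125, lam_range = 40,
                         positions = NULL), params)
    ch <- noise_layers()
    raster <- array(0, c(h, w, 3))
    base_cols <- c(0.95, 0.65, 0.2)
    for (k in 1:3) raster[, , k] <- base_cols[k] * (0.75 + 0.3 * ch[[k]])
    if (!is.null(p$positions)) {
      spots <- as.data.frame(p$positions)   # columns phi, lam, diam_px
    } else {
      spots <- with_seed(seed + 1L, {
        data.frame(
          phi = runif(p$n_spots, -180, 180),
          lam = runif(p$n_spots, -p$lam_range, p$lam_range),
          diam_px = runif(p$n_spots, p$spot_diam_px[1], p$spot_diam_px[2])
        )
      })
      ## enforce pairwise separation so spots stay individually countable
      for (i in seq_len(nrow(spots))[-1]) {
        repeat {
          d <- sqrt(((spots$phi[i] - spots$phi[seq_len(i - 1)]) *
                       cos(deg2rad(spots$lam[i])))^2 +
                      (spots$lam[i] - spots$lam[seq_len(i - 1)])^2)
          if (min(d) > 25) break
          spots$phi[i] <- ((spots$phi[i] + 37 + 180) %% 360) - 180
        }
      }
    }
    spots$diam_deg <- rad2deg(spots$diam_px / p$equator_radius_px)
    for (i in seq_len(nrow(spots))) {
      dphi <- (PH - spots$phi[i] + 180) %% 360 - 180
      d <- sqrt((dphi * cos(deg2rad(spots$lam[i])))^2 + (LA - spots$lam[i])^2)
      hit <- d <= spots$diam_deg[i] / 2
      raster[, , 1][hit] <- 0.12; raster[, , 2][hit] <- 0.06; raster[, , 3][hit] <- 0.04
    }
  }
  structure(list(raster = raster, kind = kind, spots = spots, params = params,
                 width = w, height = h),
            class = "fruit_texture")
}

#' Sample a texture at longitude/latitude
#'
#' Bilinear lookup with periodic wrap in longitude and clamping at the poles.
#'
#' @param texture a [make_texture()] object.
#' @param phi,lam degrees (vectorised; any longitude winding accepted).
#' @return `n x 3` RGB matrix.
#' @export
texture_sample <- function(texture, phi, lam) {
  h <- texture$height; w <- texture$width
  cc <- ((phi + 180) %% 360) / 360 * w + 0.5
  cc[cc < 1] <- cc[cc < 1] + w                # wrap into the padded column
  rr <- (90 - lam) / 180 * h + 0.5
  rr <- pmin(pmax(rr, 1), h)
  R <- texture$raster
  Rp <- array(0, c(h, w + 1, 3))
  Rp[, seq_len(w), ] <- R
  Rp[, w + 1, ] <- R[, 1, ]
  bilinear_sample(Rp, cc, rr)
}

#' Define a synthetic rotating-spheroid scene
#'
#' Fixes everything the renderer needs: the spheroid, its texture, the
#' machine rotation axis (vertical, optionally tilted), an optional
#' misalignment between the fruit's revolution axis and the rotation axis
#' (slip/wobble), and the per-step rotation angles.
#'
#' @param model a [spheroid_model()].
#' @param texture a [make_texture()] object.
#' @param step_angles per-step rotation angles in degrees (default 12 steps
#'   of 30 degrees: 13 views totalling 360).
#' @param axis_tilt_deg tilt of the rotation axis away from the image
#'   vertical, toward the image x-axis (<= 15 in practice).
#' @param misalign_deg angle between the fruit revolution (y) axis and the
#'   rotation axis at the first view.
#' @param noise_sd additive Gaussian image noise (intensity units in [0,1]).
#' @param seed integer seed controlling any stochastic rendering (noise).
#' @return an object of class `synthetic_scene`.
#' @export
synthetic_scene <- function(model, texture, step_angles = rep(30, 12),
                            axis_tilt_deg = 0, misalign_deg = 0,
                            noise_sd = 0, seed = 0L) {
  axis <- c(sin(deg2rad(axis_tilt_deg)), cos(deg2rad(axis_tilt_deg)), 0)
  ## fruit y-axis at view 1: the rotation axis tipped by misalign_deg about z
  vy <- rot_axis_angle(c(0, 0, 1), misalign_deg) %*% axis
  vy <- as.numeric(vy / sqrt(sum(vy^2)))
  vz <- c(0, 0, 1) - sum(c(0, 0, 1) * vy) * vy
  vz <- vz / sqrt(sum(vz^2))
  vx <- c(vy[2] * vz[3] - vy[3] * vz[2],
          vy[3] * vz[1] - vy[1] * vz[3],
          vy[1] * vz[2] - vy[2] * vz[1])
  frame0 <- nearest_rotation(cbind(vx, vy, vz, deparse.level = 0))
  structure(list(model = model, texture = texture, rotation_axis = axis,
                 step_angles = step_angles, frame0 = frame0,
                 axis_tilt_deg = axis_tilt_deg, misalign_deg = misalign_deg,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Render one orthographic view of the scene
#'
#' Flat (unshaded) texture rendering: each pixel's viewing ray is intersected
#' with the rotated spheroid, the hit point is converted to (phi, lam) and the
#' texture sampled there — no photometric effects, so geometric correctness
#' can be tested in isolation. The silhouette is anti-aliased by 2x2
#' supersampling; the mask keeps only fully-covered pixels.
#'
#' @param scene a [synthetic_scene()].
#' @param cumulative_rotation 3x3 rotation applied to the fruit since view 1.
#' @param image_size side of the square view raster (default fits the model
#'   with a 10-pixel margin).
#' @param view_index used only to decorrelate the noise stream per view.
#' @return a list: `image` (`S x S x 3`), `mask`, `gt_lonlat` (`S x S x 2`
#'   array of per-pixel ground-truth (phi, lam), `NA` off the fruit),
#'   `frame` (ground-truth fruit frame at this view).
#' @export
render_view <- function(scene, cumulative_rotation = diag(3), image_size = NULL,
                        view_index = 1L) {
  m <- scene$model
  rmax <- max(m$rx, m$ry, m$rz)
  S <- image_size %||% (2L * ceiling(rmax) + 21L)
  Fr <- nearest_rotation(cumulative_rotation %*% scene$frame0)
  ctr <- (S + 1) / 2
  cols <- rep(seq_len(S), each = S); rows <- rep(seq_len(S), times = S)
  eval_at <- function(dx, dy) {
    x <- cols - ctr + dx; y <- ctr - rows + dy
    z <- surface_height(x, y, m, Fr)
    hit <- !is.na(z)
    XYZ <- cbind(x, y, ifelse(hit, z, 0)) %*% Fr
    lam <- rad2deg(asin(pmin(1, pmax(-1, XYZ[, 2] / m$ry))))
    phi <- rad2deg(atan2(XYZ[, 3] / m$rz, XYZ[, 1] / m$rx))
    rgb <- matrix(0.08, length(x), 3)           # dark machine background
    if (any(hit)) rgb[hit, ] <- texture_sample(scene$texture, phi[hit], lam[hit])
    list(hit = hit, rgb = rgb, phi = phi, lam = lam)
  }
  subs <- list(eval_at(-0.25, -0.25), eval_at(0.25, -0.25),
               eval_at(-0.25, 0.25), eval_at(0.25, 0.25))
  hits <- Reduce(`+`, lapply(subs, function(s) as.numeric(s$hit)))
  rgb <- Reduce(`+`, lapply(subs, `[[`, "rgb")) / 4
  ctr_eval <- eval_at(0, 0)
  img <- array(0, c(S, S, 3))
  for (k in 1:3) img[, , k] <- matrix(rgb[, k], S, S)
  if (scene$noise_sd > 0) {
    img <- with_seed(scene$seed + 1000L + view_index,
                     img + array(rnorm(length(img), 0, scene$noise_sd), dim(img)))
    img <- pmin(pmax(img, 0), 1)
  }
  mask <- matrix(as.numeric(hits == 4), S, S)
  gt <- array(NA_real_, c(S, S, 2))
  gt[, , 1] <- matrix(ifelse(ctr_eval$hit, ctr_eval$phi, NA_real_), S, S)
  gt[, , 2] <- matrix(ifelse(ctr_eval$hit, ctr_eval$lam, NA_real_), S, S)
  list(image = img, mask = mask, gt_lonlat = gt, frame = Fr)
}

#' Render the full synthetic view sequence with ground truth
#'
#' @param scene a [synthetic_scene()].
#' @param image_size passed to [render_view()].
#' @return an object of class `synthetic_bundle`: `views` (list of
#'   [view_obs()] with an extra `gt_lonlat` field), `truth` (list with
#'   `pairwise` rotation matrices, `frames`, `model`, `axis`,
#'   `cumulative_deg`, `spots`, `texture`), `scene`.
#' @export
generate_sequence <- function(scene, image_size = NULL) {
  steps <- scene$step_angles
  if (length(steps) < 1L) stop_spheromap("need at least 2 views")
  n <- length(steps) + 1L
  pairwise <- lapply(steps, function(a) rot_axis_angle(scene$rotation_axis, a))
  views <- vector("list", n)
  frames <- vector("list", n)
  M <- diag(3)
  cum <- c(0, cumsum(steps))
  for (i in seq_len(n)) {
    rv <- render_view(scene, M, image_size, view_index = i)
    ob <- view_obs(rv$image, rv$mask)
    ob$gt_lonlat <- rv$gt_lonlat
    views[[i]] <- ob
    frames[[i]] <- rv$frame
    if (i < n) M <- pairwise[[i]] %*% M
  }
  structure(list(
    views = views,
    truth = list(pairwise = pairwise, frames = frames, model = scene$model,
                 axis = scene$rotation_axis, cumulative_deg = cum,
                 spots = scene$texture$spots, texture = scene$texture),
    scene = scene
  ), class = "synthetic_bundle")
}
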
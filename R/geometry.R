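## Geometry module: spheroid model, silhouette analysis, reference view and
## fruit-frame initialisation, orthographic surface height.

#' Spheroid model of a fruit
#'
#' A spheroid (ellipsoid of revolution) with principal radii `rx`, `ry`, `rz`
#' in pixels. By construction the distinct (revolution) axis is the fruit
#' y-axis, so `rx = rz` always; the geometry class is `"oblate"` when
#' `ry < rx`, `"prolate"` when `ry > rx` and `"spherical"` when all three are
#' equal within `tol_rel`.
#'
#' @param rx,ry,rz principal radii (pixels), strictly positive; `rx` and `rz`
#'   must agree within `tol_rel`.
#' @param geometry_class optional explicit class label; inferred from the
#'   radii when `NULL`.
#' @param tol_rel relative tolerance used to compare radii.
#' @return an object of class `spheroid_model`.
#' @export
spheroid_model <- function(rx, ry, rz = rx, geometry_class = NULL, tol_rel = 0.03) {
  if (any(c(rx, ry, rz) <= 0)) stop_spheromap("spheroid radii must be strictly positive")
  if (abs(rx - rz) > tol_rel * max(rx, rz))
    stop_spheromap("rx and rz must be equal: the revolution axis is the fruit y-axis")
  if (is.null(geometry_class)) {
    r <- (rx + rz) / 2
    geometry_class <- if (abs(ry - r) <= tol_rel * max(ry, r)) "spherical"
                      else if (ry < r) "oblate" else "prolate"
  }
  geometry_class <- match.arg(geometry_class, c("oblate", "spherical", "prolate"))
  structure(list(rx = rx, ry = ry, rz = rz, geometry_class = geometry_class),
            class = "spheroid_model")
}

#' @export
print.spheroid_model <- function(x, ...) {
  cat(sprintf("<spheroid_model> %s  radii (rx, ry, rz) = (%.1f, %.1f, %.1f) px\n",
              x$geometry_class, x$rx, x$ry, x$rz))
  invisible(x)
}

#' Fit the silhouette ellipse of a foreground mask
#'
#' Computes the centroid and the second-moment (best-fit) ellipse of the
#' single large connected foreground component of a binary mask. The ellipse
#' semi-axes are those of the solid ellipse with the same second central
#' moments.
#'
#' @param mask 0/1 (or logical) matrix, row 1 at the top of the image.
#' @param min_pixels minimum size of the foreground component.
#' @return a list with `centroid = c(col, row)` (raster coordinates),
#'   `a`, `b` (semi-major/minor, pixels, `a >= b`), `theta` (orientation of
#'   the major axis in degrees from the image x-axis toward image-up,
#'   in `(-90, 90]`) and `npix`.
#' @export
fit_silhouette <- function(mask, min_pixels = 100L) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) stop_spheromap("empty mask: no foreground pixels", "spheromap_invalid_input")
  lab <- EBImage::bwlabel(m)
  sizes <- tabulate(lab[lab > 0])
  big <- which(sizes >= min_pixels)
  if (length(big) == 0L)
    stop_spheromap(sprintf("no foreground component with >= %d pixels", min_pixels),
                   "spheromap_invalid_input")
  if (length(big) > 1L)
    stop_spheromap("multiple large foreground components: expected a single fruit",
                   "spheromap_invalid_input")
  sel <- lab == big
  idx <- which(sel, arr.ind = TRUE)
  rowc <- idx[, 1]; colc <- idx[, 2]
  cx <- mean(colc); cy <- mean(rowc)
  ## view coordinates: x rightward, y upward
  x <- colc - cx; y <- cy - rowc
  C <- matrix(c(mean(x * x), mean(x * y), mean(x * y), mean(y * y)), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  ## solid ellipse with semi-axes (a, b): second moment along an axis = a^2/4
  a <- 2 * sqrt(max(e$values[1], 0))
  b <- 2 * sqrt(max(e$values[2], 0))
  v <- e$vectors[, 1]
  theta <- rad2deg(atan2(v[2], v[1]))
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  list(centroid = c(col = cx, row = cy), a = a, b = b, theta = theta,
       npix = length(rowc))
}

#' Bundle an image and mask into a view observation
#'
#' Runs [fit_silhouette()] and attaches its result, giving the per-view record
#' (image, mask, centroid, ellipse) the rest of the pipeline consumes.
#'
#' @param image `[h, w, 3]` array in `[0, 1]`.
#' @param mask binary matrix of the same height/width.
#' @param min_pixels passed to [fit_silhouette()].
#' @return an object of class `view_obs`.
#' @export
view_obs <- function(image, mask, min_pixels = 100L) {
  sil <- fit_silhouette(mask, min_pixels = min_pixels)
  structure(list(image = image, mask = matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)),
                 centroid = sil$centroid,
                 ellipse = sil[c("a", "b", "theta")], npix = sil$npix),
            class = "view_obs")
}

## semi-axis lengths along the near-vertical and near-horizontal principal
## directions of a view's silhouette ellipse
silhouette_vh <- function(obs) {
  th <- obs$ellipse$theta
  ## major axis at angle th from x-axis; it is the "vertical" one when
  ## |th| > 45 degrees
  if (abs(th) > 45) c(v = obs$ellipse$a, h = obs$ellipse$b)
  else c(v = obs$ellipse$b, h = obs$ellipse$a)
}

#' Classify the fruit geometry from a view sequence
#'
#' Decides oblate / spherical / prolate from the silhouette ellipses of at
#' least three views. The fruit rotates about a near-vertical axis, so the
#' silhouette semi-axis along the near-vertical principal direction tracks the
#' distinct (revolution) radius and stays stable across views, while the
#' horizontal one tracks the common radius.
#'
#' @param views list of [view_obs()] objects (>= 3).
#' @param tol_rel relative circularity tolerance: spherical when
#'   `(a - b)/a <= tol_rel` in every view.
#' @return `"oblate"`, `"spherical"` or `"prolate"`.
#' @export
classify_geometry <- function(views, tol_rel = 0.03) {
  if (length(views) < 3L)
    stop_spheromap("geometry classification needs at least 3 views",
                   "spheromap_invalid_input")
  ecc <- vapply(views, function(o) (o$ellipse$a - o$ellipse$b) / o$ellipse$a, 0)
  if (max(ecc) <= tol_rel) return("spherical")
  vh <- vapply(views, silhouette_vh, c(v = 0, h = 0))
  if (median(vh["v", ]) < median(vh["h", ])) "oblate" else "prolate"
}

#' Select the reference view
#'
#' The reference view is where the fruit frame is initialised: the first view
#' for spherical fruit; for oblate fruit the view with the shortest silhouette
#' semi-minor axis, and for prolate fruit the view with the longest semi-major
#' axis — both are the views where the distinct axis lies in the image plane.
#' Ties break toward the earliest view.
#'
#' @param views list of [view_obs()] objects.
#' @param geometry_class as returned by [classify_geometry()].
#' @return the 1-based index of the reference view.
#' @export
select_reference_view <- function(views, geometry_class) {
  switch(geometry_class,
    spherical = 1L,
    oblate = which.min(vapply(views, function(o) o$ellipse$b, 0)),
    prolate = which.max(vapply(views, function(o) o$ellipse$a, 0)),
    stop_spheromap("unknown geometry class")
  )
}

#' Estimate the spheroid radii from the silhouettes
#'
#' The common radius (`rx = rz`) is the median across views of the silhouette
#' semi-axis along the near-horizontal principal direction (the direction the
#' rotation sweeps); the distinct radius `ry` is the near-vertical semi-axis
#' at the reference view, where the distinct axis lies in the image plane.
#' Medians make the estimate robust to segmentation noise in single views.
#'
#' @param views list of [view_obs()] objects.
#' @param geometry_class geometry label.
#' @param ref_index reference view index from [select_reference_view()].
#' @param tol_rel passed through to [spheroid_model()].
#' @return a [spheroid_model()].
#' @export
estimate_radii <- function(views, geometry_class, ref_index, tol_rel = 0.03) {
  vh <- vapply(views, silhouette_vh, c(v = 0, h = 0))
  if (geometry_class == "spherical") {
    r <- median(c(vh))
    return(spheroid_model(r, r, r, "spherical", tol_rel = tol_rel))
  }
  common <- unname(median(vh["h", ]))
  ry <- unname(vh["v", ref_index])
  spheroid_model(common, ry, common, geometry_class, tol_rel = 1)
}

#' Initialise the fruit-centric axis frame at the reference view
#'
#' Returns the 3x3 matrix whose columns are the fruit axis unit vectors
#' (vx, vy, vz) in view coordinates. vz is always `(0, 0, 1)` (toward the
#' camera). For spherical fruit the frame is the identity (fruit axes aligned
#' with the view axes). Otherwise vy is the in-plane unit vector along the
#' silhouette principal direction making the smaller angle with the image
#' vertical — the expected rotation axis given the machine geometry — with its
#' sign chosen to point up; vx completes the right-handed triad (both vx and
#' vy lie in the image plane at the reference view).
#'
#' @param ref_view a [view_obs()].
#' @param geometry_class geometry label.
#' @param tol_rel circularity tolerance below which a non-spherical label
#'   falls back to the identity frame (with a warning).
#' @return a 3x3 rotation matrix with columns (vx, vy, vz), determinant +1.
#' @export
init_fruit_frame <- function(ref_view, geometry_class, tol_rel = 0.03) {
  if (geometry_class == "spherical") return(diag(3))
  a <- ref_view$ellipse$a; b <- ref_view$ellipse$b
  if ((a - b) / a <= tol_rel) {
    warning("reference silhouette nearly circular: falling back to a vertical fruit y-axis")
    return(diag(3))
  }
  th <- deg2rad(ref_view$ellipse$theta)
  major <- c(cos(th), sin(th))
  minor <- c(-sin(th), cos(th))
  ## the principal direction closer to the vertical (ties favour the major
  ## axis, i.e. exactly-45-degree silhouettes take the major direction)
  vy2 <- if (abs(major[2]) >= abs(minor[2])) major else minor
  if (vy2[2] < 0) vy2 <- -vy2
  vy <- c(vy2, 0)
  vz <- c(0, 0, 1)
  vx <- c(vy[2] * vz[3] - vy[3] * vz[2],
          vy[3] * vz[1] - vy[1] * vz[3],
          vy[1] * vz[2] - vy[2] * vz[1])
  F <- cbind(vx, vy, vz, deparse.level = 0)
  nearest_rotation(F)
}

#' Orthographic surface height above a view point
#'
#' For a view point `(x, y)` relative to the fruit centroid, intersects the
#' orthographic viewing ray `(x, y, t)` with the fruit-frame ellipsoid
#' `(X/rx)^2 + (Y/ry)^2 + (Z/rz)^2 = 1` and returns the camera-side (largest
#' `t`) intersection. `NA` where the ray misses the spheroid (the point lies
#' outside the silhouette) — a no-intersection signal, not an error.
#'
#' @param x,y numeric vectors of view coordinates (pixels, x rightward,
#'   y upward, origin at the centroid).
#' @param model a [spheroid_model()].
#' @param frame fruit frame at this view (3x3, columns vx, vy, vz).
#' @return numeric vector of heights `z` (pixels); positive inside the
#'   silhouette, `NA` outside.
#' @export
surface_height <- function(x, y, model, frame = diag(3)) {
  A <- c(1 / model$rx^2, 1 / model$ry^2, 1 / model$rz^2)
  u <- frame[3, ]                       # components of e_z on the fruit axes
  w1 <- outer(x, frame[1, ]) + outer(y, frame[2, ])  # n x 3
  a <- sum(A * u^2)
  b <- 2 * (w1 %*% (A * u))
  cc <- (w1^2 %*% A) - 1
  disc <- b^2 - 4 * a * cc
  z <- rep(NA_real_, length(x))
  ok <- disc >= 0
  z[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a)
  z
}
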
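## Small numeric / rotation / raster helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

## round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

stop_spheromap <- function(msg, class = "spheromap_error") {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "spheromap_error", "error", "condition")
  ))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula for the rotation of `angle_deg` degrees about the unit
#' direction `axis` (normalised internally). Positive angles follow the
#' right-hand rule.
#'
#' @param axis numeric length-3 direction (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Project a near-rotation matrix onto the nearest rotation
#'
#' Polar projection via SVD; used to remove orthogonality drift accumulated
#' when chaining many rotations.
#'
#' @param M a 3x3 matrix close to a rotation.
#' @return the closest (Frobenius) 3x3 matrix with `R'R = I`, `det R = +1`.
#' @export
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Geodesic angle between two rotations
#'
#' The angle (degrees) of the relative rotation `R1' R2`; the standard
#' rotation-recovery error metric.
#'
#' @param R1,R2 3x3 rotation matrices (`R2` defaults to the identity).
#' @return angle in degrees, in `[0, 180]`.
#' @export
geodesic_angle <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
}

## rotation logarithm: axis-angle vector (radians)
rot_log <- function(R) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (abs(pi - ang) < 1e-6) {
    ## near 180 deg the skew part vanishes; recover axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    ax <- B[, k] / ax[k]
    return(ang * ax / sqrt(sum(ax^2)))
  }
  ang * w / (2 * sin(ang))
}

rot_exp <- function(w) {
  ang <- sqrt(sum(w^2))
  if (ang < 1e-12) return(diag(3))
  rot_axis_angle(w / ang, rad2deg(ang))
}

#' Geodesic mean of rotations
#'
#' Intrinsic (Karcher) mean on SO(3), used to substitute a pairwise rotation
#' whose estimation failed with the mean of its neighbours.
#'
#' @param Rs list of 3x3 rotation matrices.
#' @return a 3x3 rotation matrix.
#' @export
rotation_mean <- function(Rs) {
  if (length(Rs) == 1L) return(Rs[[1L]])
  R <- Rs[[1L]]
  for (it in 1:20) {
    w <- Reduce(`+`, lapply(Rs, function(Q) rot_log(crossprod(R, Q)))) / length(Rs)
    if (sqrt(sum(w^2)) < 1e-12) break
    R <- R %*% rot_exp(w)
  }
  nearest_rotation(R)
}

## ---- raster helpers -------------------------------------------------------
## images are arrays [row, col, channel] in [0,1]; masks are 0/1 matrices.

#' Bilinear raster sampling
#'
#' Samples an image or matrix at fractional raster coordinates
#' (`col`, `row`), with row 1 the top row. Out-of-range coordinates return
#' `NA`.
#'
#' @param img matrix or `[h, w, 3]` array.
#' @param col,row numeric vectors of fractional column/row positions
#'   (pixel centres at integers).
#' @return a numeric vector (matrix input) or n x 3 matrix (array input).
#' @export
bilinear_sample <- function(img, col, row) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  c0 <- floor(col); r0 <- floor(row)
  fc <- col - c0; fr <- row - r0
  ok <- c0 >= 1 & c0 <= w - 1 & r0 >= 1 & r0 <= h - 1
  ## clamp indices so arithmetic stays legal; mask afterwards
  c0c <- pmin(pmax(c0, 1), w - 1); r0c <- pmin(pmax(r0, 1), h - 1)
  i00 <- r0c + (c0c - 1) * h
  w00 <- (1 - fc) * (1 - fr); w10 <- fc * (1 - fr)
  w01 <- (1 - fc) * fr;       w11 <- fc * fr
  one <- function(m) {
    v <- m[i00] * w00 + m[i00 + h] * w10 + m[i00 + 1] * w01 + m[i00 + h + 1] * w11
    v[!ok] <- NA_real_
    v
  }
  if (length(d) == 2L) return(one(img))
  out <- matrix(NA_real_, length(col), d[3])
  for (k in seq_len(d[3])) out[, k] <- one(img[, , k])
  out
}

## nearest-neighbour sampling, same interface
nearest_sample <- function(img, col, row) {
  d <- dim(img)
  h <- d[1]; w <- d[2]
  ci <- round(col); ri <- round(row)
  ok <- ci >= 1 & ci <= w & ri >= 1 & ri <= h
  cic <- pmin(pmax(ci, 1), w); ric <- pmin(pmax(ri, 1), h)
  idx <- ric + (cic - 1) * h
  one <- function(m) { v <- m[idx]; v[!ok] <- NA_real_; v }
  if (length(d) == 2L) return(one(img))
  out <- matrix(NA_real_, length(col), d[3])
  for (k in seq_len(d[3])) out[, k] <- one(img[, , k])
  out
}

## shift a matrix by (dr, dc) with edge replication
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1), w)
  m[ri, ci, drop = FALSE]
}

## separable convolution with an odd-length kernel, replicate padding
conv_sep <- function(m, kernel) {
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel)) out <- out + kernel[j] * shift_mat(m, j - 1L - r, 0L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kernel)) out <- out + kernel[j] * shift_mat(m2, 0L, j - 1L - r)
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## TRUE where m equals the max of its (2r+1)^2 neighbourhood
local_maxima <- function(m, r = 2L) {
  mx <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0L && dc == 0L) next
    mx <- pmax(mx, shift_mat(m, dr, dc))
  }
  m >= mx
}

## fraction of the (2r+1)^2 box that lies inside the mask (box filter)
box_mean <- function(mask, r) {
  k <- rep(1 / (2 * r + 1), 2 * r + 1)
  conv_sep(mask, k)
}
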
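## Rotation module: pairwise 3D rotation estimation from texture, rotation
## chaining, frame propagation.
##
## The estimator back-projects matched texture keypoints onto the spheroid and
## solves the absolute-orientation problem on the two 3D point sets. It needs
## visible texture and inter-view rotations small enough (roughly 20-40
## degrees) that consecutive views share content.

## ---- keypoints ------------------------------------------------------------

## Harris corners inside the (eroded) mask; returns col/row raster coords.
detect_keypoints <- function(image, mask, max_points = 300L, patch_radius = 5L,
                             sigma_d = 1, sigma_i = 2, k = 0.05) {
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  g <- conv_sep(g, gaussian_kernel(sigma_d))
  Ix <- (shift_mat(g, 0L, -1L) - shift_mat(g, 0L, 1L)) / 2
  Iy <- (shift_mat(g, -1L, 0L) - shift_mat(g, 1L, 0L)) / 2   # image-up gradient sign irrelevant
  kk <- gaussian_kernel(sigma_i)
  Sxx <- conv_sep(Ix * Ix, kk); Syy <- conv_sep(Iy * Iy, kk); Sxy <- conv_sep(Ix * Iy, kk)
  R <- Sxx * Syy - Sxy^2 - k * (Sxx + Syy)^2
  inside <- box_mean(mask, patch_radius + 2L) > 0.999
  R[!inside] <- -Inf
  cand <- local_maxima(R, 2L) & R > 0
  if (!any(cand)) return(cbind(col = numeric(0), row = numeric(0)))
  thr <- 0.005 * max(R[cand])
  cand <- cand & R >= thr
  idx <- which(cand, arr.ind = TRUE)
  ord <- order(R[cand], decreasing = TRUE)
  idx <- idx[head(ord, max_points), , drop = FALSE]
  cbind(col = idx[, 2], row = idx[, 1])
}

## normalized grayscale patch descriptors; rows are unit vectors
patch_descriptors <- function(image, kp, patch_radius = 5L) {
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  n <- nrow(kp)
  side <- 2L * patch_radius + 1L
  D <- matrix(0, n, side * side)
  offs <- expand.grid(dr = -patch_radius:patch_radius, dc = -patch_radius:patch_radius)
  h <- nrow(g)
  base <- kp[, "row"] + (kp[, "col"] - 1) * h
  for (j in seq_len(nrow(offs)))
    D[, j] <- g[base + offs$dr[j] + offs$dc[j] * h]
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm < 1e-8] <- 1
  D / nrm
}

## mutual-best NCC matches above a floor; returns index pairs + scores
match_descriptors <- function(Da, Db, min_ncc = 0.5) {
  if (nrow(Da) == 0L || nrow(Db) == 0L)
    return(cbind(a = integer(0), b = integer(0), ncc = numeric(0)))
  C <- Da %*% t(Db)
  ba <- max.col(C)                       # best b for each a
  ab <- max.col(t(C))                    # best a for each b
  a <- seq_len(nrow(Da))
  keep <- ab[ba] == a & C[cbind(a, ba)] >= min_ncc
  cbind(a = a[keep], b = ba[keep], ncc = C[cbind(a, ba)][keep])
}

## absolute orientation about a fixed origin (Kabsch): q ~ R p
kabsch_origin <- function(P, Q) {
  H <- crossprod(Q, P)    # 3x3: sum q_i p_i'
  s <- svd(H)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Estimate the 3D rotation between two consecutive views
#'
#' Detects and matches local texture keypoints between the two masked views,
#' back-projects each match to 3D with [surface_height()] (the second view is
#' back-projected with the same frame — exact when the fruit spins about its
#' revolution axis, since that rotation leaves the view-space quadric
#' unchanged), then solves the absolute-orientation problem on the two 3D
#' point sets with a random 3-point consensus search followed by a refit on
#' the inliers.
#'
#' @param view_a,view_b [view_obs()] objects for views i and i+1.
#' @param model a [spheroid_model()].
#' @param frame_a fruit frame at view a.
#' @param max_points,min_ncc keypoint budget and match acceptance floor.
#' @param ransac_iter number of 3-point consensus samples.
#' @param inlier_tol inlier residual threshold as a fraction of the largest
#'   radius (3D distance).
#' @param min_inliers below this many inliers the estimation is declared
#'   failed (`ok = FALSE`) rather than returning a poor rotation.
#' @param seed integer seed for the consensus sampler (deterministic runs).
#' @return a list: `R` (3x3 rotation or `NULL`), `ok`, `n_inliers`,
#'   `rmse` (inlier residual, pixels), `n_matches`.
#' @export
estimate_pairwise_rotation <- function(view_a, view_b, model, frame_a,
                                       max_points = 300L, min_ncc = 0.5,
                                       ransac_iter = 600L, inlier_tol = 0.05,
                                       min_inliers = 6L, seed = 0L) {
  failed <- function(nm) list(R = NULL, ok = FALSE, n_inliers = 0L,
                              rmse = NA_real_, n_matches = nm)
  pr <- 5L
  kpa <- detect_keypoints(view_a$image, view_a$mask, max_points, pr)
  kpb <- detect_keypoints(view_b$image, view_b$mask, max_points, pr)
  if (nrow(kpa) < min_inliers || nrow(kpb) < min_inliers) return(failed(0L))
  Da <- patch_descriptors(view_a$image, kpa, pr)
  Db <- patch_descriptors(view_b$image, kpb, pr)
  mm <- match_descriptors(Da, Db, min_ncc)
  if (nrow(mm) < min_inliers) return(failed(nrow(mm)))
  ## raster -> view coordinates, then back-project to 3D
  to3d <- function(kp, centroid) {
    x <- kp[, "col"] - centroid["col"]
    y <- centroid["row"] - kp[, "row"]
    z <- surface_height(x, y, model, frame_a)
    cbind(x, y, z)
  }
  P <- to3d(kpa[mm[, "a"], , drop = FALSE], view_a$centroid)
  Q <- to3d(kpb[mm[, "b"], , drop = FALSE], view_b$centroid)
  rmax <- max(model$rx, model$ry, model$rz)
  keep <- !is.na(P[, 3]) & !is.na(Q[, 3]) &
    P[, 3] > 0.05 * rmax & Q[, 3] > 0.05 * rmax
  P <- P[keep, , drop = FALSE]; Q <- Q[keep, , drop = FALSE]
  n <- nrow(P)
  if (n < min_inliers) return(failed(n))

  tol <- inlier_tol * rmax
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  best_inl <- logical(n); best_count <- 0L
  for (it in seq_len(ransac_iter)) {
    s <- sample.int(n, 3L)
    R <- kabsch_origin(P[s, , drop = FALSE], Q[s, , drop = FALSE])
    res <- sqrt(rowSums((Q - P %*% t(R))^2))
    inl <- res < tol
    if (sum(inl) > best_count) { best_count <- sum(inl); best_inl <- inl }
  }
  if (best_count < min_inliers) return(failed(n))
  R <- kabsch_origin(P[best_inl, , drop = FALSE], Q[best_inl, , drop = FALSE])
  ## one re-scoring pass tightens the inlier set after the refit
  res <- sqrt(rowSums((Q - P %*% t(R))^2))
  inl <- res < tol
  if (sum(inl) >= min_inliers)
    R <- kabsch_origin(P[inl, , drop = FALSE], Q[inl, , drop = FALSE])
  else inl <- best_inl
  list(R = nearest_rotation(R), ok = TRUE, n_inliers = sum(inl),
       rmse = sqrt(mean(res[inl]^2)), n_matches = n)
}

## ---- chaining -------------------------------------------------------------

#' Rotation chain over a view sequence
#'
#' @param pairwise list of 3x3 rotation matrices, element i mapping view i to
#'   view i+1 (`length = n_views - 1`).
#' @param reference_index 1-based index of the reference view.
#' @return an object of class `rotation_chain`.
#' @export
rotation_chain <- function(pairwise, reference_index = 1L) {
  for (R in pairwise) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
      stop_spheromap("pairwise matrices must be rotations (orthogonal, det +1)")
  }
  structure(list(pairwise = pairwise, reference_index = as.integer(reference_index),
                 n_views = length(pairwise) + 1L),
            class = "rotation_chain")
}

#' Chain pairwise rotations between two views
#'
#' Returns the rotation taking view `i` to view `j`: the product of the
#' consecutive pairwise rotations for `j > i`, the transposed product for
#' `j < i`, and the identity for `j = i`. The result is re-projected onto the
#' nearest rotation whenever orthogonality drift exceeds 1e-9, so chains of a
#' dozen links stay numerically orthonormal.
#'
#' @param chain a [rotation_chain()].
#' @param i,j 1-based view indices.
#' @return a 3x3 rotation matrix.
#' @export
chain_rotations <- function(chain, i, j) {
  n <- chain$n_views
  if (i < 1L || i > n || j < 1L || j > n)
    stop_spheromap("view index out of range", "spheromap_invalid_input")
  if (i == j) return(diag(3))
  if (j < i) return(t(chain_rotations(chain, j, i)))
  acc <- diag(3)
  for (k in i:(j - 1L)) acc <- chain$pairwise[[k]] %*% acc
  if (max(abs(crossprod(acc) - diag(3))) > 1e-9) acc <- nearest_rotation(acc)
  acc
}

#' Propagate the fruit frame from the reference view to any view
#'
#' Each fruit axis rotates rigidly with the fruit, so the axes at view `j`
#' are the reference axes rotated by the chained view-to-view rotation.
#'
#' @param frame_ref 3x3 fruit frame at the chain's reference view.
#' @param chain a [rotation_chain()].
#' @param j target view index.
#' @return the 3x3 fruit frame at view `j`.
#' @export
propagate_frame <- function(frame_ref, chain, j) {
  R <- chain_rotations(chain, chain$reference_index, j)
  nearest_rotation(R %*% frame_ref)
}

#' Estimate the full rotation chain of a sequence
#'
#' Runs [estimate_pairwise_rotation()] on every consecutive pair. A failed
#' pair is substituted with the geodesic mean of its neighbouring pairwise
#' rotations (or a copy of the single neighbour); if every pair fails the
#' chain cannot be built and an error is raised.
#'
#' @param views list of [view_obs()] objects.
#' @param model a [spheroid_model()].
#' @param frame_ref fruit frame at `reference_index`.
#' @param reference_index reference view index.
#' @param seed integer; pair k uses `seed + k` for its consensus sampler.
#' @param ... passed to [estimate_pairwise_rotation()].
#' @return a list: `chain` (a [rotation_chain()]) and `qc`, a data.frame with
#'   per-pair inlier counts, residuals and substitution flags.
#' @export
estimate_rotation_chain <- function(views, model, frame_ref, reference_index = 1L,
                                    seed = 0L, ...) {
  n <- length(views)
  ests <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    fr_k <- frame_ref   # frames refined after chaining; see vignette
    ests[[k]] <- estimate_pairwise_rotation(views[[k]], views[[k + 1L]], model,
                                            fr_k, seed = seed + k, ...)
  }
  ok <- vapply(ests, `[[`, TRUE, "ok")
  if (!any(ok))
    stop_spheromap("rotation estimation failed for every view pair; cannot build the map")
  Rs <- lapply(ests, `[[`, "R")
  subst <- !ok
  for (k in which(!ok)) {
    nb <- Filter(Negate(is.null), list(if (k > 1L) Rs[[k - 1L]],
                                       if (k < n - 1L) Rs[[k + 1L]]))
    if (length(nb) == 0L) {
      ## no direct neighbour available yet: borrow the nearest estimated pair
      near <- which(ok)[which.min(abs(which(ok) - k))]
      nb <- list(Rs[[near]])
    }
    Rs[[k]] <- rotation_mean(nb)
  }
  qc <- data.frame(
    pair = seq_len(n - 1L),
    ok = ok,
    substituted = subst,
    n_matches = vapply(ests, `[[`, 0L, "n_matches"),
    n_inliers = vapply(ests, `[[`, 0L, "n_inliers"),
    rmse = vapply(ests, `[[`, 0, "rmse")
  )
  list(chain = rotation_chain(Rs, reference_index), qc = qc)
}
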
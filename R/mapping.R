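## Mapping module: map<->view correspondence, longitude schedule, blending,
## map dimensioning, map filling, per-pixel surface area and surface
## fractions.

#' Surface point for a longitude/latitude pair
#'
#' The equirectangular parametrisation of the spheroid:
#' `X = rx cos(lam) cos(phi)`, `Y = ry sin(lam)`, `Z = rz cos(lam) sin(phi)`,
#' in fruit-frame coordinates.
#'
#' @param phi,lam longitude and latitude in degrees (vectorised).
#' @param model a [spheroid_model()].
#' @return an `n x 3` matrix with columns X, Y, Z (pixels).
#' @export
lonlat_to_surface <- function(phi, lam, model) {
  p <- deg2rad(phi); l <- deg2rad(lam)
  cbind(X = model$rx * cos(l) * cos(p),
        Y = model$ry * sin(l),
        Z = model$rz * cos(l) * sin(p))
}

#' Project a fruit-frame surface point into a view
#'
#' The view position of a surface point is the linear combination of the
#' fruit axis vectors at that view with coefficients (X, Y, Z); the point is
#' visible in the view when its z component (toward the camera) is positive.
#'
#' @param point length-3 vector or `n x 3` matrix of fruit-frame coordinates.
#' @param frame fruit frame at the view (3x3, columns vx, vy, vz).
#' @return an `n x 4` matrix with columns `x`, `y`, `z` (view coordinates,
#'   pixels) and `visible` (0/1).
#' @export
surface_to_view <- function(point, frame) {
  P <- if (is.matrix(point)) point else matrix(point, 1)
  v <- P %*% t(frame)
  cbind(x = v[, 1], y = v[, 2], z = v[, 3], visible = as.numeric(v[, 3] > 0))
}

#' Longitude/latitude of a view point
#'
#' Back-projects a view point to the visible spheroid surface with
#' [surface_height()], expresses it on the fruit axes and inverts the
#' equirectangular parametrisation: `lam = asin(Y/ry)`,
#' `phi = atan2(Z/rz, X/rx)` in `(-180, 180]`. Longitude unwrapping across
#' views is the schedule's job, not this function's.
#'
#' @param x,y view coordinates (pixels, vectorised).
#' @param model a [spheroid_model()].
#' @param frame fruit frame at the view.
#' @return a two-column matrix `phi`, `lam` in degrees; `NA` rows where the
#'   point lies outside the silhouette.
#' @export
view_to_lonlat <- function(x, y, model, frame = diag(3)) {
  z <- surface_height(x, y, model, frame)
  XYZ <- cbind(x, y, z) %*% frame       # dot products with the axis columns
  lam <- rad2deg(asin(pmin(1, pmax(-1, XYZ[, 2] / model$ry))))
  phi <- rad2deg(atan2(XYZ[, 3] / model$rz, XYZ[, 1] / model$rx))
  phi[!is.na(phi) & phi <= -180] <- phi[!is.na(phi) & phi <= -180] + 360
  cbind(phi = phi, lam = lam)
}

#' Longitude schedule of a view sequence
#'
#' Computes the map longitude of each view's central point (the fruit
#' centroid, view coordinates (0, 0)) and unwraps the sequence so it is
#' strictly increasing: whenever `L[i+1] <= L[i]`, 360 degrees are added to
#' `L[i+1]` and all subsequent longitudes. The map is extended by `preroll`
#' degrees before `L[1]` and `postroll` after `L[N]`; those ranges are filled
#' from the first/last view alone.
#'
#' @param views list of [view_obs()] (only the length is used).
#' @param model a [spheroid_model()].
#' @param frames list of fruit frames, one per view.
#' @param preroll,postroll extensions in degrees (>= 0).
#' @return an object of class `longitude_schedule`: `L` (degrees, strictly
#'   increasing), `preroll`, `postroll`.
#' @export
compute_longitude_schedule <- function(views, model, frames, preroll = 45,
                                       postroll = 45) {
  if (preroll < 0 || postroll < 0)
    stop_spheromap("preroll and postroll must be non-negative")
  L <- vapply(frames, function(F) view_to_lonlat(0, 0, model, F)[1, "phi"], 0)
  L <- unwrap_longitudes(L)
  structure(list(L = L, preroll = preroll, postroll = postroll),
            class = "longitude_schedule")
}

## strictly-increasing unwrap: add 360 to L[i+1..] while L[i+1] <= L[i]
unwrap_longitudes <- function(L) {
  for (i in seq_along(L)[-1]) {
    while (L[i] <= L[i - 1]) L[i:length(L)] <- L[i:length(L)] + 360
  }
  L
}

#' @export
print.longitude_schedule <- function(x, ...) {
  cat(sprintf("<longitude_schedule> %d views, L = %.1f .. %.1f deg (+%g/-%g roll)\n",
              length(x$L), x$L[1], x$L[length(x$L)], x$preroll, x$postroll))
  invisible(x)
}

#' Blending weights at a longitude
#'
#' Between consecutive central longitudes the two bracketing views blend
#' linearly: for `L[i] <= phi <= L[i+1]`,
#' `w_i = (L[i+1] - phi) / (L[i+1] - L[i])` and `w_{i+1} = 1 - w_i`.
#' In the pre-roll (`phi < L[1]`) only the first view contributes, in the
#' post-roll (`phi > L[N]`) only the last.
#'
#' @param phi scalar longitude in degrees.
#' @param schedule a [compute_longitude_schedule()] result.
#' @return a data.frame with columns `view` and `weight` (weights sum to 1;
#'   zero-weight entries are dropped).
#' @export
blend_weights <- function(phi, schedule) {
  L <- schedule$L; n <- length(L)
  if (phi < L[1] - schedule$preroll || phi > L[n] + schedule$postroll)
    stop_spheromap("longitude outside the extended map span",
                   "spheromap_invalid_input")
  if (phi <= L[1]) return(data.frame(view = 1L, weight = 1))
  if (phi >= L[n]) return(data.frame(view = n, weight = 1))
  i <- findInterval(phi, L)
  wi <- (L[i + 1] - phi) / (L[i + 1] - L[i])
  out <- data.frame(view = c(i, i + 1L), weight = c(wi, 1 - wi))
  out[out$weight > 0, , drop = FALSE]
}

#' Angular step for 1-pixel equator resolution
#'
#' One map pixel spans `beta = 1/R` radians, so that at the equator of a
#' fruit of largest radius `R` pixels the map resolution equals the view
#' resolution.
#'
#' @param R_max largest fruit radius in pixels.
#' @return the angular step in radians per pixel.
#' @export
angular_step <- function(R_max) {
  if (R_max <= 0) stop_spheromap("radius must be positive")
  1 / R_max
}

#' Map raster dimensions for an angular step
#'
#' @param beta angular step (radians per pixel).
#' @param span_deg longitude span of the map in degrees.
#' @param lambda_max latitude crop in degrees, or `NULL` for the full
#'   pole-to-pole height.
#' @return `c(rows, cols)`; dimensions round half away from zero.
#' @export
map_dimensions <- function(beta, span_deg = 360, lambda_max = NULL) {
  rows <- if (is.null(lambda_max)) pi / beta else 2 * deg2rad(lambda_max) / beta
  cols <- deg2rad(span_deg) / beta
  c(rows = as.integer(round_half_away(rows)), cols = as.integer(round_half_away(cols)))
}

#' Fill the surface map from the views
#'
#' Builds the fused equirectangular map. For every map pixel inside the
#' latitude crop, the fruit-frame surface point is computed from (phi, lam),
#' the one or two scheduled views for that longitude are projected to with
#' [surface_to_view()], invisible contributions (z <= 0, or sampling outside
#' the view's mask) are dropped with the surviving weight renormalised to 1,
#' and the output pixel is the weighted sum of the (bilinear) view samples.
#' Each pixel touches at most two views. Rows beyond the latitude crop and
#' pixels with no visible contribution get the background fill.
#'
#' @param views list of [view_obs()] objects.
#' @param model a [spheroid_model()].
#' @param frames list of fruit frames, one per view.
#' @param schedule a [compute_longitude_schedule()] result.
#' @param beta angular step (radians/pixel), e.g. [angular_step()] of the
#'   largest radius.
#' @param lambda_max latitude crop in degrees; the raster still spans the
#'   full -90..90 so the polar bands appear as background.
#' @param interp `"bilinear"` or `"nearest"` view sampling.
#' @param background RGB background fill in `[0, 1]` (mid-gray).
#' @return an object of class `surface_map`: `pixels` (`rows x cols x 3`),
#'   `coverage` (contributing-view count, 0/1/2), `beta`, `lambda_max`,
#'   `lon`, `lat` (pixel-centre coordinates, degrees), `lon_start`,
#'   `lon_end`, `schedule`, `model`.
#' @export
fill_map <- function(views, model, frames, schedule, beta,
                     lambda_max = 60, interp = c("bilinear", "nearest"),
                     background = c(0.5, 0.5, 0.5)) {
  interp <- match.arg(interp)
  if (length(schedule$L) == 0L) stop_spheromap("empty longitude schedule")
  L <- schedule$L; nv <- length(L)
  lon_start <- L[1] - schedule$preroll
  lon_end <- L[nv] + schedule$postroll
  bdeg <- rad2deg(beta)
  dims <- map_dimensions(beta, lon_end - lon_start, NULL)
  nr <- dims["rows"]; nc <- dims["cols"]
  lon <- lon_start + (seq_len(nc) - 0.5) * bdeg
  lat <- 90 - (seq_len(nr) - 0.5) * bdeg
  active_rows <- which(abs(lat) < lambda_max)

  ## per-column contributing views and weights (at most two)
  v1 <- integer(nc); w1 <- numeric(nc); v2 <- integer(nc); w2 <- numeric(nc)
  pre <- lon <= L[1]; post <- lon >= L[nv]
  v1[pre] <- 1L; w1[pre] <- 1
  v1[post] <- nv; w1[post] <- 1
  mid <- !pre & !post
  if (any(mid)) {
    i <- findInterval(lon[mid], L)
    wi <- (L[i + 1] - lon[mid]) / (L[i + 1] - L[i])
    v1[mid] <- i; w1[mid] <- wi
    v2[mid] <- i + 1L; w2[mid] <- 1 - wi
  }

  nact <- length(active_rows)
  acc <- array(0, c(nact, nc, 3))
  wsum <- matrix(0, nact, nc)
  cover <- matrix(0L, nact, nc)
  sampler <- if (interp == "bilinear") bilinear_sample else nearest_sample

  for (v in seq_len(nv)) {
    colw <- numeric(nc)
    colw[v1 == v] <- w1[v1 == v]
    colw[v2 == v] <- w2[v2 == v]
    cols <- which(colw > 0)
    if (length(cols) == 0L) next
    grid_phi <- rep(lon[cols], each = nact)
    grid_lam <- rep(lat[active_rows], times = length(cols))
    S <- lonlat_to_surface(grid_phi, grid_lam, model)
    pv <- S %*% t(frames[[v]])
    vis <- pv[, 3] > 0
    obs <- views[[v]]
    pc <- obs$centroid["col"] + pv[, 1]
    prw <- obs$centroid["row"] - pv[, 2]
    inmask <- rep(FALSE, length(vis))
    inmask[vis] <- !is.na(nearest_sample(obs$mask, pc[vis], prw[vis])) &
      nearest_sample(obs$mask, pc[vis], prw[vis]) > 0.5
    use <- vis & inmask
    if (!any(use)) next
    rgb <- matrix(NA_real_, length(vis), 3)
    rgb[use, ] <- sampler(obs$image, pc[use], prw[use])
    use <- use & !is.na(rgb[, 1])
    w <- rep(colw[cols], each = nact) * use
    wm <- matrix(w, nact, length(cols))
    for (k in 1:3) {
      ch <- matrix(ifelse(use, rgb[, k], 0) * w, nact, length(cols))
      acc[, cols, k] <- acc[, cols, k] + ch
    }
    wsum[, cols] <- wsum[, cols] + wm
    cover[, cols] <- cover[, cols] + matrix(as.integer(use & w > 0), nact, length(cols))
  }

  pixels <- array(rep(background, each = nr * nc), c(nr, nc, 3))
  covered <- wsum > 0
  for (k in 1:3) {
    ch <- matrix(background[k], nact, nc)
    ch[covered] <- acc[, , k][covered] / wsum[covered]
    full <- pixels[, , k]
    full[active_rows, ] <- ch
    pixels[, , k] <- full
  }
  coverage <- matrix(0L, nr, nc)
  coverage[active_rows, ] <- cover

  structure(list(pixels = pixels, coverage = coverage, beta = beta,
                 lambda_max = lambda_max, lon = lon, lat = lat,
                 lon_start = lon_start, lon_end = lon_end,
                 schedule = schedule, model = model),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf(paste0("<surface_map> %d x %d px, beta = %.5f rad/px, ",
                     "lon %.1f..%.1f deg, |lat| < %g deg\n"),
              nrow(x$coverage), ncol(x$coverage), x$beta,
              x$lon_start, x$lon_end, x$lambda_max))
  invisible(x)
}

#' Surface area of a map pixel
#'
#' The true spheroid surface area of the patch
#' `[phi, phi + beta] x [lam, lam + beta]`. Spheres use the closed form
#' `r^2 * beta * (sin(lam + beta) - sin(lam))`; general spheroids integrate
#' the first fundamental form of the equirectangular parametrisation with a
#' 2-point Gauss rule per axis. Latitude cells are clipped to +/-90 degrees.
#'
#' @param lam,phi lower-corner latitude/longitude of the cell (degrees,
#'   vectorised).
#' @param model a [spheroid_model()].
#' @param beta angular step (radians).
#' @return patch areas in squared pixels.
#' @export
pixel_area <- function(lam, phi, model, beta) {
  n <- max(length(lam), length(phi))
  lam <- rep_len(deg2rad(lam), n); phi <- rep_len(deg2rad(phi), n)
  l0 <- pmax(lam, -pi / 2); l1 <- pmin(lam + beta, pi / 2)
  dl <- pmax(l1 - l0, 0)
  if (model$geometry_class == "spherical" && model$rx == model$ry) {
    return(model$rx^2 * beta * (sin(l1) - sin(l0)))
  }
  ## |S_phi x S_lam| via 2-point Gauss-Legendre in each direction
  g <- 0.5 / sqrt(3)
  nodes <- c(0.5 - g, 0.5 + g)
  rx <- model$rx; ry <- model$ry; rz <- model$rz
  area <- numeric(n)
  for (tp in nodes) for (tl in nodes) {
    p <- phi + tp * beta
    l <- l0 + tl * dl
    cl <- cos(l); sl <- sin(l); cp <- cos(p); sp <- sin(p)
    ## S_phi = (-rx cl sp, 0, rz cl cp); S_lam = (-rx sl cp, ry cl, -rz sl sp)
    ax <- -rx * cl * sp; ay <- 0;        az <- rz * cl * cp
    bx <- -rx * sl * cp; by <- ry * cl;  bz <- -rz * sl * sp
    cx <- ay * bz - az * by
    cy <- az * bx - ax * bz
    cz <- ax * by - ay * bx
    area <- area + 0.25 * sqrt(cx^2 + cy^2 + cz^2) * beta * dl
  }
  area
}

#' Area-weighted surface fraction on a map
#'
#' The fraction of the imaged fruit surface selected by a class mask (for
#' example "green" pixels), weighting every map pixel by its true surface
#' area so high-latitude pixels do not over-count. Only pixels with coverage
#' are included, and when the map's longitude span exceeds 360 degrees the
#' columns beyond the first full turn are excluded so re-imaged surface is
#' not double counted.
#'
#' @param map a [fill_map()] result.
#' @param class_mask logical/0-1 matrix of the map's size.
#' @param model spheroid model (defaults to the map's).
#' @param beta angular step (defaults to the map's).
#' @return a fraction in `[0, 1]`.
#' @export
surface_fraction <- function(map, class_mask, model = map$model, beta = map$beta) {
  if (!all(dim(class_mask)[1:2] == dim(map$coverage)))
    stop_spheromap("class mask must match the map dimensions")
  bdeg <- rad2deg(beta)
  first_turn <- map$lon < map$lon_start + 360
  sel <- map$coverage > 0 & matrix(first_turn, nrow(map$coverage),
                                   ncol(map$coverage), byrow = TRUE)
  if (!any(sel)) stop_spheromap("no covered map pixels to measure")
  idx <- which(sel, arr.ind = TRUE)
  areas <- pixel_area(map$lat[idx[, 1]] - bdeg / 2, map$lon[idx[, 2]] - bdeg / 2,
                      model, beta)
  total <- sum(areas)
  inmask <- class_mask[sel] > 0
  sum(areas[inmask]) / total
}

#' Recover dark defect spots from a map
#'
#' Thresholds the map luminance, labels connected components over covered
#' pixels, and merges detections whose centres coincide modulo 360 degrees of
#' longitude (the same surface point re-imaged after a full turn).
#'
#' @param map a [fill_map()] result.
#' @param threshold luminance below which a pixel is "defect".
#' @param min_pixels discard components smaller than this.
#' @param dedup_tol_deg centre distance (degrees, after mod-360 reduction)
#'   below which two detections count as one spot.
#' @return a data.frame with one row per distinct spot: `phi` (reduced to
#'   `[-180, 180)`), `lam`, `npix`, `n_detections`.
#' @export
find_spots <- function(map, threshold = 0.3, min_pixels = 4L, dedup_tol_deg = 6) {
  lum <- (map$pixels[, , 1] + map$pixels[, , 2] + map$pixels[, , 3]) / 3
  bin <- (lum < threshold) & (map$coverage > 0)
  lab <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  nlab <- max(lab)
  if (nlab == 0) return(data.frame(phi = numeric(0), lam = numeric(0),
                                   npix = integer(0), n_detections = integer(0)))
  det <- do.call(rbind, lapply(seq_len(nlab), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_pixels) return(NULL)
    data.frame(phi = mean(map$lon[idx[, 2]]), lam = mean(map$lat[idx[, 1]]),
               npix = nrow(idx))
  }))
  if (is.null(det)) return(data.frame(phi = numeric(0), lam = numeric(0),
                                      npix = integer(0), n_detections = integer(0)))
  reduce180 <- function(p) ((p + 180) %% 360) - 180
  det$phi_red <- reduce180(det$phi)
  used <- rep(FALSE, nrow(det))
  out <- NULL
  for (i in order(-det$npix)) {
    if (used[i]) next
    dphi <- abs(reduce180(det$phi_red - det$phi_red[i]))
    dlam <- abs(det$lam - det$lam[i])
    grp <- !used & dphi < dedup_tol_deg & dlam < dedup_tol_deg
    used[grp] <- TRUE
    out <- rbind(out, data.frame(phi = det$phi_red[i], lam = det$lam[i],
                                 npix = det$npix[i], n_detections = sum(grp)))
  }
  out[order(out$phi), , drop = FALSE]
}

#' Seam statistics of a map
#'
#' Quantifies the "seamless" requirement: the RGB jump across each interior
#' view-boundary longitude, compared to the 95th-percentile adjacent-column
#' gradient in mid-segment (single-pair) regions.
#'
#' @param map a [fill_map()] result.
#' @return a list: `boundary_jumps` (mean |dRGB| at the column nearest each
#'   interior `L_i`), `p95_insegment` (reference gradient), `L` (the interior
#'   boundaries used).
#' @export
seam_statistics <- function(map) {
  L <- map$schedule$L
  nL <- length(L)
  active <- abs(map$lat) < map$lambda_max
  ## per-row |dRGB| (channel mean) across the step from column c1 to c1+1
  rowdiffs <- function(c1) {
    d <- abs(map$pixels[active, c1 + 1, , drop = FALSE] -
               map$pixels[active, c1, , drop = FALSE])
    rowMeans(matrix(d, sum(active), 3))
  }
  col_of <- function(phi) pmin(pmax(round((phi - map$lon_start) / rad2deg(map$beta) + 0.5), 1),
                               ncol(map$coverage) - 1L)
  boundary_cols <- if (nL > 2) col_of(L[-c(1, nL)]) else integer(0)
  jumps <- vapply(boundary_cols, function(c1) mean(rowdiffs(c1)), 0)
  ## reference distribution: pixel-level gradients away from every boundary
  allcols <- seq_len(ncol(map$coverage) - 1L)
  nearb <- if (length(boundary_cols)) {
    vapply(allcols, function(c1) min(abs(c1 - boundary_cols)), 0)
  } else rep(Inf, length(allcols))
  refcols <- allcols[nearb > 5 & map$lon[allcols] > L[1] & map$lon[allcols] < L[nL]]
  ref <- unlist(lapply(refcols, rowdiffs))
  list(boundary_jumps = jumps,
       p95_insegment = if (length(ref)) quantile(ref, 0.95, names = FALSE) else NA_real_,
       L = if (nL > 2) L[-c(1, nL)] else numeric(0))
}
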
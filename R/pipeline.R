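## Pipeline + I/O module: configuration, the end-to-end map builder, bundle
## reading/writing, map serialization, and surface-fraction reporting.

#' Pipeline configuration
#'
#' Validated bag of the tunable parameters of the map-building pipeline.
#'
#' @param geometry_class `"auto"` or an explicit class override.
#' @param preroll_deg,postroll_deg single-view longitude extensions (degrees).
#' @param lambda_max_deg latitude crop (degrees).
#' @param interp view sampling: `"bilinear"` or `"nearest"`.
#' @param seed integer seed for the rotation estimator's consensus sampler.
#' @param tol_spherical relative silhouette circularity below which the fruit
#'   counts as spherical.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry_class = c("auto", "oblate", "spherical", "prolate"),
                            preroll_deg = 45, postroll_deg = 45,
                            lambda_max_deg = 60,
                            interp = c("bilinear", "nearest"),
                            seed = 0L, tol_spherical = 0.03) {
  geometry_class <- match.arg(geometry_class)
  interp <- match.arg(interp)
  if (preroll_deg < 0 || postroll_deg < 0)
    stop_spheromap("pre/post-roll must be non-negative")
  if (lambda_max_deg <= 0 || lambda_max_deg > 90)
    stop_spheromap("lambda_max must be in (0, 90]")
  if (tol_spherical < 0 || tol_spherical > 0.5)
    stop_spheromap("tol_spherical must be a small fraction")
  structure(list(geometry_class = geometry_class, preroll_deg = preroll_deg,
                 postroll_deg = postroll_deg, lambda_max_deg = lambda_max_deg,
                 interp = interp, seed = as.integer(seed),
                 tol_spherical = tol_spherical),
            class = "pipeline_config")
}

config_to_list <- function(cfg) unclass(cfg)
config_from_list <- function(x) do.call(pipeline_config, x)

#' Build a surface map from a view sequence
#'
#' The full pipeline on in-memory views: silhouette fitting, geometry
#' classification, reference-view selection, radii estimation, fruit-frame
#' initialisation, pairwise rotation estimation with chaining (skipped when
#' ground-truth rotations are supplied), longitude scheduling and map
#' filling.
#'
#' @param views list of [view_obs()] objects in capture order.
#' @param config a [pipeline_config()].
#' @param true_rotations optional list of ground-truth pairwise rotation
#'   matrices (bypasses estimation; used for validation).
#' @param true_model optional [spheroid_model()] override.
#' @return a list: `map` (a [fill_map()] result), `model`, `frames`,
#'   `chain`, `schedule`, `reference_index`, `qc` (per-pair estimation QC,
#'   `NULL` when rotations were supplied).
#' @export
build_surface_map <- function(views, config = pipeline_config(),
                              true_rotations = NULL, true_model = NULL) {
  n <- length(views)
  if (n < 1L) stop_spheromap("no views supplied")
  if (n >= 3L && config$geometry_class == "auto") {
    gclass <- classify_geometry(views, config$tol_spherical)
  } else if (config$geometry_class != "auto") {
    gclass <- config$geometry_class
  } else {
    gclass <- "spherical"   # too few views to classify; assume the simplest
  }
  ref <- if (n >= 2L) select_reference_view(views, gclass) else 1L
  model <- true_model %||% estimate_radii(views, gclass, ref, config$tol_spherical)
  frame_ref <- init_fruit_frame(views[[ref]], gclass, config$tol_spherical)

  qc <- NULL
  if (n == 1L) {
    chain <- rotation_chain(list(), 1L)
    frames <- list(frame_ref)
  } else if (!is.null(true_rotations)) {
    chain <- rotation_chain(true_rotations, ref)
    frames <- lapply(seq_len(n), function(j) propagate_frame(frame_ref, chain, j))
  } else {
    est <- estimate_rotation_chain(views, model, frame_ref, ref, seed = config$seed)
    chain <- est$chain
    qc <- est$qc
    frames <- lapply(seq_len(n), function(j) propagate_frame(frame_ref, chain, j))
  }
  schedule <- compute_longitude_schedule(views, model, frames,
                                         config$preroll_deg, config$postroll_deg)
  beta <- angular_step(max(model$rx, model$ry, model$rz))
  map <- fill_map(views, model, frames, schedule, beta,
                  lambda_max = config$lambda_max_deg, interp = config$interp)
  list(map = map, model = model, frames = frames, chain = chain,
       schedule = schedule, reference_index = ref, qc = qc)
}

## ---- raster I/O -----------------------------------------------------------

read_image <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop_spheromap(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
                   "spheromap_io_error"))
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3), c(dim(img), 3))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

read_mask <- function(path) {
  m <- tryCatch(png::readPNG(path), error = function(e)
    stop_spheromap(sprintf("cannot read mask '%s': %s", path, conditionMessage(e)),
                   "spheromap_io_error"))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
}

## foreground from a dark background when no mask file exists
threshold_mask <- function(image, background_level = 0.2) {
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  matrix(as.numeric(lum > background_level), nrow(lum), ncol(lum))
}

## ---- bundles --------------------------------------------------------------

#' Write a synthetic bundle to a directory
#'
#' Renders [generate_sequence()] and writes `view_###.png`, `mask_###.png`,
#' `texture.png` and `truth.json` (row-major rotation matrices, radii, axis,
#' spots, step angles, seed).
#'
#' @param scene a [synthetic_scene()].
#' @param dir output directory (created if needed).
#' @param image_size passed to [render_view()].
#' @return the [generate_sequence()] bundle, invisibly.
#' @export
simulate_bundle <- function(scene, dir, image_size = NULL) {
  bundle <- generate_sequence(scene, image_size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(bundle$views)
  for (i in seq_len(n)) {
    png::writePNG(bundle$views[[i]]$image, file.path(dir, sprintf("view_%03d.png", i)))
    png::writePNG(bundle$views[[i]]$mask, file.path(dir, sprintf("mask_%03d.png", i)))
  }
  png::writePNG(bundle$truth$texture$raster, file.path(dir, "texture.png"))
  truth <- list(
    radii = c(bundle$truth$model$rx, bundle$truth$model$ry, bundle$truth$model$rz),
    geometry_class = bundle$truth$model$geometry_class,
    rotation_axis = bundle$truth$axis,
    step_angles = scene$step_angles,
    cumulative_deg = bundle$truth$cumulative_deg,
    pairwise = lapply(bundle$truth$pairwise, function(R) as.numeric(t(R))),
    frames = lapply(bundle$truth$frames, function(F) as.numeric(t(F))),
    spots = bundle$truth$spots,
    seed = scene$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(bundle)
}

#' Read a directory of views into the pipeline's input form
#'
#' Views are ordered by filename sort (`view_*.png`); matching `mask_*.png`
#' files are used when present, otherwise the foreground is thresholded from
#' the dark background. A `manifest.json` with a `views` (and optional
#' `masks`) array of filenames overrides the filename ordering.
#'
#' @param dir input directory.
#' @param background_level threshold for maskless foreground extraction.
#' @return a list of [view_obs()] objects.
#' @export
read_view_dir <- function(dir, background_level = 0.2) {
  if (!dir.exists(dir)) stop_spheromap(sprintf("no such directory: '%s'", dir),
                                       "spheromap_io_error")
  manifest <- file.path(dir, "manifest.json")
  if (file.exists(manifest)) {
    man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    vfiles <- file.path(dir, man$views)
    mfiles <- if (!is.null(man$masks)) file.path(dir, man$masks) else rep(NA, length(vfiles))
  } else {
    vfiles <- sort(list.files(dir, pattern = "^view_.*\\.png$", full.names = TRUE))
    mfiles <- sub("view_", "mask_", vfiles)
    mfiles[!file.exists(mfiles)] <- NA
  }
  if (length(vfiles) == 0L)
    stop_spheromap(sprintf("no view images found in '%s'", dir), "spheromap_io_error")
  lapply(seq_along(vfiles), function(i) {
    img <- read_image(vfiles[i])
    msk <- if (is.na(mfiles[i])) threshold_mask(img, background_level)
           else read_mask(mfiles[i])
    view_obs(img, msk)
  })
}

## ---- map serialization ----------------------------------------------------

#' Write a map with its geo-reference sidecar
#'
#' Writes the map raster as PNG, a JSON sidecar with everything needed to
#' geo-reference the pixels bit-exactly (beta, crop, longitude range, the
#' schedule, radii and geometry class), and optionally the coverage channel.
#'
#' @param result a [build_surface_map()] result (or a list with `map`,
#'   `model`, `qc`).
#' @param path output PNG path; the sidecar goes to `<path>.json` and the
#'   coverage to `<path>_coverage.png`.
#' @param write_coverage write the coverage channel too?
#' @return `path`, invisibly.
#' @export
write_map <- function(result, path, write_coverage = TRUE) {
  map <- result$map
  png::writePNG(map$pixels, path)
  sidecar <- list(
    beta = map$beta, lambda_max = map$lambda_max,
    lon_start = map$lon_start, lon_end = map$lon_end,
    L = map$schedule$L, preroll = map$schedule$preroll,
    postroll = map$schedule$postroll,
    radii = c(map$model$rx, map$model$ry, map$model$rz),
    geometry_class = map$model$geometry_class
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  if (write_coverage)
    png::writePNG(map$coverage / 2, paste0(sub("\\.png$", "", path), "_coverage.png"))
  if (!is.null(result$qc))
    jsonlite::write_json(result$qc, paste0(sub("\\.png$", "", path), "_qc.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a map + sidecar back into a `surface_map`
#'
#' @param path the map PNG (sidecar expected at `<path>.json`).
#' @return a `surface_map` object (coverage is reloaded when the coverage
#'   PNG is present, otherwise inferred as "covered wherever not background").
#' @export
read_map <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(sc_path))
    stop_spheromap(sprintf("missing sidecar '%s'", sc_path), "spheromap_io_error")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pixels <- read_image(path)
  nr <- nrow(pixels); nc <- ncol(pixels)
  bdeg <- rad2deg(sc$beta)
  cov_path <- paste0(sub("\\.png$", "", path), "_coverage.png")
  coverage <- if (file.exists(cov_path)) {
    m <- png::readPNG(cov_path); if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 2)), nr, nc)
  } else {
    bg <- abs(pixels[, , 1] - 0.5) < 2/255 & abs(pixels[, , 2] - 0.5) < 2/255 &
      abs(pixels[, , 3] - 0.5) < 2/255
    matrix(as.integer(!bg), nr, nc)
  }
  model <- spheroid_model(sc$radii[1], sc$radii[2], sc$radii[3],
                          sc$geometry_class, tol_rel = 1)
  schedule <- structure(list(L = sc$L, preroll = sc$preroll, postroll = sc$postroll),
                        class = "longitude_schedule")
  structure(list(pixels = pixels, coverage = coverage, beta = sc$beta,
                 lambda_max = sc$lambda_max,
                 lon = sc$lon_start + (seq_len(nc) - 0.5) * bdeg,
                 lat = 90 - (seq_len(nr) - 0.5) * bdeg,
                 lon_start = sc$lon_start, lon_end = sc$lon_end,
                 schedule = schedule, model = model),
            class = "surface_map")
}

## ---- drivers --------------------------------------------------------------

#' Build a map from a directory of views
#'
#' CLI-facing driver: reads the views, runs [build_surface_map()] and writes
#' the map PNG, JSON sidecar, coverage channel and QC log.
#'
#' @param input_dir directory of `view_*.png` (+ optional `mask_*.png`).
#' @param output_path output map PNG path.
#' @param config a [pipeline_config()].
#' @return the [build_surface_map()] result, invisibly.
#' @export
build_map_dir <- function(input_dir, output_path, config = pipeline_config()) {
  views <- read_view_dir(input_dir)
  res <- build_surface_map(views, config)
  write_map(res, output_path)
  invisible(res)
}

#' Measure a surface fraction on a stored map
#'
#' Applies a colour-threshold rule to form the class mask and computes the
#' area-weighted [surface_fraction()]. The built-in rule `"green_dominant"`
#' selects pixels whose green channel exceeds the red by `margin`.
#'
#' @param map_path map PNG with sidecar.
#' @param rule `"green_dominant"` or a function `(h x w x 3 array) -> logical
#'   matrix`.
#' @param margin channel margin for the built-in rule, in `[0,1]` units.
#' @return a list report: `fraction`, `rule`, `map` (path), `n_selected`,
#'   `n_covered`.
#' @export
measure_map <- function(map_path, rule = "green_dominant", margin = 0) {
  map <- read_map(map_path)
  cmask <- if (is.function(rule)) {
    rule(map$pixels)
  } else if (identical(rule, "green_dominant")) {
    map$pixels[, , 2] > map$pixels[, , 1] + margin
  } else stop_spheromap(sprintf("unknown mask rule '%s'", rule))
  frac <- surface_fraction(map, cmask)
  list(fraction = frac, rule = if (is.function(rule)) "custom" else rule,
       map = map_path,
       n_selected = sum(cmask & map$coverage > 0),
       n_covered = sum(map$coverage > 0))
}
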
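#!/usr/bin/env Rscript
# Command-line driver for the spheromap pipeline.
#
#   Rscript scripts/fruitmap.R simulate  --out <dir> [--radii 125,125,125]
#       [--steps 30x12] [--texture noise|checker|spots|hemi] [--noise-sd 0]
#       [--seed 0]
#   Rscript scripts/fruitmap.R build-map --in <dir> --out <map.png>
#       [--config cfg.json|cfg.yaml] [--seed 0] [--log-level info|quiet]
#   Rscript scripts/fruitmap.R measure   --map <map.png> [--rule green_dominant]
#
# --config accepts a JSON or YAML file with pipeline_config() fields.

suppressPackageStartupMessages(library(spheromap))

`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  cat("usage: fruitmap.R <simulate|build-map|measure> [options]\n")
  quit(status = 2)
}
cmd <- args[1]
opts <- args[-1]
get_opt <- function(flag, default = NULL) {
  i <- match(flag, opts)
  if (is.na(i) || i == length(opts)) default else opts[i + 1]
}
log_level <- get_opt("--log-level", "info")
say <- function(...) if (!identical(log_level, "quiet")) message(...)

read_config <- function(path, seed) {
  base <- list(seed = seed)
  if (!is.null(path)) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    base <- utils::modifyList(cfg, base[setdiff(names(base), names(cfg))])
  }
  do.call(pipeline_config, base)
}

status <- tryCatch({
  seed <- as.integer(get_opt("--seed", "0"))
  if (cmd == "simulate") {
    out <- get_opt("--out") %||% stop("simulate needs --out <dir>")
    radii <- as.numeric(strsplit(get_opt("--radii", "125,125,125"), ",")[[1]])
    st <- strsplit(get_opt("--steps", "30x12"), "x")[[1]]
    steps <- rep(as.numeric(st[1]), as.integer(st[2]))
    tex <- make_texture(get_opt("--texture", "noise"), seed = seed)
    scene <- synthetic_scene(spheroid_model(radii[1], radii[2], radii[3]), tex,
                             step_angles = steps,
                             noise_sd = as.numeric(get_opt("--noise-sd", "0")),
                             seed = seed)
    b <- simulate_bundle(scene, out)
    say(sprintf("wrote %d views to %s", length(b$views), out))
    0L
  } else if (cmd == "build-map") {
    ind <- get_opt("--in") %||% stop("build-map needs --in <dir>")
    out <- get_opt("--out") %||% stop("build-map needs --out <map.png>")
    cfg <- read_config(get_opt("--config"), seed)
    res <- build_map_dir(ind, out, cfg)
    say(sprintf("map %s: %s, %d x %d px, lon %.1f..%.1f deg",
                out, res$model$geometry_class,
                nrow(res$map$coverage), ncol(res$map$coverage),
                res$map$lon_start, res$map$lon_end))
    if (!is.null(res$qc) && any(res$qc$substituted))
      say(sprintf("note: %d pairwise rotation(s) substituted from neighbours",
                  sum(res$qc$substituted)))
    0L
  } else if (cmd == "measure") {
    mp <- get_opt("--map") %||% stop("measure needs --map <map.png>")
    rep <- measure_map(mp, get_opt("--rule", "green_dominant"),
                       margin = as.numeric(get_opt("--margin", "0")))
    cat(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
    0L
  } else {
    message("unknown command: ", cmd)
    2L
  }
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
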
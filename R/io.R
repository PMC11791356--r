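#' Write a movie as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Counts are rounded and clamped to the 16-bit range. Geometry, protocol
#' and (optionally) ground truth are written to `<path>.json`.
#'
#' @param movie A [movie_stack()].
#' @param path Output TIFF path.
#' @param truth Optional ground-truth data.frame (from [simulate_movie()]).
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, truth = NULL) {
  stopifnot(inherits(movie, "movie_stack"))
  g <- movie$geometry
  pages <- lapply(seq_len(g$n_frames), function(f) {
    m <- movie$frames[f, , ]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- list(geometry = unclass(g))
  if (!is.null(movie$protocol)) side$protocol <- unclass(movie$protocol)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' Metadata (pixel size, frame rate, protocol) is taken from the
#' `<path>.json` sidecar when present, otherwise from the arguments; missing
#' values fall back to the standard defaults (0.74 um, 5 fps), with a
#' message.
#'
#' @param path TIFF path (8/16-bit integer or float pages).
#' @param pixel_size,frame_rate Metadata overrides used when no sidecar is
#'   present.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("corrupt or unreadable TIFF: ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  for (i in seq_along(dims))
    if (!identical(dims[[i]], dims[[1]]))
      stop(sprintf("inconsistent page shapes: page %d is %s, page 1 is %s",
                   i, paste(dims[[i]], collapse = "x"),
                   paste(dims[[1]], collapse = "x")))
  side_path <- paste0(path, ".json")
  protocol <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    gg <- side$geometry
    pixel_size <- gg$pixel_size
    frame_rate <- gg$frame_rate
    exposure <- gg$exposure
    if (!is.null(side$protocol))
      protocol <- do.call(stimulus_protocol, side$protocol)
  } else {
    exposure <- 0.2
    if (is.null(pixel_size)) {
      message("no sidecar or pixel_size given; defaulting to 0.74 um")
      pixel_size <- 0.74
    }
    if (is.null(frame_rate)) {
      message("no sidecar or frame_rate given; defaulting to 5 fps")
      frame_rate <- 5
    }
  }
  frames <- array(0, dim = c(length(pages), dims[[1]][1], dims[[1]][2]))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]]
  g <- movie_geometry(height = dims[[1]][1], width = dims[[1]][2],
                      n_frames = length(pages), pixel_size = pixel_size,
                      frame_rate = frame_rate, exposure = exposure)
  movie_stack(frames, g, protocol)
}

#' Write a dF/F0 stack as TIFF plus mask
#'
#' dF/F0 values are affinely scaled into 32-bit integer pages
#' (`stored = (dff - offset) / scale`); the scale, offset and the
#' baseline-estimation parameters are recorded in `<path>.json` and the
#' validity mask is written as an 8-bit TIFF at `<path>.mask.tif`.
#'
#' @param dff A [compute_dff()] stack.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_dff <- function(dff, path) {
  stopifnot(inherits(dff, "dff_stack"))
  g <- dff$geometry
  x <- dff$dff
  x[is.na(x)] <- 0
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) (hi - lo) else 1
  pages <- lapply(seq_len(g$n_frames),
                  function(f) (x[f, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  tiff::writeTIFF(list(dff$mask * 1), paste0(path, ".mask.tif"),
                  bits.per.sample = 8)
  jsonlite::write_json(list(offset = lo, scale = scale, params = dff$params,
                            geometry = unclass(g)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

rc_schema <- list(
  input = NULL, output_dir = NULL, seed = NULL, log_level = NULL,
  group = NULL,
  sensor = c("kd", "dfmax", "hill"),
  baseline = c("window_frames", "n_rounds", "floor"),
  detection = c("pixel_size", "derivative_smoothing", "min_separation",
                "roi_growth_fraction", "peak_smoothing",
                "variation_limit", "min_area",
                "snr_min", "peak_window_pad", "highfreq_cutoff",
                "highfreq_max_fraction", "max_radius_um"),
  simulation = c("height", "width", "n_frames", "pixel_size", "frame_rate",
                 "exposure", "stim_start", "stim_duration", "stim_frequency",
                 "n_repeats", "repeat_period", "preset", "baseline_level",
                 "shot_noise", "read_noise_sd"),
  stats = c("size_bounds_um2", "welch"))

#' Read a pipeline run configuration
#'
#' YAML mapping with blocks `sensor`, `baseline`, `detection`, `simulation`,
#' `stats` plus `input`, `output_dir`, `seed`, `group`, `log_level`. Every
#' pipeline constant (0.74 um pixel, 1.64 um^2 size threshold, 500%
#' variation limit, 9/36 um^2 size categories, 20 Hz / 5 s stimulation,
#' 5 fps) is a named key here, never hard-coded. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), names(rc_schema))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  for (blk in names(cfg)) {
    allowed <- rc_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[blk]]), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in '%s': %s", blk,
                   paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration
#' @param cfg A `run_config` (or plain list following the schema).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# assemble module objects from a run_config with package defaults
config_sensor <- function(cfg) do.call(sensor_params, cfg$sensor %||% list())
config_detection <- function(cfg)
  do.call(detection_params, cfg$detection %||% list())
config_geometry <- function(cfg) {
  sim <- cfg$simulation %||% list()
  keys <- intersect(names(sim), c("height", "width", "n_frames",
                                  "pixel_size", "frame_rate", "exposure"))
  do.call(movie_geometry, sim[keys])
}
config_protocol <- function(cfg) {
  sim <- cfg$simulation %||% list()
  keys <- intersect(names(sim), c("stim_start", "stim_duration",
                                  "stim_frequency", "n_repeats",
                                  "repeat_period"))
  do.call(stimulus_protocol, sim[keys])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
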
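# shared fixture builders: everything is generated in code at test time

default_sensor <- function() sensor_params(kd = 15, dfmax = 6.44)

# mean of a Gaussian profile over its half-max disk relative to the center
HM <- 0.5 / log(2)

# a movie with explicitly planted release sites on a coarse grid
planted_movie <- function(n_sites = 10, target_peak = 0.5, dim_px = 96,
                          n_frames = 150, seed = 1, shot_noise = TRUE,
                          read_noise_sd = 10, area_um2 = 26, tau = 2,
                          stim_start = 10) {
  p <- default_sensor()
  g <- movie_geometry(dim_px, dim_px, n_frames)
  pr <- stimulus_protocol(stim_start = stim_start)
  pos <- seq(16, dim_px - 16, by = 16)
  grid <- expand.grid(row = pos, col = pos)
  stopifnot(n_sites <= nrow(grid))
  sites <- lapply(seq_len(n_sites), function(i)
    release_site(grid$row[i], grid$col[i],
                 amplitude = invert_response(p, target_peak / HM),
                 sigma_um = sqrt(area_um2 / (2 * pi * log(2))),
                 onset = stim_start + 0.2, tau = tau))
  cfg <- sim_config(g, pr, p, sites = sites, shot_noise = shot_noise,
                    read_noise_sd = read_noise_sd, seed = seed)
  simulate_movie(cfg)
}

# recall/precision of detected hotspot seeds against ground-truth centers
match_stats <- function(hotspot_set, truth, radius_px = 3) {
  if (!length(hotspot_set$hotspots))
    return(list(recall = 0, precision = NA_real_))
  det <- t(vapply(hotspot_set$hotspots, function(h) h$seed, integer(2)))
  r2 <- radius_px^2
  recall <- mean(vapply(seq_len(nrow(truth)), function(i)
    any((det[, 1] - truth$row[i])^2 + (det[, 2] - truth$col[i])^2 <= r2),
    logical(1)))
  precision <- mean(vapply(seq_len(nrow(det)), function(j)
    any((det[j, 1] - truth$row)^2 + (det[j, 2] - truth$col)^2 <= r2),
    logical(1)))
  list(recall = recall, precision = precision)
}

# minimal hotspot candidate for exercising filter_hotspots directly
fake_hotspot <- function(id = 1, n_px = 4, peak = 0.5, repeat_peaks = peak,
                         pixel_size = 0.74, frame_rate = 5,
                         trace = NULL, prestim_mad = 0.01,
                         windows = cbind(start = 5, end = 12)) {
  if (is.null(trace)) {
    t <- seq(0, 29.8, by = 1 / frame_rate)
    trace <- peak * exp(-(t - 8)^2 / 2) * (t > 5)
  }
  t <- seq(0, by = 1 / frame_rate, length.out = length(trace))
  structure(list(
    id = as.integer(id),
    seed = c(row = 5L, col = 5L),
    roi = cbind(row = rep(5L, n_px), col = seq_len(n_px)),
    area_um2 = n_px * pixel_size^2,
    trace = trace, time_s = t,
    peak_dff = max(trace), peak_time_s = t[which.max(trace)],
    repeat_peaks = repeat_peaks,
    fwhm_s = 1, fwhm_one_sided = FALSE,
    prestim_median = 0, prestim_mad = prestim_mad,
    windows = windows, frame_rate = frame_rate,
    qc = NULL, reject_reason = NA_character_), class = "hotspot")
}
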
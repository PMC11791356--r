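#' Movie geometry
#'
#' Spatial and temporal geometry of a fluorescence movie. Defaults follow the
#' imaging configuration of the recordings the pipeline targets: 0.74 um
#' pixels, 5 frames/s, 200 ms exposure.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames.
#' @param pixel_size Pixel edge length in um (default 0.74).
#' @param frame_rate Frames per second (default 5).
#' @param exposure Exposure time per frame in s (default 0.2).
#' @return A `movie_geometry` object.
#' @export
movie_geometry <- function(height, width, n_frames, pixel_size = 0.74,
                           frame_rate = 5, exposure = 0.2) {
  stopifnot(height >= 1, width >= 1, n_frames >= 1,
            pixel_size > 0, frame_rate > 0, exposure > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 frame_rate = frame_rate, exposure = exposure),
            class = "movie_geometry")
}

#' Electrical stimulation protocol
#'
#' Square-wave field stimulation: 20 Hz for 5 s by default, optionally
#' repeated. `frame_time(geometry, i)` of the first stimulated frame is
#' `stim_start`.
#'
#' @param stim_start Onset of the first stimulation, s from movie start.
#' @param stim_duration Stimulation duration in s (default 5).
#' @param stim_frequency Pulse frequency in Hz (default 20).
#' @param n_repeats Number of stimulation repeats (default 1).
#' @param repeat_period Interval between repeat onsets in s (default 10).
#' @return A `stimulus_protocol` object.
#' @export
stimulus_protocol <- function(stim_start, stim_duration = 5,
                              stim_frequency = 20, n_repeats = 1,
                              repeat_period = 10) {
  stopifnot(stim_start >= 0, stim_duration > 0, stim_frequency > 0,
            n_repeats >= 1, repeat_period > stim_duration || n_repeats == 1)
  structure(list(stim_start = stim_start, stim_duration = stim_duration,
                 stim_frequency = stim_frequency,
                 n_repeats = as.integer(n_repeats),
                 repeat_period = repeat_period),
            class = "stimulus_protocol")
}

#' Stimulation repeat onset times
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector of repeat onsets in s.
#' @export
repeat_onsets <- function(protocol) {
  protocol$stim_start + (seq_len(protocol$n_repeats) - 1) * protocol$repeat_period
}

#' A dopamine release site for simulation
#'
#' @param row,col Center pixel (1-based) of the site.
#' @param amplitude Peak local dopamine concentration at the center, uM.
#' @param sigma_um Spatial Gaussian sigma of the concentration field, um.
#' @param onset Release onset, s from movie start (per stimulation repeat the
#'   onset shifts by the repeat period).
#' @param tau Clearance (decay) time constant, s.
#' @return A `release_site` object.
#' @export
release_site <- function(row, col, amplitude, sigma_um = 2, onset = 0,
                         tau = 2) {
  stopifnot(row >= 1, col >= 1, amplitude > 0, sigma_um > 0, onset >= 0,
            tau > 0)
  structure(list(row = row, col = col, amplitude = amplitude,
                 sigma_um = sigma_um, onset = onset, tau = tau),
            class = "release_site")
}

# Mean of a Gaussian profile over its half-maximum disk, relative to the
# center value: (1 - 1/2) / ln 2. Converts a measured (ROI-mean) hotspot
# peak into the corresponding center-pixel amplitude and back.
HALFMAX_MEAN_FACTOR <- 0.5 / log(2)

#' Experimental-group presets for the synthetic generator
#'
#' Per-group hotspot statistics (measured hotspot peak dF/F0, per-FOV hotspot
#' count, hotspot area) and clearance time constant for the four experimental
#' groups: control and GBA1-PD dopaminergic cultures at the early (25 d) and
#' late (40 d) differentiation stages. Peak and area values are the group
#' means +- sd of the measured hotspot populations; the generator samples
#' peaks and areas from lognormal distributions with these moments (positive
#' support, right-skewed) and counts from a rounded normal truncated at 0.
#'
#' Absolute clearance time constants are not established quantities; the
#' defaults (control 2 s, PD 7 s) are conventions that preserve the
#' established 3.5-fold control-to-PD ratio.
#'
#' @param name One of `"control_early"`, `"control_late"`, `"pd_early"`,
#'   `"pd_late"`.
#' @return A `group_preset` list with fields `name`, `peak_mean`, `peak_sd`,
#'   `count_mean`, `count_sd`, `area_mean`, `area_sd`, `clearance_tau`.
#' @export
group_preset <- function(name = c("control_early", "control_late",
                                  "pd_early", "pd_late")) {
  name <- match.arg(name)
  tab <- list(
    control_early = list(peak_mean = 0.158, peak_sd = 0.084,
                         count_mean = 45.0, count_sd = 12.6,
                         area_mean = 26, area_sd = 21, clearance_tau = 2.0),
    control_late  = list(peak_mean = 0.513, peak_sd = 0.431,
                         count_mean = 55.8, count_sd = 23.1,
                         area_mean = 26, area_sd = 21, clearance_tau = 2.0),
    pd_early      = list(peak_mean = 0.845, peak_sd = 0.364,
                         count_mean = 17.0, count_sd = 8.8,
                         area_mean = 32, area_sd = 21, clearance_tau = 7.0),
    pd_late       = list(peak_mean = 0.328, peak_sd = 0.312,
                         count_mean = 16.3, count_sd = 8.1,
                         area_mean = 11, area_sd = 13, clearance_tau = 7.0))
  structure(c(list(name = name), tab[[name]]), class = "group_preset")
}

# lognormal parameters matching a target mean and sd
lnorm_from_moments <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# noiseless single-site spot statistics on the pixel grid: center-pixel
# dF/F0, mean dF/F0 over the pixelated half-max region (the expected
# measured hotspot peak) and the half-max area
spot_stats <- function(sensor, amplitude, sigma_um, row, col, geometry) {
  sig_px <- sigma_um / geometry$pixel_size
  half <- ceiling(4 * sig_px)
  rr <- max(1L, as.integer(round(row)) - half):
        min(geometry$height, as.integer(round(row)) + half)
  cc <- max(1L, as.integer(round(col)) - half):
        min(geometry$width, as.integer(round(col)) + half)
  kern <- exp(-(outer((rr - row)^2, (cc - col)^2, "+")) / (2 * sig_px^2))
  center_dff <- da_response(sensor, amplitude)
  spot <- da_response(sensor, amplitude * kern)
  # half-max relative to the brightest *pixel* (what a detector seeds on);
  # never empty even for sub-pixel sites
  hm <- spot >= max(spot) / 2
  list(center_dff = center_dff,
       peak_dff = mean(spot[hm]),
       area_um2 = sum(hm) * geometry$pixel_size^2,
       rows = rr, cols = cc, kern = kern)
}

#' Sample release sites from a group preset
#'
#' Draws a per-FOV site count from round(N(count_mean, count_sd)) truncated
#' at 0, uniform site positions (with an edge margin), measured-peak targets
#' and hotspot areas from moment-matched lognormals, and a release-onset
#' delay uniform on 0-1 s after stimulation onset. The sampled measured peak
#' is converted to a center-pixel dF/F0 through the half-max averaging factor
#' 0.5/ln(2) and then to a concentration amplitude by inverting the sensor
#' isotherm.
#'
#' Site centers are drawn so that any two sites are separated by at least
#' the sum of their half-max radii plus `sep_margin_um`: the preset counts
#' are counts of *resolved* hotspots, so the generator places sites whose
#' half-max regions do not overlap and which a detector can resolve. Uses
#' the current RNG state; seed upstream (see [simulate_movie()]).
#'
#' @param preset A [group_preset()].
#' @param geometry A [movie_geometry()].
#' @param protocol A [stimulus_protocol()].
#' @param sensor A [sensor_params()].
#' @param sep_margin_um Extra center-to-center separation beyond the sum of
#'   the two sites' half-max radii, um (default 2).
#' @return List of [release_site()] objects with attribute `target_peak_dff`
#'   (the sampled measured peaks).
#' @export
preset_sites <- function(preset, geometry, protocol, sensor = sensor_params(),
                         sep_margin_um = 2) {
  stopifnot(inherits(preset, "group_preset"))
  n <- max(0L, as.integer(round(stats::rnorm(1, preset$count_mean,
                                             preset$count_sd))))
  if (n == 0L) {
    sites <- list()
    attr(sites, "target_peak_dff") <- numeric(0)
    return(sites)
  }
  pk <- lnorm_from_moments(preset$peak_mean, preset$peak_sd)
  ar <- lnorm_from_moments(preset$area_mean, preset$area_sd)
  sigma_guess <- sqrt(preset$area_mean / (2 * pi * log(2)))
  margin <- ceiling(3 * sigma_guess / geometry$pixel_size) + 1
  margin <- min(margin, floor(min(geometry$height, geometry$width) / 4))
  sites <- vector("list", n)
  targets <- numeric(n)
  rows <- numeric(0); cols <- numeric(0); rhalf <- numeric(0)
  for (i in seq_len(n)) {
    d <- stats::rlnorm(1, pk$meanlog, pk$sdlog)
    d <- min(d, 0.9 * sensor$dfmax * HALFMAX_MEAN_FACTOR)
    area <- stats::rlnorm(1, ar$meanlog, ar$sdlog)
    r_i <- sqrt(area / pi)  # half-max radius, um
    min_sep_px <- (rhalf + r_i + sep_margin_um) / geometry$pixel_size
    for (attempt in 1:200) {
      row <- stats::runif(1, margin + 1, geometry$height - margin)
      col <- stats::runif(1, margin + 1, geometry$width - margin)
      if (!length(rows) ||
          all((rows - row)^2 + (cols - col)^2 >= min_sep_px^2)) break
    }
    rows <- c(rows, row); cols <- c(cols, col); rhalf <- c(rhalf, r_i)
    delay <- stats::runif(1, 0, 1)
    onset <- protocol$stim_start + delay
    sigma_um <- sqrt(area / (2 * pi * log(2)))
    # fraction of the continuous kinetics peak the frame grid samples for
    # this onset phase
    tfr <- (seq_len(geometry$n_frames) - 1) / geometry$frame_rate
    kmax <- max(release_kinetics(tfr, onset, preset$clearance_tau,
                                 geometry$frame_rate))
    # calibrate the *sampled* peak concentration so the pixelated half-max
    # mean hits the target measured peak d (two fixed-point refinements of
    # the continuous-profile factor 0.5/ln 2)
    center_dff <- d / HALFMAX_MEAN_FACTOR
    for (it in 1:2) {
      st <- spot_stats(sensor, invert_response(sensor, center_dff),
                       sigma_um, row, col, geometry)
      center_dff <- min(center_dff * d / st$peak_dff, 0.95 * sensor$dfmax)
    }
    sites[[i]] <- release_site(
      row = row, col = col,
      amplitude = invert_response(sensor, center_dff) / kmax,
      sigma_um = sigma_um,
      onset = onset,
      tau = preset$clearance_tau)
    targets[i] <- d
  }
  attr(sites, "target_peak_dff") <- targets
  sites
}

#' Simulation configuration
#'
#' @param geometry A [movie_geometry()].
#' @param protocol A [stimulus_protocol()].
#' @param sensor A [sensor_params()].
#' @param sites Explicit list of [release_site()] objects, or `NULL` to
#'   sample from `preset`.
#' @param preset Optional [group_preset()] (or preset name) used when
#'   `sites` is `NULL`.
#' @param baseline_level Baseline fluorescence in camera counts (default 5000).
#' @param shot_noise Apply Poisson shot noise? (default `TRUE`).
#' @param read_noise_sd Gaussian read-noise sd in counts (default 10).
#' @param seed Integer seed fixing the movie bit-exactly.
#' @return A `sim_config` object.
#' @export
sim_config <- function(geometry, protocol, sensor = sensor_params(),
                       sites = NULL, preset = NULL, baseline_level = 5000,
                       shot_noise = TRUE, read_noise_sd = 10, seed = 1L) {
  stopifnot(inherits(geometry, "movie_geometry"),
            inherits(protocol, "stimulus_protocol"),
            inherits(sensor, "sensor_params"),
            baseline_level > 0, read_noise_sd >= 0)
  if (is.character(preset)) preset <- group_preset(preset)
  duration <- geometry$n_frames / geometry$frame_rate
  last_end <- max(repeat_onsets(protocol)) + protocol$stim_duration
  if (last_end > duration)
    stop("stimulation window extends past the end of the movie")
  if (!is.null(sites)) {
    for (s in sites) {
      stopifnot(inherits(s, "release_site"))
      if (s$row > geometry$height || s$col > geometry$width)
        stop("release site lies outside the frame")
    }
  }
  structure(list(geometry = geometry, protocol = protocol, sensor = sensor,
                 sites = sites, preset = preset,
                 baseline_level = baseline_level, shot_noise = shot_noise,
                 read_noise_sd = read_noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# temporal kinetics of one release event: linear rise over one frame from
# `onset`, then exponential decay with constant tau; evaluated at times t (s)
release_kinetics <- function(t, onset, tau, frame_rate) {
  rise <- 1 / frame_rate
  k <- numeric(length(t))
  up <- t >= onset & t < onset + rise
  k[up] <- (t[up] - onset) / rise
  dn <- t >= onset + rise
  k[dn] <- exp(-(t[dn] - onset - rise) / tau)
  k
}

#' Simulate a nanosensor fluorescence movie
#'
#' Forward model: each release site contributes an isotropic 2-D Gaussian
#' dopamine concentration field (fields from overlapping sites add in
#' concentration space) with a linear one-frame rise at onset and exponential
#' clearance; pixel fluorescence is
#' `baseline_level * (1 + da_response(sensor, c))` plus optional Poisson shot
#' noise and Gaussian read noise. The sensor does not photobleach, so the
#' pre-stimulus expectation is exactly `baseline_level` everywhere.
#'
#' Ground truth per site records the center-pixel peak dF/F0 (`center_dff` =
#' the isotherm at the site amplitude), the expected measured hotspot peak
#' (`peak_dff` = mean dF/F0 over the pixelated half-max region of the
#' noiseless single-site field), and the half-max area in um^2 (pixelated
#' count and the analytic `2*pi*sigma^2*ln 2`).
#'
#' @param config A [sim_config()].
#' @return A list with elements `movie` (a [movie_stack()]), `truth`
#'   (data.frame: site, row, col, amplitude_uM, sigma_um, onset_s, tau_s,
#'   center_dff, peak_dff, area_um2, area_analytic_um2) and `sites`.
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    g <- config$geometry
    sites <- config$sites
    if (is.null(sites)) {
      sites <- if (is.null(config$preset)) list()
               else preset_sites(config$preset, g, config$protocol,
                                 config$sensor)
    }
    t <- (seq_len(g$n_frames) - 1) / g$frame_rate
    onsets0 <- repeat_onsets(config$protocol) - config$protocol$stim_start

    # dopamine concentration stack (uM), sites additive
    conc <- array(0, dim = c(g$n_frames, g$height, g$width))
    truth <- vector("list", length(sites))
    for (i in seq_along(sites)) {
      s <- sites[[i]]
      kin <- rep(0, g$n_frames)
      for (o in onsets0)
        kin <- kin + release_kinetics(t, s$onset + o, s$tau, g$frame_rate)
      # truth reflects what the frame grid actually samples: the kinetics
      # maximum over frame times, not the continuous peak
      st <- spot_stats(config$sensor, s$amplitude * max(kin), s$sigma_um,
                       s$row, s$col, g)
      live <- which(kin > 1e-6)
      for (f in live)
        conc[f, st$rows, st$cols] <- conc[f, st$rows, st$cols] +
          s$amplitude * kin[f] * st$kern

      truth[[i]] <- data.frame(
        site = i, row = s$row, col = s$col, amplitude_uM = s$amplitude,
        sigma_um = s$sigma_um, onset_s = s$onset, tau_s = s$tau,
        center_dff = st$center_dff,
        peak_dff = st$peak_dff,
        area_um2 = st$area_um2,
        area_analytic_um2 = 2 * pi * s$sigma_um^2 * log(2))
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(site = integer(0), row = numeric(0),
                             col = numeric(0), amplitude_uM = numeric(0),
                             sigma_um = numeric(0), onset_s = numeric(0),
                             tau_s = numeric(0), center_dff = numeric(0),
                             peak_dff = numeric(0), area_um2 = numeric(0),
                             area_analytic_um2 = numeric(0))

    frames <- config$baseline_level * (1 + da_response(config$sensor, conc))
    if (config$shot_noise)
      frames[] <- stats::rpois(length(frames), frames)
    if (config$read_noise_sd > 0)
      frames[] <- frames + stats::rnorm(length(frames),
                                        sd = config$read_noise_sd)
    frames[frames < 0] <- 0

    list(movie = movie_stack(frames, g, config$protocol),
         truth = truth, sites = sites)
  })
}

#' Simulate a dose-response calibration table
#'
#' Responses are `da_response(params, c) * (1 + eps)` with multiplicative
#' Gaussian noise `eps ~ N(0, noise_cv^2)`, seeded.
#'
#' @param params A [sensor_params()].
#' @param concentrations Concentrations in uM (default 12 log-spaced points
#'   over 0.001-1000 uM, the sensor's working range).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed Integer seed.
#' @return A [dose_response()] table.
#' @export
simulate_dose_response <- function(params,
                                   concentrations = 10^seq(-3, 3,
                                                           length.out = 12),
                                   noise_cv = 0, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  with_seed(seed, {
    mu <- da_response(params, concentrations)
    eps <- if (noise_cv > 0)
      stats::rnorm(length(mu), 0, noise_cv) else rep(0, length(mu))
    dose_response(concentrations, mu * (1 + eps))
  })
}

#' Simulate a dopamine clearance trace
#'
#' `peak_dff * exp(-t / tau)` sampled at `frame_rate` over `duration`
#' seconds, plus seeded additive Gaussian noise.
#'
#' @param tau Clearance time constant in s.
#' @param peak_dff Initial dF/F0 amplitude.
#' @param frame_rate Sampling rate, frames/s (default 5).
#' @param duration Trace duration in s (default 30).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return Numeric dF/F0 trace with attribute `time_s`.
#' @export
simulate_clearance_trace <- function(tau, peak_dff = 1, frame_rate = 5,
                                     duration = 30, noise_sd = 0, seed = 1L) {
  stopifnot(tau > 0, duration > 0, frame_rate > 0, noise_sd >= 0)
  with_seed(seed, {
    t <- seq(0, duration, by = 1 / frame_rate)
    y <- peak_dff * exp(-t / tau)
    if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
    structure(y, time_s = t)
  })
}
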
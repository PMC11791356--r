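test_that("null movie without noise is identically the baseline level", {
  g <- movie_geometry(16, 16, 60)
  pr <- stimulus_protocol(stim_start = 4)
  cfg <- sim_config(g, pr, sites = list(), baseline_level = 1000,
                    shot_noise = FALSE, read_noise_sd = 0, seed = 1)
  res <- simulate_movie(cfg)
  expect_true(all(res$movie$frames == 1000))
  expect_equal(nrow(res$truth), 0)
})

test_that("noiseless site peak matches the isotherm in closed form", {
  p <- default_sensor()
  g <- movie_geometry(32, 32, 80)
  pr <- stimulus_protocol(stim_start = 4)
  for (amp in c(5, 100, 5000)) {  # 5000 uM >> Kd: near-saturation
    site <- release_site(16, 16, amplitude = amp, sigma_um = 2,
                         onset = 4.2, tau = 2)
    cfg <- sim_config(g, pr, p, sites = list(site), baseline_level = 2000,
                      shot_noise = FALSE, read_noise_sd = 0, seed = 1)
    res <- simulate_movie(cfg)
    expected <- p$dfmax * amp / (amp + p$kd)
    peak_px <- max(res$movie$frames) / 2000 - 1
    expect_equal(peak_px, expected, tolerance = 1e-12)
    expect_equal(res$truth$center_dff, expected, tolerance = 1e-12)
  }
})

test_that("same seed gives bit-identical movies, different seed does not", {
  g <- movie_geometry(24, 24, 60)
  pr <- stimulus_protocol(stim_start = 4)
  cfg <- sim_config(g, pr, preset = "pd_early", seed = 42)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_config(g, pr, preset = "pd_early", seed = 43)
  expect_false(identical(simulate_movie(cfg2)$movie$frames, a$movie$frames))
})

test_that("increasing a site's amplitude never decreases its true peak", {
  p <- default_sensor()
  g <- movie_geometry(32, 32, 60)
  pr <- stimulus_protocol(stim_start = 4)
  peaks <- vapply(c(1, 5, 20, 80, 400), function(amp) {
    site <- release_site(16, 16, amplitude = amp, sigma_um = 2,
                         onset = 4.2, tau = 2)
    cfg <- sim_config(g, pr, p, sites = list(site), shot_noise = FALSE,
                      read_noise_sd = 0, seed = 1)
    max(simulate_movie(cfg)$truth$center_dff)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("site outside the frame is rejected", {
  g <- movie_geometry(16, 16, 60)
  pr <- stimulus_protocol(stim_start = 4)
  bad <- release_site(30, 5, amplitude = 10)
  expect_error(sim_config(g, pr, sites = list(bad)), "outside the frame")
  expect_error(sim_config(movie_geometry(16, 16, 20), pr, sites = list()),
               "past the end")
})

test_that("preset site statistics reproduce the group presets", {
  g <- movie_geometry(128, 128, 150)
  pr <- stimulus_protocol(stim_start = 10)
  for (nm in c("control_early", "pd_late")) {
    preset <- group_preset(nm)
    counts <- numeric(50); pkm <- numeric(50)
    for (s in 1:50) {
      set.seed(7000 + s)
      sites <- preset_sites(preset, g, pr)
      counts[s] <- length(sites)
      pkm[s] <- mean(attr(sites, "target_peak_dff"))
    }
    se_count <- stats::sd(counts) / sqrt(50)
    expect_lt(abs(mean(counts) - preset$count_mean), 2 * se_count + 1e-9)
    se_peak <- stats::sd(pkm, na.rm = TRUE) / sqrt(sum(!is.na(pkm)))
    expect_lt(abs(mean(pkm, na.rm = TRUE) - preset$peak_mean), 2 * se_peak)
  }
})

test_that("ground-truth measured peak matches its sampled target", {
  g <- movie_geometry(128, 128, 150)
  pr <- stimulus_protocol(stim_start = 10)
  cfg <- sim_config(g, pr, preset = "control_early", seed = 11)
  res <- simulate_movie(cfg)
  expect_equal(res$truth$peak_dff,
               attr(res$sites, "target_peak_dff"), tolerance = 0.02)
  # pixelated truth area tracks the analytic half-max area
  expect_equal(res$truth$area_um2, res$truth$area_analytic_um2,
               tolerance = 0.25)
})

test_that("simulated dose-response matches the model exactly at zero noise", {
  p <- default_sensor()
  cur <- simulate_dose_response(p, noise_cv = 0, seed = 1)
  expect_equal(cur$dff, da_response(p, cur$concentration_uM))
  c100 <- simulate_dose_response(p, concentrations = c(1, 10, 100),
                                 noise_cv = 0, seed = 1)
  expect_equal(c100$dff[3], 5.60)
  a <- simulate_dose_response(p, noise_cv = 0.05, seed = 9)
  b <- simulate_dose_response(p, noise_cv = 0.05, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_dose_response(p, noise_cv = -1), "noise_cv")
})

test_that("clearance traces follow the closed form", {
  tr <- simulate_clearance_trace(tau = 2, peak_dff = 1, frame_rate = 5,
                                 duration = 10, noise_sd = 0)
  t <- attr(tr, "time_s")
  expect_equal(tr[t == 0], 1)
  expect_equal(unname(tr[t == 2]), exp(-1), tolerance = 1e-12)
  a <- simulate_clearance_trace(2, 1, 5, 10, 0.1, seed = 3)
  b <- simulate_clearance_trace(2, 1, 5, 10, 0.1, seed = 3)
  expect_identical(a, b)
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  r1 <- stats::runif(1)
  set.seed(123)
  invisible(simulate_dose_response(default_sensor(), noise_cv = 0.1,
                                   seed = 999))
  r2 <- stats::runif(1)
  expect_identical(r1, r2)
})
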
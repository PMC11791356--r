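constant_dff <- function(h = 8, w = 8, n = 40, protocol = NULL) {
  g <- movie_geometry(h, w, n)
  m <- movie_stack(array(100, c(n, h, w)), g,
                   protocol %||% stimulus_protocol(stim_start = 3))
  compute_dff(m, window_frames = 31)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("score map is zero for constant traces and errors without a window", {
  d <- constant_dff()
  sm <- score_map(d)
  expect_true(all(sm$score == 0))
  d2 <- d
  d2$protocol <- NULL
  expect_error(score_map(d2), "window")
  expect_equal(dim(score_map(d2, window = c(3, 7))$score), c(8, 8))
})

test_that("a unit step between consecutive frames scores frame_rate", {
  d <- constant_dff()
  d$dff[20:40, 4, 5] <- 1   # step of +1 at 5 fps inside the window
  sm <- score_map(d)
  expect_equal(sm$score[4, 5], 5)
  expect_equal(max(sm$score[-(4 + (5 - 1) * 8)]), 0)
})

test_that("score argmax hits the injected site center", {
  res <- planted_movie(n_sites = 1, target_peak = 0.5, dim_px = 48, seed = 3)
  d <- compute_dff(res$movie)
  sm <- score_map(d)
  ij <- which(sm$score == max(sm$score), arr.ind = TRUE)
  expect_lte(max(abs(ij - c(res$truth$row, res$truth$col))), 1)
})

test_that("find_seeds returns local maxima with deterministic tie-breaking", {
  d <- constant_dff()
  expect_equal(nrow(find_seeds(score_map(d))), 0)
  # two separated maxima -> two seeds
  d$dff[20:24, 2, 2] <- 0.8
  d$dff[20:24, 7, 7] <- 0.5
  seeds <- find_seeds(score_map(d), detection_params(min_separation = 3))
  expect_equal(seeds[, c("row", "col")],
               data.frame(row = c(2L, 7L), col = c(2L, 7L)))
  # 1 px apart with min_separation 3 -> only the stronger survives;
  # exact tie resolved toward the smaller row
  d2 <- constant_dff()
  d2$dff[20:24, 4, 4] <- 0.6
  d2$dff[20:24, 5, 4] <- 0.6
  s2 <- find_seeds(score_map(d2), detection_params(min_separation = 3))
  expect_equal(nrow(s2), 1)
  expect_equal(unname(unlist(s2[1, c("row", "col")])), c(4L, 4L))
})

test_that("grow_roi produces connected half-max regions", {
  d <- constant_dff(16, 16, 60)
  d$dff[20:24, 5, 5] <- 1
  roi <- grow_roi(d, c(5, 5))
  expect_equal(roi, matrix(c(5L, 5L), 1,
                           dimnames = list(NULL, c("row", "col"))))
  expect_equal(nrow(roi) * 0.74^2, 0.5476)
  # a noiseless Gaussian spot grows to about its analytic half-max area
  res <- planted_movie(n_sites = 1, target_peak = 0.5, dim_px = 48,
                       shot_noise = FALSE, read_noise_sd = 0, seed = 2)
  dg <- compute_dff(res$movie)
  sg <- find_seeds(score_map(dg))
  roig <- grow_roi(dg, c(sg$row[1], sg$col[1]))
  area <- nrow(roig) * 0.74^2
  expect_lt(abs(area - res$truth$area_analytic_um2) /
              res$truth$area_analytic_um2, 0.15)
  # two disjoint spots never share ROI pixels
  res2 <- planted_movie(n_sites = 2, target_peak = 0.5, dim_px = 48,
                        shot_noise = FALSE, read_noise_sd = 0, seed = 2)
  d2 <- compute_dff(res2$movie)
  s2 <- find_seeds(score_map(d2))
  r1 <- grow_roi(d2, c(s2$row[1], s2$col[1]))
  r2 <- grow_roi(d2, c(s2$row[2], s2$col[2]))
  expect_equal(nrow(merge(as.data.frame(r1), as.data.frame(r2))), 0)
})

test_that("temporal FWHM matches closed-form pulse widths", {
  rate <- 10
  t <- seq(0, 20, by = 1 / rate)
  tri <- pmax(0, 1 - abs(t - 10) / 2)  # triangle, 4 s base
  expect_equal(as.numeric(temporal_fwhm(tri, rate, baseline = 0)), 2)
  gauss <- exp(-(t - 10)^2 / 2)        # sigma = 1 s
  w <- temporal_fwhm(gauss, rate, baseline = 0)
  expect_equal(as.numeric(w), 2 * sqrt(2 * log(2)), tolerance = 1 / rate)
  expect_false(attr(w, "one_sided"))
  rising <- t / 20
  wr <- temporal_fwhm(rising, rate, baseline = 0)
  expect_true(attr(wr, "one_sided"))
})

test_that("refinement filters implement the documented rejection rules", {
  params <- detection_params()
  # 2 px = 1.10 um^2 rejected, 3 px = 1.6428 um^2 accepted (inclusive)
  small <- fake_hotspot(id = 1, n_px = 2)
  three <- fake_hotspot(id = 2, n_px = 3)
  out <- filter_hotspots(list(small, three), params)
  expect_equal(length(out$accepted), 1)
  expect_equal(out$accepted[[1]]$id, 2)
  expect_false(out$rejected[[1]]$qc$size_ok)
  expect_match(out$log$reason, "size")
  expect_equal(three$area_um2, 1.6428)
  # repeat peaks {0.1, 0.7}: variation 600% >= 500% -> rejected
  varying <- fake_hotspot(id = 3, repeat_peaks = c(0.1, 0.7))
  stable <- fake_hotspot(id = 4, repeat_peaks = c(0.4, 0.5))
  out2 <- filter_hotspots(list(varying, stable), params, n_repeats = 2)
  expect_equal(vapply(out2$accepted, `[[`, integer(1), "id"), 4L)
  expect_false(out2$rejected[[1]]$qc$variation_ok)
  # low-SNR and high-frequency traces are rejected as noise
  lowsnr <- fake_hotspot(id = 5, peak = 0.02, prestim_mad = 0.05)
  out3 <- filter_hotspots(list(lowsnr), params)
  expect_false(out3$rejected[[1]]$qc$noise_ok)
  set.seed(1)
  buzz <- fake_hotspot(id = 6, prestim_mad = 0.2)  # mad consistent w/ noise
  buzz$trace <- rnorm(length(buzz$trace), sd = 0.2)  # pure noise, no event
  buzz$peak_dff <- max(buzz$trace)
  out4 <- filter_hotspots(list(buzz), params)
  expect_equal(length(out4$accepted), 0)
})

test_that("every candidate lands in accepted or the rejection log", {
  for (s in 1:3) {
    res <- planted_movie(n_sites = 6, target_peak = 0.4, seed = s)
    hs <- detect_hotspots(compute_dff(res$movie))
    n_cand <- length(hs$hotspots) + length(hs$rejected)
    expect_equal(nrow(hs$log), length(hs$rejected))
    expect_equal(sort(c(vapply(hs$hotspots, `[[`, integer(1), "id"),
                        vapply(hs$rejected, `[[`, integer(1), "id"))),
                 seq_len(n_cand))
  }
})

test_that("null noiseless movie yields zero hotspots and zero dF/F0", {
  g <- movie_geometry(32, 32, 100)
  pr <- stimulus_protocol(stim_start = 8)
  cfg <- sim_config(g, pr, sites = list(), shot_noise = FALSE,
                    read_noise_sd = 0, seed = 1)
  res <- simulate_movie(cfg)
  d <- compute_dff(res$movie)
  expect_true(all(d$dff == 0))
  hs <- detect_hotspots(d)
  expect_equal(length(hs$hotspots), 0)
  expect_equal(nrow(hotspot_table(hs)), 0)
})

test_that("detection recovers planted sites with high recall and precision", {
  rec <- c(); prec <- c(); dpk <- c(); tpk <- c()
  for (s in 1:3) {
    res <- planted_movie(n_sites = 10, target_peak = 0.5, seed = s)
    hs <- detect_hotspots(compute_dff(res$movie))
    m <- match_stats(hs, res$truth)
    rec <- c(rec, m$recall); prec <- c(prec, m$precision)
    dpk <- c(dpk, vapply(hs$hotspots, `[[`, numeric(1), "peak_dff"))
    tpk <- c(tpk, res$truth$peak_dff)
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec), 0.9)
  # mean detected peak within 10% of the planted measured peak
  expect_lt(abs(mean(dpk) - mean(tpk)) / mean(tpk), 0.1)
})

test_that("filters are monotone in their thresholds", {
  res <- planted_movie(n_sites = 10, target_peak = 0.3, seed = 4)
  d <- compute_dff(res$movie)
  n_by_area <- vapply(c(0.5, 1.64, 5, 20), function(a)
    length(detect_hotspots(d, detection_params(min_area = a))$hotspots),
    numeric(1))
  expect_true(all(diff(n_by_area) <= 0))
  n_by_snr <- vapply(c(1, 3, 8, 20), function(s)
    length(detect_hotspots(d, detection_params(snr_min = s))$hotspots),
    numeric(1))
  expect_true(all(diff(n_by_snr) <= 0))
})

test_that("detection is deterministic", {
  res <- planted_movie(n_sites = 5, seed = 6)
  d <- compute_dff(res$movie)
  h1 <- detect_hotspots(d)
  h2 <- detect_hotspots(d)
  expect_identical(hotspot_table(h1, "all"), hotspot_table(h2, "all"))
})

test_that("detection survives multi-repeat stimulation protocols", {
  p <- default_sensor()
  g <- movie_geometry(32, 32, 200)  # 40 s at 5 fps
  pr <- stimulus_protocol(stim_start = 5, n_repeats = 2, repeat_period = 15)
  sites <- list(release_site(16, 16, invert_response(p, 0.4 / HM),
                             sigma_um = 2.4, onset = 5.3, tau = 2))
  res <- simulate_movie(sim_config(g, pr, p, sites = sites, seed = 8))
  hs <- detect_hotspots(compute_dff(res$movie, window_frames = 61))
  expect_equal(length(hs$hotspots), 1)
  h <- hs$hotspots[[1]]
  expect_equal(length(h$repeat_peaks), 2)
  # both repeats release equally: variation far below the 500% limit
  v <- 100 * diff(range(h$repeat_peaks)) / min(h$repeat_peaks)
  expect_lt(v, 100)
})

test_that("detect_hotspots matches the brute-force reference exactly", {
  for (s in 1:2) {
    p <- default_sensor()
    g <- movie_geometry(16, 16, 50)
    pr <- stimulus_protocol(stim_start = 4, stim_duration = 3)
    sites <- list(
      release_site(5, 5, invert_response(p, 0.5 / HM), sigma_um = 1.5,
                   onset = 4.2, tau = 2),
      release_site(12, 11, invert_response(p, 0.35 / HM), sigma_um = 1.2,
                   onset = 4.4, tau = 2))
    res <- simulate_movie(sim_config(g, pr, p, sites = sites,
                                     baseline_level = 3000, seed = 30 + s))
    d <- compute_dff(res$movie, window_frames = 31)
    params <- detection_params()
    got <- detect_hotspots(d, params)
    ref <- reference_detect(d, params)
    expect_equal(got$seeds[, c("row", "col")], ref$seeds)
    expect_equal(length(got$hotspots), length(ref$accepted))
    expect_equal(length(got$rejected), length(ref$rejected))
    for (k in seq_along(got$hotspots)) {
      expect_equal(unname(got$hotspots[[k]]$seed), ref$accepted[[k]]$seed)
      expect_equal(unname(got$hotspots[[k]]$roi),
                   unname(ref$accepted[[k]]$roi))
      expect_equal(got$hotspots[[k]]$peak_dff, ref$accepted[[k]]$peak_dff)
      expect_equal(got$hotspots[[k]]$area_um2, ref$accepted[[k]]$area_um2)
    }
  }
})
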
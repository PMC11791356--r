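#' Hotspot detection parameters
#'
#' Tuning parameters of the hotspot detector and its refinement filters.
#' `min_area` defaults to the area of three combined pixels,
#' `3 * pixel_size^2` = 1.6428 um^2 at the standard 0.74 um pixel — the
#' size threshold separating genuine release hotspots from impulse noise.
#' The acceptance comparison for the size filter is inclusive
#' (`area >= min_area`), so a 3-pixel ROI passes.
#'
#' @param pixel_size Pixel edge length in um used for the `min_area`
#'   default (default 0.74).
#' @param derivative_smoothing Moving-average window (frames) applied to
#'   each dF/F0 trace before differentiation; 1 = no smoothing.
#' @param min_separation Minimum Euclidean distance between seeds, px.
#'   Default 8 px (5.9 um at the standard pixel size): the diameter of a
#'   typical ~26 um^2 hotspot, i.e. two release sites closer than one
#'   hotspot diameter are not counted as separate hotspots.
#' @param roi_growth_fraction ROI growth threshold as a fraction of the
#'   seed's peak dF/F0 (default 0.5 = half-max region).
#' @param peak_smoothing Moving-average window (frames, odd) applied to
#'   traces before taking the per-pixel peak used for ROI growth (default
#'   3); hotspot traces and reported peaks stay unsmoothed.
#' @param variation_limit Peak-height variation limit across stimulation
#'   repeats, percent (default 500); candidates at or above it are rejected.
#' @param min_area Minimum ROI area in um^2 (default `3 * pixel_size^2`).
#' @param snr_min Minimum peak SNR versus the pre-stimulus MAD (default 3).
#' @param peak_window_pad Evaluation-window padding after stimulation end,
#'   s (default 2, reflecting release/diffusion lag).
#' @param highfreq_cutoff High-frequency cutoff in Hz (default 1).
#' @param highfreq_max_fraction Maximum tolerated fraction of (non-DC)
#'   spectral power above the cutoff (default 0.5).
#' @param max_radius_um Hard cap on ROI radius from the seed, um (default
#'   12): a guard that stops the half-max flood from chaining across
#'   adjacent release sites into one runaway region.
#' @return A `detection_params` object.
#' @export
detection_params <- function(pixel_size = 0.74,
                             derivative_smoothing = 1,
                             min_separation = 8,
                             roi_growth_fraction = 0.5,
                             peak_smoothing = 3,
                             variation_limit = 500,
                             min_area = 3 * pixel_size^2,
                             snr_min = 3,
                             peak_window_pad = 2,
                             highfreq_cutoff = 1,
                             highfreq_max_fraction = 0.5,
                             max_radius_um = 12) {
  p <- list(pixel_size = pixel_size,
            derivative_smoothing = as.integer(derivative_smoothing),
            min_separation = min_separation,
            roi_growth_fraction = roi_growth_fraction,
            peak_smoothing = as.integer(peak_smoothing),
            variation_limit = variation_limit,
            min_area = min_area,
            snr_min = snr_min,
            peak_window_pad = peak_window_pad,
            highfreq_cutoff = highfreq_cutoff,
            highfreq_max_fraction = highfreq_max_fraction,
            max_radius_um = max_radius_um)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1))))
  structure(p, class = "detection_params")
}

# frame times in s (frame 1 at t = 0)
frame_times <- function(geometry) {
  (seq_len(geometry$n_frames) - 1) / geometry$frame_rate
}

# evaluation windows: one (start, end) row per stimulation repeat, padded
# after stimulation end; overall window = their range
eval_windows <- function(protocol, params, window = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    return(matrix(window, nrow = 1,
                  dimnames = list(NULL, c("start", "end"))))
  }
  if (is.null(protocol))
    stop("no stimulation protocol and no explicit evaluation window")
  on <- repeat_onsets(protocol)
  cbind(start = on, end = on + protocol$stim_duration + params$peak_window_pad)
}

#' Per-pixel release score map
#'
#' For every pixel: smooth the dF/F0 trace with a moving average of
#' `derivative_smoothing` frames, take the first difference scaled by the
#' frame rate (units 1/s), and keep the maximum derivative inside the
#' stimulus evaluation window (stimulation start to end +
#' `peak_window_pad`). The same statistic over the pre-stimulus frames is
#' returned as the noise reference for seed thresholding.
#'
#' @param dff A [compute_dff()] stack.
#' @param params A [detection_params()].
#' @param window Optional explicit `(start, end)` evaluation window in s,
#'   overriding the stack's protocol.
#' @return A `score_map` object: `score` and `prestim` matrices
#'   (height x width; `prestim` is `NULL` when no pre-stimulus frames
#'   exist), plus the windows used.
#' @export
score_map <- function(dff, params = detection_params(), window = NULL) {
  stopifnot(inherits(dff, "dff_stack"))
  g <- dff$geometry
  if (g$n_frames < 3) stop("need at least 3 frames")
  win <- eval_windows(dff$protocol, params, window)
  t <- frame_times(g)
  mat <- matrix(dff$dff, nrow = g$n_frames)
  mat[is.na(mat)] <- 0
  if (params$derivative_smoothing > 1)
    mat <- moving_average_mat(mat, params$derivative_smoothing)
  d <- diff(mat) * g$frame_rate
  td <- t[-1]  # derivative sample i spans frames i..i+1; timestamp at t[i+1]
  inwin <- td >= min(win[, "start"]) & td <= max(win[, "end"])
  if (!any(inwin)) stop("evaluation window contains no frames")
  score <- apply(d[inwin, , drop = FALSE], 2, max)
  pre <- td < min(win[, "start"])
  prestim <- if (any(pre)) apply(d[pre, , drop = FALSE], 2, max) else NULL
  shape <- function(v) if (is.null(v)) NULL else
    matrix(v, nrow = g$height, ncol = g$width)
  sc <- shape(score)
  sc[!dff$mask] <- -Inf
  ps <- shape(prestim)
  if (!is.null(ps)) ps[!dff$mask] <- NA_real_
  structure(list(score = sc, prestim = ps, windows = win,
                 geometry = g), class = "score_map")
}

#' Find hotspot seed pixels
#'
#' Spatial local maxima (8-neighborhood) of the score map exceeding the
#' noise-derived threshold `median + snr_min * MAD` of the pre-stimulus
#' score distribution (0 when no pre-stimulus frames exist), thinned
#' greedily so no two seeds are closer than `min_separation` px. Candidates
#' are visited in descending score order, ties broken by (row, col), so the
#' result is deterministic.
#'
#' @param score A [score_map()] object.
#' @param params A [detection_params()].
#' @return data.frame with columns `row`, `col`, `score`, ordered by
#'   descending score.
#' @export
find_seeds <- function(score, params = detection_params()) {
  stopifnot(inherits(score, "score_map"))
  s <- score$score
  thr <- if (is.null(score$prestim)) 0 else {
    pv <- score$prestim[!is.na(score$prestim)]
    stats::median(pv) + params$snr_min * stats::mad(pv)
  }
  nr <- nrow(s); nc <- ncol(s)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- s
  ismax <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    ismax <- ismax & (s >= nb)
  }
  cand <- which(ismax & is.finite(s) & s > thr, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(row = integer(0), col = integer(0), score = numeric(0)))
  sc <- s[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (cand[keep, 1] - cand[i, 1])^2 + (cand[keep, 2] - cand[i, 2])^2
    keep[i] <- all(d2 >= params$min_separation^2)
  }
  data.frame(row = as.integer(cand[keep, 1]),
             col = as.integer(cand[keep, 2]),
             score = sc[keep])
}

# per-pixel maximum dF/F0 inside the overall evaluation window, computed on
# traces smoothed with a `peak_smoothing`-frame moving average: light
# temporal smoothing suppresses the upward bias of a max over noisy frames,
# which would otherwise pull background pixels over the half-max ROI
# threshold and dilute hotspot traces
peak_map <- function(dff, params, window = NULL) {
  g <- dff$geometry
  win <- eval_windows(dff$protocol, params, window)
  t <- frame_times(g)
  inwin <- t >= min(win[, "start"]) & t <= max(win[, "end"])
  mat <- matrix(dff$dff, nrow = g$n_frames)
  mat[is.na(mat)] <- 0
  if (params$peak_smoothing > 1)
    mat <- moving_average_mat(mat, params$peak_smoothing)
  pm <- apply(mat[inwin, , drop = FALSE], 2, max)
  pm <- matrix(pm, nrow = g$height, ncol = g$width)
  pm[!dff$mask] <- -Inf
  pm
}

# noise floor of the peak map: the same per-pixel maximum statistic over the
# pre-stimulus frames summarised as median + snr_min * MAD across pixels.
# -Inf when there are no pre-stimulus frames.
peak_map_floor <- function(dff, params, window = NULL) {
  g <- dff$geometry
  win <- eval_windows(dff$protocol, params, window)
  t <- frame_times(g)
  pre <- t < min(win[, "start"])
  if (!any(pre)) return(-Inf)
  mat <- matrix(dff$dff, nrow = g$n_frames)
  mat[is.na(mat)] <- 0
  if (params$peak_smoothing > 1)
    mat <- moving_average_mat(mat, params$peak_smoothing)
  pp <- apply(mat[pre, , drop = FALSE], 2, max)
  pp <- pp[as.vector(dff$mask)]
  stats::median(pp) + params$snr_min * stats::mad(pp)
}

#' Grow a hotspot ROI from a seed
#'
#' 8-connected region of pixels, containing the seed, whose peak dF/F0
#' inside the evaluation window is at least `roi_growth_fraction` times the
#' seed's peak dF/F0 (half-max region by default) and above the pre-stimulus
#' noise floor of the peak map (median + `snr_min` * MAD of the same
#' per-pixel maximum statistic over pre-stimulus frames). The noise floor
#' keeps a spurious low-amplitude seed from flooding into background whose
#' noisy peaks exceed half of the seed's own (noise-level) peak; on
#' noiseless data it is zero and the rule reduces to pure half-max growth.
#' Grown by breadth-first flood fill, so the region is connected by
#' construction.
#'
#' @param dff A [compute_dff()] stack.
#' @param seed Length-2 integer `(row, col)`.
#' @param params A [detection_params()].
#' @param window Optional explicit evaluation window in s.
#' @param .peak_map,.floor Precomputed [peak_map] matrix and noise floor
#'   (internal reuse).
#' @param .barrier Optional logical matrix of pixels the flood may not
#'   enter (pixels already claimed by stronger candidates).
#' @return Integer matrix with columns `row`, `col`; one row per ROI pixel.
#' @export
grow_roi <- function(dff, seed, params = detection_params(), window = NULL,
                     .peak_map = NULL, .floor = NULL, .barrier = NULL) {
  stopifnot(inherits(dff, "dff_stack"), length(seed) == 2)
  g <- dff$geometry
  pm <- if (is.null(.peak_map)) peak_map(dff, params, window) else .peak_map
  if (is.null(.floor)) .floor <- peak_map_floor(dff, params, window)
  sr <- as.integer(seed[1]); sc <- as.integer(seed[2])
  stopifnot(sr >= 1, sr <= g$height, sc >= 1, sc <= g$width)
  thr <- max(params$roi_growth_fraction * pm[sr, sc], .floor)
  max_r2 <- (params$max_radius_um / g$pixel_size)^2
  flood_fill(pm, sr, sc, thr, max_r2, .barrier)
}

# breadth-first 8-connected flood fill from (sr, sc) over map >= thr,
# restricted to a squared radius and optional barrier; always contains the
# start pixel
flood_fill <- function(pm, sr, sc, thr, max_r2, barrier = NULL) {
  nrp <- nrow(pm); ncp <- ncol(pm)
  inroi <- matrix(FALSE, nrp, ncp)
  qr <- integer(nrp * ncp); qc <- qr
  qr[1] <- sr; qc[1] <- sc
  inroi[sr, sc] <- TRUE
  head <- 1L; tail <- 1L
  if (pm[sr, sc] >= thr) while (head <= tail) {
    r <- qr[head]; cc <- qc[head]; head <- head + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nr <- r + dr; ncl <- cc + dc
      if (nr < 1L || nr > nrp || ncl < 1L || ncl > ncp) next
      if (inroi[nr, ncl] || pm[nr, ncl] < thr) next
      if ((nr - sr)^2 + (ncl - sc)^2 > max_r2) next
      if (!is.null(barrier) && barrier[nr, ncl]) next
      inroi[nr, ncl] <- TRUE
      tail <- tail + 1L
      qr[tail] <- nr; qc[tail] <- ncl
    }
  }
  px <- which(inroi, arr.ind = TRUE)
  px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
  colnames(px) <- c("row", "col")
  px
}

#' Temporal full width at half maximum of a transient
#'
#' Width of the trace at half of (max - baseline), with linear interpolation
#' between samples; the baseline defaults to the median of the first 10% of
#' samples (a pre-stimulus estimate). If the trace never recrosses the
#' half-max level on one side of the peak, the width of the available side
#' is doubled and the result is flagged with attribute `one_sided = TRUE`.
#'
#' @param trace Numeric dF/F0 trace with a positive maximum above baseline.
#' @param frame_rate Sampling rate, frames/s.
#' @param baseline Baseline level; `NULL` for the default estimate.
#' @return FWHM in seconds, with attributes `one_sided`, `left_s`,
#'   `right_s` (half-widths).
#' @export
temporal_fwhm <- function(trace, frame_rate, baseline = NULL) {
  stopifnot(length(trace) >= 3, frame_rate > 0)
  if (is.null(baseline))
    baseline <- stats::median(trace[seq_len(max(1L, length(trace) %/% 10))])
  pk <- which.max(trace)
  if (trace[pk] <= baseline) stop("trace has no positive maximum above baseline")
  half <- baseline + (trace[pk] - baseline) / 2
  cross <- function(i, j) {  # fractional index where trace crosses `half`
    i + (half - trace[i]) / (trace[j] - trace[i]) * (j - i)
  }
  left <- NA_real_
  for (i in rev(seq_len(pk - 1)))
    if (trace[i] <= half) { left <- cross(i, i + 1); break }
  right <- NA_real_
  if (pk < length(trace))
    for (i in (pk + 1):length(trace))
      if (trace[i] <= half) { right <- cross(i - 1, i); break }
  lw <- (pk - left) / frame_rate
  rw <- (right - pk) / frame_rate
  one_sided <- is.na(left) || is.na(right)
  w <- if (is.na(left) && is.na(right)) NA_real_
       else if (is.na(left)) 2 * rw
       else if (is.na(right)) 2 * lw
       else lw + rw
  structure(w, one_sided = one_sided, left_s = lw, right_s = rw)
}

# fraction of non-DC spectral power above `cutoff` Hz
highfreq_power_fraction <- function(trace, frame_rate, cutoff) {
  n <- length(trace)
  p <- Mod(stats::fft(trace - mean(trace)))^2
  f <- (seq_len(n) - 1) * frame_rate / n
  keep <- f > 0 & f <= frame_rate / 2
  tot <- sum(p[keep])
  if (tot == 0) return(0)
  sum(p[keep & f > cutoff]) / tot
}

# assemble one hotspot candidate from a grown ROI
build_hotspot <- function(dff, id, seed, roi, params, window = NULL) {
  g <- dff$geometry
  t <- frame_times(g)
  win <- eval_windows(dff$protocol, params, window)
  mat <- matrix(dff$dff, nrow = g$n_frames)
  idx <- (roi[, "col"] - 1L) * g$height + roi[, "row"]
  trace <- rowMeans(mat[, idx, drop = FALSE])
  inwin <- t >= min(win[, "start"]) & t <= max(win[, "end"])
  pk_i <- which(inwin)[which.max(trace[inwin])]
  rep_peaks <- apply(win, 1, function(w) {
    sel <- t >= w["start"] & t <= w["end"]
    if (any(sel)) max(trace[sel]) else NA_real_
  })
  pre <- t < min(win[, "start"])
  pre_med <- if (any(pre)) stats::median(trace[pre]) else 0
  pre_mad <- if (any(pre)) stats::mad(trace[pre]) else 0
  fwhm <- tryCatch(temporal_fwhm(trace, g$frame_rate, baseline = pre_med),
                   error = function(e) structure(NA_real_, one_sided = TRUE))
  structure(list(
    id = as.integer(id),
    seed = c(row = as.integer(seed[1]), col = as.integer(seed[2])),
    roi = roi,
    area_um2 = nrow(roi) * g$pixel_size^2,
    trace = trace,
    time_s = t,
    peak_dff = trace[pk_i],
    peak_time_s = t[pk_i],
    repeat_peaks = as.numeric(rep_peaks),
    fwhm_s = as.numeric(fwhm),
    fwhm_one_sided = isTRUE(attr(fwhm, "one_sided")),
    prestim_median = pre_med,
    prestim_mad = pre_mad,
    windows = win,
    frame_rate = g$frame_rate,
    qc = NULL,
    reject_reason = NA_character_), class = "hotspot")
}

#' Apply the hotspot refinement filters
#'
#' Rejects candidates that fail any of:
#' * `variation`: peak-height variation across stimulation repeats,
#'   `100 * (max - min) / min`, at or above `variation_limit` percent (the
#'   minimum-denominator form is the most permissive reading of the limit);
#'   only tested with more than one repeat;
#' * `size`: ROI area below `min_area` (inclusive threshold: `area >=
#'   min_area` is accepted);
#' * `noise`: peak SNR versus the pre-stimulus trace MAD below `snr_min`,
#'   or the trace's global maximum falling outside the evaluation window
#'   ("absent peak"), or more than `highfreq_max_fraction` of the non-DC
#'   spectral power above `highfreq_cutoff` Hz.
#'
#' Every candidate ends up in exactly one of `accepted` or `rejected`, and
#' each rejection is logged with its reasons.
#'
#' @param candidates List of hotspot candidates (from the detection
#'   pipeline; see [detect_hotspots()]).
#' @param params A [detection_params()].
#' @param n_repeats Number of stimulation repeats the traces cover.
#' @return List with `accepted`, `rejected` (both lists of hotspots with
#'   filled `qc` flags) and `log` (data.frame `id`, `reason`).
#' @export
filter_hotspots <- function(candidates, params = detection_params(),
                            n_repeats = 1) {
  accepted <- list(); rejected <- list()
  log <- data.frame(id = integer(0), reason = character(0))
  for (h in candidates) {
    reasons <- character(0)

    variation_ok <- TRUE
    if (n_repeats > 1) {
      pks <- h$repeat_peaks[!is.na(h$repeat_peaks)]
      if (length(pks) < n_repeats || min(pks) <= 0) {
        variation_ok <- FALSE
        reasons <- c(reasons, "variation: missing or non-positive repeat peak")
      } else {
        v <- 100 * (max(pks) - min(pks)) / min(pks)
        if (v >= params$variation_limit) {
          variation_ok <- FALSE
          reasons <- c(reasons, sprintf("variation: %.0f%% >= %.0f%%", v,
                                        params$variation_limit))
        }
      }
    }

    size_ok <- h$area_um2 >= params$min_area
    if (!size_ok)
      reasons <- c(reasons, sprintf("size: %.3f um2 < %.3f um2",
                                    h$area_um2, params$min_area))

    noise_ok <- TRUE
    amp <- h$peak_dff - h$prestim_median
    snr <- if (h$prestim_mad > 0) amp / h$prestim_mad
           else if (amp > 0) Inf else 0
    if (snr < params$snr_min) {
      noise_ok <- FALSE
      reasons <- c(reasons, sprintf("noise: SNR %.2f < %.2f", snr,
                                    params$snr_min))
    }
    gmax_t <- h$time_s[which.max(h$trace)]
    if (gmax_t < min(h$windows[, "start"]) ||
        gmax_t > max(h$windows[, "end"])) {
      noise_ok <- FALSE
      reasons <- c(reasons, "noise: trace maximum outside evaluation window")
    }
    hf <- highfreq_power_fraction(h$trace, h$frame_rate,
                                  params$highfreq_cutoff)
    if (hf > params$highfreq_max_fraction) {
      noise_ok <- FALSE
      reasons <- c(reasons,
                   sprintf("noise: high-frequency power fraction %.2f > %.2f",
                           hf, params$highfreq_max_fraction))
    }

    h$qc <- list(variation_ok = variation_ok, size_ok = size_ok,
                 noise_ok = noise_ok)
    if (variation_ok && size_ok && noise_ok) {
      accepted[[length(accepted) + 1]] <- h
    } else {
      h$reject_reason <- paste(reasons, collapse = "; ")
      rejected[[length(rejected) + 1]] <- h
      log <- rbind(log, data.frame(id = h$id, reason = h$reject_reason))
    }
  }
  list(accepted = accepted, rejected = rejected, log = log)
}

#' Detect dopamine-release hotspots
#'
#' End-to-end detection: score map (peak derivative) -> seed finding (local
#' maxima above the noise threshold) -> half-max ROI growth -> trace, peak,
#' FWHM characterization -> refinement filters. Seeds are processed in
#' descending score order with greedy non-maximum suppression: a later seed
#' falling inside an already-claimed ROI is suppressed, a later ROI cannot
#' flood into claimed pixels, and a candidate whose grown ROI contains a
#' pixel brighter than its seed peak divided by `roi_growth_fraction` is
#' suppressed as inconsistent — the seed would lie outside that pixel's own
#' half-max region, the signature of a spurious flank seed riding the halo
#' of a stronger hotspot. One release site therefore yields one candidate.
#' Deterministic given its inputs.
#'
#' @param dff A [compute_dff()] stack (with a protocol, or pass `window`).
#' @param params A [detection_params()].
#' @param window Optional explicit `(start, end)` evaluation window, s.
#' @return A `hotspot_set`: list with `hotspots` (accepted), `rejected`,
#'   `log` (rejection log), `seeds`, `params`.
#' @export
detect_hotspots <- function(dff, params = detection_params(), window = NULL) {
  sm <- score_map(dff, params, window)
  seeds <- find_seeds(sm, params)
  pm <- peak_map(dff, params, window)
  fl <- peak_map_floor(dff, params, window)
  g <- dff$geometry
  claimed <- matrix(FALSE, g$height, g$width)
  candidates <- list()
  for (i in seq_len(nrow(seeds))) {
    seed <- c(seeds$row[i], seeds$col[i])
    if (claimed[seed[1], seed[2]]) next
    roi <- grow_roi(dff, seed, params, window, .peak_map = pm, .floor = fl,
                    .barrier = claimed)
    if (max(pm[roi]) * params$roi_growth_fraction > pm[seed[1], seed[2]])
      next  # seed not dominant in its own ROI: flank of a stronger hotspot
    claimed[roi] <- TRUE
    candidates[[length(candidates) + 1]] <-
      build_hotspot(dff, length(candidates) + 1, seed, roi, params, window)
  }
  n_rep <- if (!is.null(dff$protocol)) dff$protocol$n_repeats else 1
  res <- filter_hotspots(candidates, params, n_repeats = n_rep)
  structure(list(hotspots = res$accepted, rejected = res$rejected,
                 log = res$log, seeds = seeds, params = params),
            class = "hotspot_set")
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Hotspot detection: %d seed(s), %d accepted, %d rejected\n",
              nrow(x$seeds), length(x$hotspots), length(x$rejected)))
  if (nrow(x$log)) {
    cat("Rejections:\n")
    for (i in seq_len(nrow(x$log)))
      cat(sprintf("  #%d: %s\n", x$log$id[i], x$log$reason[i]))
  }
  invisible(x)
}

#' Tabulate a hotspot set
#'
#' @param x A `hotspot_set` from [detect_hotspots()].
#' @param which `"accepted"` (default), `"rejected"`, or `"all"`.
#' @return data.frame with one row per hotspot: id, seed coordinates, area,
#'   peak dF/F0, peak time, FWHM, QC flags and rejection reason.
#' @export
hotspot_table <- function(x, which = c("accepted", "rejected", "all")) {
  which <- match.arg(which)
  hs <- switch(which, accepted = x$hotspots, rejected = x$rejected,
               all = c(x$hotspots, x$rejected))
  if (!length(hs))
    return(data.frame(id = integer(0), row = integer(0), col = integer(0),
                      area_um2 = numeric(0), peak_dff = numeric(0),
                      peak_time_s = numeric(0), fwhm_s = numeric(0),
                      variation_ok = logical(0), size_ok = logical(0),
                      noise_ok = logical(0), reject_reason = character(0)))
  do.call(rbind, lapply(hs, function(h) data.frame(
    id = h$id, row = h$seed["row"], col = h$seed["col"],
    area_um2 = h$area_um2, peak_dff = h$peak_dff,
    peak_time_s = h$peak_time_s, fwhm_s = h$fwhm_s,
    variation_ok = h$qc$variation_ok, size_ok = h$qc$size_ok,
    noise_ok = h$qc$noise_ok, reject_reason = h$reject_reason,
    row.names = NULL)))
}
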
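# brute-force reference detector: an independent, naive per-pixel
# implementation of the documented detection rules, used to cross-check
# detect_hotspots() on small movies. Deliberately loop-based and slow.

ref_smooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x); h <- (w - 1) / 2
  vapply(seq_len(n),
         function(i) mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

ref_windows <- function(protocol, params) {
  on <- protocol$stim_start +
    (seq_len(protocol$n_repeats) - 1) * protocol$repeat_period
  cbind(start = on, end = on + protocol$stim_duration + params$peak_window_pad)
}

ref_hf_fraction <- function(trace, rate, cutoff) {
  n <- length(trace)
  p <- Mod(stats::fft(trace - mean(trace)))^2
  f <- (seq_len(n) - 1) * rate / n
  keep <- f > 0 & f <= rate / 2
  tot <- sum(p[keep])
  if (tot == 0) return(0)
  sum(p[keep & f > cutoff]) / tot
}

reference_detect <- function(dff, params) {
  g <- dff$geometry
  H <- g$height; W <- g$width
  rate <- g$frame_rate
  t <- (seq_len(g$n_frames) - 1) / rate
  win <- ref_windows(dff$protocol, params)
  w0 <- min(win[, "start"]); w1 <- max(win[, "end"])

  # per-pixel max-derivative score inside the window; the same statistic
  # pre-stimulus is the noise reference
  score <- matrix(-Inf, H, W)
  prevec <- c()
  pkmap <- matrix(-Inf, H, W)
  prepk <- c()
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!dff$mask[r, c]) next
    tr <- dff$dff[, r, c]
    d <- diff(ref_smooth(tr, params$derivative_smoothing)) * rate
    td <- t[-1]
    score[r, c] <- max(d[td >= w0 & td <= w1])
    prevec <- c(prevec, max(d[td < w0]))
    trs <- ref_smooth(tr, params$peak_smoothing)
    pkmap[r, c] <- max(trs[t >= w0 & t <= w1])
    prepk <- c(prepk, max(trs[t < w0]))
  }
  thr <- stats::median(prevec) + params$snr_min * stats::mad(prevec)
  floor_pk <- stats::median(prepk) + params$snr_min * stats::mad(prepk)

  # 8-neighborhood local maxima above threshold
  cand <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    s <- score[r, c]
    if (!is.finite(s) || s <= thr) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (score[rr, cc] > s) ok <- FALSE
    }
    if (ok) cand <- rbind(cand, c(r, c, s))
  }
  if (is.null(cand))
    return(list(seeds = data.frame(row = integer(0), col = integer(0)),
                accepted = list(), rejected = list()))
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  keep <- rep(FALSE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (sum((cand[i, 1:2] - cand[j, 1:2])^2) < params$min_separation^2)
        ok <- FALSE
    }
    keep[i] <- ok
  }
  seeds <- cand[keep, , drop = FALSE]

  max_r2 <- (params$max_radius_um / g$pixel_size)^2
  claimed <- matrix(FALSE, H, W)
  accepted <- list(); rejected <- list()
  for (i in seq_len(nrow(seeds))) {
    sr <- seeds[i, 1]; sc <- seeds[i, 2]
    if (claimed[sr, sc]) next
    thr2 <- max(params$roi_growth_fraction * pkmap[sr, sc], floor_pk)
    inroi <- matrix(FALSE, H, W)
    inroi[sr, sc] <- TRUE
    if (pkmap[sr, sc] >= thr2) repeat {  # naive fixed-point flood
      grew <- FALSE
      for (r in seq_len(H)) for (c in seq_len(W)) {
        if (inroi[r, c] || pkmap[r, c] < thr2 || claimed[r, c]) next
        if ((r - sr)^2 + (c - sc)^2 > max_r2) next
        nb <- FALSE
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && inroi[rr, cc])
            nb <- TRUE
        }
        if (nb) { inroi[r, c] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    roi <- which(inroi, arr.ind = TRUE)
    roi <- roi[order(roi[, 1], roi[, 2]), , drop = FALSE]
    if (max(pkmap[roi]) * params$roi_growth_fraction > pkmap[sr, sc]) next
    claimed[roi] <- TRUE

    trace <- rep(0, g$n_frames)
    for (k in seq_len(nrow(roi)))
      trace <- trace + dff$dff[, roi[k, 1], roi[k, 2]]
    trace <- trace / nrow(roi)
    area <- nrow(roi) * g$pixel_size^2
    inwin <- t >= w0 & t <= w1
    peak <- max(trace[inwin])
    rep_peaks <- apply(win, 1, function(w) max(trace[t >= w["start"] &
                                                     t <= w["end"]]))
    pre <- t < w0
    pre_med <- stats::median(trace[pre])
    pre_mad <- stats::mad(trace[pre])

    reasons <- character(0)
    if (dff$protocol$n_repeats > 1) {
      if (min(rep_peaks) <= 0 ||
          100 * (max(rep_peaks) - min(rep_peaks)) / min(rep_peaks) >=
            params$variation_limit)
        reasons <- c(reasons, "variation")
    }
    if (area < params$min_area) reasons <- c(reasons, "size")
    amp <- peak - pre_med
    snr <- if (pre_mad > 0) amp / pre_mad else if (amp > 0) Inf else 0
    if (snr < params$snr_min) reasons <- c(reasons, "snr")
    if (t[which.max(trace)] < w0 || t[which.max(trace)] > w1)
      reasons <- c(reasons, "absent_peak")
    if (ref_hf_fraction(trace, rate, params$highfreq_cutoff) >
          params$highfreq_max_fraction)
      reasons <- c(reasons, "highfreq")

    rec <- list(seed = c(sr, sc), roi = roi, area_um2 = area,
                peak_dff = peak, reasons = reasons)
    if (length(reasons) == 0) accepted[[length(accepted) + 1]] <- rec
    else rejected[[length(rejected) + 1]] <- rec
  }
  list(seeds = data.frame(row = seeds[, 1], col = seeds[, 2]),
       accepted = accepted, rejected = rejected)
}
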
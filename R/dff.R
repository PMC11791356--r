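#' Raw fluorescence movie container
#'
#' @param frames 3-D numeric array `(time, row, col)` of nonnegative
#'   intensities.
#' @param geometry A [movie_geometry()]; its `n_frames`/`height`/`width`
#'   must match the array.
#' @param protocol Optional [stimulus_protocol()].
#' @return A `movie_stack` object.
#' @export
movie_stack <- function(frames, geometry, protocol = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3,
            inherits(geometry, "movie_geometry"))
  d <- dim(frames)
  if (d[1] != geometry$n_frames || d[2] != geometry$height ||
      d[3] != geometry$width)
    stop("frame array dimensions do not match the geometry")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and >= 0")
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stimulus_protocol"))
  structure(list(frames = frames, geometry = geometry, protocol = protocol),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("Fluorescence movie: %d frames of %d x %d px (%.2f um/px, %g fps)\n",
              g$n_frames, g$height, g$width, g$pixel_size, g$frame_rate))
  if (!is.null(x$protocol))
    cat(sprintf("  stimulation: %g Hz for %g s from t = %g s (%d repeat%s)\n",
                x$protocol$stim_frequency, x$protocol$stim_duration,
                x$protocol$stim_start, x$protocol$n_repeats,
                if (x$protocol$n_repeats > 1) "s" else ""))
  invisible(x)
}

# centered moving average along rows of a (frames x pixels) matrix;
# the window shrinks symmetrically at the edges so a constant column is a
# fixed point
moving_average_mat <- function(mat, window) {
  n <- nrow(mat)
  h <- (window - 1L) %/% 2L
  cs <- rbind(0, apply(mat, 2, cumsum))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Estimate the per-pixel baseline F0
#'
#' Iterative low-pass/clip baseline: for each pixel trace, `n_rounds` times
#' smooth with a centered moving average of `window_frames` and replace
#' samples exceeding the smoothed estimate by the estimate (asymmetric
#' clipping, so positive transients cannot inflate the baseline); the final
#' F0 is the temporal mean of the last smoothed, clipped trace. A constant
#' trace is a fixed point. The default window (61 frames, about 12 s at
#' 5 fps) is longer than the 5-s stimulus plus the few-second clearance
#' decay, so a full stimulus-locked transient cannot masquerade as drift;
#' 3 rounds suffice to push the residual transient contamination of F0
#' below about 1-2%.
#'
#' @param movie A [movie_stack()].
#' @param window_frames Odd moving-average window length, >= 3 (default 61).
#' @param n_rounds Number of smooth-and-clip rounds, >= 1 (default 3).
#' @return Numeric matrix (height x width) of per-pixel F0.
#' @export
estimate_baseline <- function(movie, window_frames = 61, n_rounds = 3) {
  stopifnot(inherits(movie, "movie_stack"),
            window_frames >= 3, window_frames %% 2 == 1, n_rounds >= 1)
  g <- movie$geometry
  if (g$n_frames < window_frames)
    stop("movie is shorter than the smoothing window")
  mat <- matrix(movie$frames, nrow = g$n_frames)  # frames x pixels
  for (r in seq_len(n_rounds)) {
    sm <- moving_average_mat(mat, window_frames)
    mat <- pmin(mat, sm)
  }
  matrix(colMeans(mat), nrow = g$height, ncol = g$width)
}

#' Compute the dF/F0 stack
#'
#' `dff[t, r, c] = (F[t, r, c] - F0[r, c]) / F0[r, c]` wherever the baseline
#' is valid. Pixels with F0 at or below the validity floor — the larger of
#' the absolute `floor` and 1% of the median baseline — are masked invalid
#' (their dF/F0 is `NA`, never silently 0) to prevent division blow-ups on
#' dark background.
#'
#' @param movie A [movie_stack()].
#' @param baseline Per-pixel F0 matrix matching the movie spatially; if
#'   missing, computed by [estimate_baseline()] with `...` passed on.
#' @param floor Absolute F0 validity floor in counts (default 1); must be
#'   > 0.
#' @param ... Passed to [estimate_baseline()] when `baseline` is missing.
#' @return A `dff_stack` object: `dff` (3-D array), `baseline`, `mask`
#'   (TRUE = valid), `geometry`, `protocol`, `params`.
#' @export
compute_dff <- function(movie, baseline = NULL, floor = 1, ...) {
  stopifnot(inherits(movie, "movie_stack"), floor > 0)
  g <- movie$geometry
  used <- list(floor = floor)
  if (is.null(baseline)) {
    baseline <- estimate_baseline(movie, ...)
    used <- c(used, list(...))
  }
  stopifnot(is.matrix(baseline), nrow(baseline) == g$height,
            ncol(baseline) == g$width)
  mask <- baseline > max(floor, 0.01 * stats::median(baseline))
  if (!any(mask))
    warning("all pixels masked: baseline entirely at or below the floor")
  b <- baseline
  b[!mask] <- NA_real_
  dff <- sweep(sweep(movie$frames, c(2, 3), b, "-"), c(2, 3), b, "/")
  structure(list(dff = dff, baseline = baseline, mask = mask,
                 geometry = g, protocol = movie$protocol, params = used),
            class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("dF/F0 stack: %d frames of %d x %d px; %d/%d pixels valid\n",
              g$n_frames, g$height, g$width, sum(x$mask), length(x$mask)))
  v <- matrix(x$dff, nrow = g$n_frames)[, as.vector(x$mask), drop = FALSE]
  rng <- range(v[is.finite(v)])
  cat(sprintf("  dF/F0 range over valid pixels: [%.3g, %.3g]\n",
              rng[1], rng[2]))
  invisible(x)
}
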
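#' Categorize hotspot sizes
#'
#' Bins hotspot areas into small (< 9 um^2), middle (9-36 um^2, boundaries
#' inclusive) and large (> 36 um^2). The bounds are the squares of 3 um and
#' 6 um characteristic lengths.
#'
#' @param areas_um2 Hotspot areas in um^2 (or a `hotspot_set`).
#' @param bounds_um2 Length-2 category bounds (default `c(9, 36)`).
#' @return Named integer vector `c(small, middle, large)`.
#' @export
size_categories <- function(areas_um2, bounds_um2 = c(9, 36)) {
  if (inherits(areas_um2, "hotspot_set"))
    areas_um2 <- vapply(areas_um2$hotspots, `[[`, numeric(1), "area_um2")
  stopifnot(is.numeric(areas_um2), all(areas_um2 >= 0),
            length(bounds_um2) == 2, bounds_um2[1] < bounds_um2[2])
  c(small = sum(areas_um2 < bounds_um2[1]),
    middle = sum(areas_um2 >= bounds_um2[1] & areas_um2 <= bounds_um2[2]),
    large = sum(areas_um2 > bounds_um2[2]))
}

#' Summarize hotspots for one field of view
#'
#' Per-movie aggregation: hotspot count, mean +- sd of peak dF/F0 and area
#' (unbiased sd; reported as 0 with `sd_defined = FALSE` when n < 2), and
#' size-category counts and fractions.
#'
#' @param hotspots A `hotspot_set` from [detect_hotspots()], or a list of
#'   hotspot objects.
#' @param movie_id Identifier of the movie/FOV.
#' @param group Group label (e.g. `"control_early"`).
#' @return A `fov_summary` (one-row data.frame plus category attributes).
#' @export
summarize_fov <- function(hotspots, movie_id = "fov1", group = NA_character_) {
  hs <- if (inherits(hotspots, "hotspot_set")) hotspots$hotspots else hotspots
  peaks <- vapply(hs, `[[`, numeric(1), "peak_dff")
  areas <- vapply(hs, `[[`, numeric(1), "area_um2")
  n <- length(hs)
  sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else 0
  cats <- size_categories(areas)
  out <- data.frame(
    movie_id = movie_id, group = group, n_hotspots = n,
    mean_peak_dff = if (n) mean(peaks) else NA_real_,
    sd_peak_dff = sd0(peaks),
    mean_area_um2 = if (n) mean(areas) else NA_real_,
    sd_area_um2 = sd0(areas),
    n_small = cats["small"], n_middle = cats["middle"],
    n_large = cats["large"],
    frac_small = if (n) cats[["small"]] / n else NA_real_,
    frac_middle = if (n) cats[["middle"]] / n else NA_real_,
    frac_large = if (n) cats[["large"]] / n else NA_real_,
    sd_defined = n >= 2, row.names = NULL)
  class(out) <- c("fov_summary", "data.frame")
  out
}

#' Fit exponential clearance kinetics
#'
#' Least-squares fit of `a * exp(-t / tau) + b` to the decay phase of a
#' dF/F0 trace, from `fit_start` (default: the trace's peak frame) onward.
#' Initialized from a log-linear regression on the offset-subtracted trace.
#' The reported `tau` is the exponential constant only; the offset `b`
#' absorbs residual baseline. A non-decaying trace yields
#' `converged = FALSE` rather than an error.
#'
#' @param trace Numeric dF/F0 trace.
#' @param frame_rate Sampling rate in frames/s.
#' @param fit_start Index of the first fitted sample (default `which.max`).
#' @return A `clearance_fit` object: `tau` (s), `amplitude`, `offset`,
#'   `rss`, `converged`, `fitted`, `time_s`.
#' @examples
#' tr <- simulate_clearance_trace(tau = 2, peak_dff = 1, noise_sd = 0)
#' fit_clearance(tr, frame_rate = 5)
#' @export
fit_clearance <- function(trace, frame_rate, fit_start = which.max(trace)) {
  stopifnot(is.numeric(trace), frame_rate > 0,
            fit_start >= 1, fit_start <= length(trace))
  y <- as.numeric(trace[fit_start:length(trace)])
  if (length(y) < 5) stop("need at least 5 frames after the peak")
  t <- (seq_along(y) - 1) / frame_rate

  fail <- function(msg) structure(
    list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
         rss = NA_real_, converged = FALSE, message = msg,
         fitted = NULL, time_s = t, data = y), class = "clearance_fit")

  # log-linear initialisation on the offset-subtracted trace
  b0 <- min(y)
  ypos <- y - b0 + 1e-12
  ll <- stats::lm(log(ypos) ~ t)
  slope <- unname(stats::coef(ll)[2])
  if (!is.finite(slope) || slope >= 0)
    return(fail("trace does not decay"))
  tau0 <- -1 / slope
  a0 <- max(y) - b0
  if (a0 <= 0) return(fail("no positive decay amplitude"))

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t / tau) + b,
                      data = data.frame(t = t, y = y),
                      start = list(a = a0, tau = tau0, b = b0),
                      lower = c(a = 1e-12, tau = 1e-9, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  est <- stats::coef(fit)
  if (!is.finite(est["tau"]) || est["tau"] <= 0)
    return(fail("fit did not converge to a positive time constant"))
  # honesty check: the exponential must explain the decay better than a
  # constant, otherwise report non-convergence (e.g. pure noise traces)
  res <- y - stats::fitted(fit)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss > 0 && rss > 0.9 * tss)
    return(fail("exponential explains < 10% of the variance"))
  structure(list(tau = unname(est["tau"]), amplitude = unname(est["a"]),
                 offset = unname(est["b"]), rss = rss, converged = TRUE,
                 message = "converged",
                 fitted = as.numeric(stats::fitted(fit)),
                 time_s = t, data = y), class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat("Exponential clearance fit\n")
  if (!x$converged) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  tau       = %.4g s\n", x$tau))
  cat(sprintf("  amplitude = %.4g dF/F0\n", x$amplitude))
  cat(sprintf("  offset    = %.4g\n", x$offset))
  cat(sprintf("  RSS       = %.4g on %d points\n", x$rss, length(x$data)))
  invisible(x)
}

#' @export
coef.clearance_fit <- function(object, ...) {
  c(tau = object$tau, amplitude = object$amplitude, offset = object$offset)
}

#' @export
predict.clearance_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  t <- if (is.null(newdata)) object$time_s
       else if (is.numeric(newdata)) newdata else newdata$time_s
  object$amplitude * exp(-t / object$tau) + object$offset
}

# significance stars at the 0.05 / 0.01 / 0.005 / 0.001 thresholds
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "****" else if (p < 0.005) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare measurement groups
#'
#' Two groups: classical pooled-variance two-sample Student's t-test
#' (two-tailed; Welch's correction behind `welch = TRUE`). Three or more
#' groups: one-way ANOVA with Tukey's HSD post-hoc comparisons.
#' Significance stars use the 0.05 / 0.01 / 0.005 / 0.001 thresholds.
#'
#' @param ... Two or more numeric sample vectors (each n >= 2), or a single
#'   named list of them.
#' @param welch Use Welch's unequal-variance t-test for pairs (default
#'   `FALSE` = pooled Student's t).
#' @return A `group_comparison`: `test`, `statistic`, `df`, `p_value`,
#'   `stars`, `means` (group mean +- sem table), and for ANOVA a `tukey`
#'   data.frame of pairwise contrasts.
#' @examples
#' compare_groups(control = c(2.1, 2.5, 2.3), pd = c(3.1, 3.5, 3.3))
#' @export
compare_groups <- function(..., welch = FALSE) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !is.numeric(gs[[1]]))
    gs <- gs[[1]]
  if (length(gs) < 2) stop("need at least two groups")
  if (is.null(names(gs)) || any(names(gs) == ""))
    names(gs) <- paste0("group", seq_along(gs))
  for (g in gs) stopifnot(is.numeric(g), length(g) >= 2)

  means <- data.frame(
    group = names(gs),
    n = vapply(gs, length, integer(1)),
    mean = vapply(gs, mean, numeric(1)),
    sem = vapply(gs, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    row.names = NULL)

  if (length(gs) == 2) {
    a <- gs[[1]]; b <- gs[[2]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) {
        out <- list(test = "Student t (degenerate: zero variance)",
                    statistic = 0, df = length(a) + length(b) - 2,
                    p_value = 1, stars = "ns", means = means,
                    degenerate = TRUE)
        class(out) <- "group_comparison"
        return(out)
      }
      # zero variance but different means: infinitely separated
      out <- list(test = "Student t (degenerate: zero variance)",
                  statistic = Inf, df = length(a) + length(b) - 2,
                  p_value = 0, stars = "****", means = means,
                  degenerate = TRUE)
      class(out) <- "group_comparison"
      return(out)
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    out <- list(test = if (welch) "Welch t" else "Student t (pooled)",
                statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, stars = p_stars(tt$p.value),
                means = means, degenerate = FALSE)
  } else {
    values <- unlist(gs, use.names = FALSE)
    fac <- factor(rep(names(gs), vapply(gs, length, integer(1))),
                  levels = names(gs))
    fit <- stats::aov(values ~ fac)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$fac
    out <- list(test = "one-way ANOVA + Tukey HSD",
                statistic = an[["F value"]][1],
                df = c(an[["Df"]][1], an[["Df"]][2]),
                p_value = an[["Pr(>F)"]][1],
                stars = p_stars(an[["Pr(>F)"]][1]),
                means = means,
                tukey = data.frame(contrast = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   stars = vapply(tk[, "p adj"], p_stars,
                                                  character(1)),
                                   row.names = NULL),
                degenerate = FALSE)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, "\n")
  cat(sprintf("  statistic = %.4g, df = %s, p = %.4g %s\n",
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, x$stars))
  for (i in seq_len(nrow(x$means)))
    cat(sprintf("  %s: mean %.4g +- %.4g sem (n = %d)\n",
                x$means$group[i], x$means$mean[i], x$means$sem[i],
                x$means$n[i]))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    for (i in seq_len(nrow(x$tukey)))
      cat(sprintf("    %s: diff %.4g, p.adj %.4g %s\n",
                  x$tukey$contrast[i], x$tukey$diff[i], x$tukey$p_adj[i],
                  x$tukey$stars[i]))
  }
  invisible(x)
}
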
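#' Nanosensor transduction parameters
#'
#' Constructor for the one-site (Langmuir) turn-on response model of the
#' (GT)6-ssDNA/SWCNT dopamine nanosensor. `kd` is the dissociation constant
#' (concentration at half-maximal response) and `dfmax` the saturation
#' amplitude of the fractional fluorescence change dF/F0.
#'
#' The defaults reproduce the calibrated sensor: Kd = 15 uM, and
#' dfmax = 6.44 derived by inverting the isotherm at the reported working
#' point (dF/F0 = 5.60 at 100 uM): 5.6 * (100 + 15) / 100 = 6.44.
#'
#' @param kd Dissociation constant in uM; must be > 0.
#' @param dfmax Saturation dF/F0 (dimensionless); must be > 0.
#' @param hill Hill exponent; defaults to 1 (pure Langmuir isotherm).
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(kd = 15, dfmax = 6.44, hill = 1) {
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd), kd > 0,
            is.numeric(dfmax), length(dfmax) == 1L, is.finite(dfmax), dfmax > 0,
            is.numeric(hill), length(hill) == 1L, is.finite(hill), hill > 0)
  structure(list(kd = kd, dfmax = dfmax, hill = hill),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat("Sensor response parameters (one-site isotherm)\n")
  cat(sprintf("  Kd     = %.4g uM\n", x$kd))
  cat(sprintf("  dFmax  = %.4g (dF/F0 at saturation)\n", x$dfmax))
  if (x$hill != 1) cat(sprintf("  Hill n = %.4g\n", x$hill))
  invisible(x)
}

#' Sensor fluorescence response to dopamine
#'
#' Evaluates the one-site binding isotherm
#' dF/F0(c) = dfmax * c^n / (c^n + kd^n) (n = 1 by default), the fractional
#' fluorescence turn-on at dopamine concentration `c`.
#'
#' @param params A [sensor_params()] object.
#' @param c Dopamine concentration(s) in uM; must be >= 0.
#' @return dF/F0 value(s), in `[0, dfmax)`, monotone nondecreasing in `c`.
#' @examples
#' p <- sensor_params(kd = 15, dfmax = 6.44)
#' da_response(p, c(0, 15, 100))
#' @export
da_response <- function(params, c) {
  stopifnot(inherits(params, "sensor_params"))
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    stop("concentrations must be finite and >= 0")
  cn <- c^params$hill
  params$dfmax * cn / (cn + params$kd^params$hill)
}

#' Invert the sensor response
#'
#' Concentration giving a target dF/F0; inverse of [da_response()].
#' `dff` must lie in `[0, dfmax)`.
#'
#' @inheritParams da_response
#' @param dff Target dF/F0 value(s).
#' @return Concentration(s) in uM.
#' @export
invert_response <- function(params, dff) {
  stopifnot(inherits(params, "sensor_params"))
  if (any(dff < 0) || any(dff >= params$dfmax))
    stop("dff must be in [0, dfmax)")
  (params$kd^params$hill * dff / (params$dfmax - dff))^(1 / params$hill)
}

#' Dose-response table
#'
#' @param concentrations Strictly increasing dopamine concentrations (uM, >= 0).
#' @param responses dF/F0 at each concentration.
#' @param sd Optional per-point replicate standard deviations.
#' @return A `dose_response` data.frame with columns `concentration_uM`,
#'   `dff` and (optionally) `sd`.
#' @export
dose_response <- function(concentrations, responses, sd = NULL) {
  stopifnot(is.numeric(concentrations), is.numeric(responses),
            length(concentrations) == length(responses),
            all(is.finite(concentrations)), all(concentrations >= 0),
            all(diff(concentrations) > 0))
  d <- data.frame(concentration_uM = concentrations, dff = responses)
  if (!is.null(sd)) {
    stopifnot(length(sd) == nrow(d), all(sd >= 0))
    d$sd <- sd
  }
  class(d) <- c("dose_response", "data.frame")
  d
}

#' Fit the one-site binding isotherm to a dose-response curve
#'
#' Least-squares fit of dF/F0(c) = dfmax * c / (c + kd) to a measured
#' dose-response table. Unweighted unless the table carries replicate
#' standard deviations, in which case inverse-variance weights are used.
#' Initialisation: dfmax0 = max(response), kd0 = the concentration whose
#' response is nearest dfmax0 / 2.
#'
#' @param curve A [dose_response()] table (or data.frame with columns
#'   `concentration_uM`, `dff`, optional `sd`) with at least 3 distinct
#'   positive concentrations.
#' @param init Optional [sensor_params()] starting values.
#' @param hill Hill exponent held fixed during the fit (default 1).
#' @return An object of class `isotherm_fit` with elements `params`
#'   (a [sensor_params()]), `rss`, `fitted`, `residuals`, `converged`,
#'   `message`, and the data. On degenerate data (e.g. all-zero responses)
#'   a non-converged fit report is returned rather than an error.
#' @examples
#' p <- sensor_params(15, 6.44)
#' cc <- 10^seq(-3, 3, length.out = 12)
#' fit <- fit_isotherm(dose_response(cc, da_response(p, cc)))
#' coef(fit)
#' @export
fit_isotherm <- function(curve, init = NULL, hill = 1) {
  stopifnot(is.data.frame(curve),
            all(c("concentration_uM", "dff") %in% names(curve)))
  conc <- curve$concentration_uM
  dff <- curve$dff
  if (sum(conc > 0) < 3)
    stop("need at least 3 distinct positive concentrations")
  w <- if ("sd" %in% names(curve) && all(curve$sd > 0)) 1 / curve$sd^2
       else rep(1, length(conc))

  fail <- function(msg) {
    structure(list(params = NULL, rss = NA_real_, fitted = NULL,
                   residuals = NULL, converged = FALSE, message = msg,
                   data = curve, hill = hill),
              class = "isotherm_fit")
  }
  if (max(dff) <= 0)
    return(fail("responses are non-positive; half-saturation cannot be bracketed"))

  if (is.null(init)) {
    dfmax0 <- max(dff)
    kd0 <- conc[which.min(abs(dff - dfmax0 / 2))]
    if (kd0 <= 0) kd0 <- min(conc[conc > 0])
  } else {
    stopifnot(inherits(init, "sensor_params"))
    dfmax0 <- init$dfmax
    kd0 <- init$kd
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      dff ~ dfmax * conc^hill / (conc^hill + kd^hill),
      data = data.frame(conc = conc, dff = dff),
      start = list(dfmax = dfmax0, kd = kd0),
      weights = w,
      lower = c(dfmax = 1e-12, kd = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))

  est <- stats::coef(fit)
  if (!all(is.finite(est)) || any(est <= 0))
    return(fail("fit did not converge to positive parameters"))
  res <- dff - stats::fitted(fit)
  structure(list(
    params = sensor_params(kd = unname(est["kd"]), dfmax = unname(est["dfmax"]),
                           hill = hill),
    rss = sum(res^2),
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(res),
    converged = TRUE,
    message = "converged",
    data = curve,
    hill = hill), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("One-site isotherm fit\n")
  if (!x$converged) {
    cat("  FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd    = %.6g uM\n", x$params$kd))
  cat(sprintf("  dFmax = %.6g\n", x$params$dfmax))
  cat(sprintf("  RSS   = %.6g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.isotherm_fit <- function(object, ...) {
  if (!object$converged) return(c(kd = NA_real_, dfmax = NA_real_))
  c(kd = object$params$kd, dfmax = object$params$dfmax)
}

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  conc <- if (is.null(newdata)) object$data$concentration_uM
          else if (is.numeric(newdata)) newdata
          else newdata$concentration_uM
  da_response(object$params, conc)
}

#' @export
summary.isotherm_fit <- function(object, ...) {
  print(object)
  if (object$converged) {
    cat(sprintf("  residual sd = %.4g\n",
                stats::sd(object$residuals)))
  }
  invisible(object)
}

#' Emission spectrum container
#'
#' @param wavelengths Increasing wavelength grid in nm (typically 900-1500).
#' @param intensities Nonnegative intensities, same length.
#' @return An `emission_spectrum` data.frame.
#' @export
emission_spectrum <- function(wavelengths, intensities) {
  stopifnot(is.numeric(wavelengths), is.numeric(intensities),
            length(wavelengths) == length(intensities),
            all(diff(wavelengths) > 0), all(intensities >= 0))
  structure(data.frame(wavelength_nm = wavelengths, intensity = intensities),
            class = c("emission_spectrum", "data.frame"))
}

#' dF/F0 at the spectral peak
#'
#' Locates the wavelength of maximal baseline intensity inside a window
#' (default 1100-1160 nm, bracketing the (9,4)-chirality peak at 1130 nm)
#' and returns (I1 - I0) / I0 there: the solution-phase dF/F0 readout.
#'
#' @param spec0 Baseline [emission_spectrum()] (before analyte).
#' @param spec1 Spectrum after analyte addition, on the identical grid.
#' @param window_nm Length-2 wavelength window (nm) searched for the peak.
#' @return A single dF/F0 value with attribute `peak_nm`.
#' @export
peak_response <- function(spec0, spec1, window_nm = c(1100, 1160)) {
  stopifnot(is.data.frame(spec0), is.data.frame(spec1),
            length(window_nm) == 2, window_nm[1] < window_nm[2])
  if (!isTRUE(all.equal(spec0$wavelength_nm, spec1$wavelength_nm)))
    stop("spectra are not on identical wavelength grids")
  wl <- spec0$wavelength_nm
  inside <- wl >= window_nm[1] & wl <= window_nm[2]
  if (!any(inside)) stop("window contains no grid points")
  idx <- which(inside)[which.max(spec0$intensity[inside])]
  f0 <- spec0$intensity[idx]
  if (f0 <= 0) stop("zero baseline intensity at the spectral peak")
  structure((spec1$intensity[idx] - f0) / f0, peak_nm = wl[idx])
}

#' Analyte selectivity table
#'
#' Normalizes a set of analyte responses to the dopamine response and ranks
#' them: DA first (reference, normalized 1), then the rest by decreasing
#' normalized response, ties broken alphabetically by analyte name.
#'
#' @param responses Named numeric vector of dF/F0 per analyte; must contain
#'   an entry named `"DA"` with positive response.
#' @return A data.frame with columns `analyte`, `dff`, `normalized`.
#' @export
selectivity_table <- function(responses) {
  stopifnot(is.numeric(responses), !is.null(names(responses)))
  if (!"DA" %in% names(responses)) stop("responses must include a 'DA' entry")
  if (responses[["DA"]] <= 0) stop("DA response must be > 0")
  norm <- responses / responses[["DA"]]
  others <- setdiff(names(responses), "DA")
  others <- others[order(-norm[others], others)]
  ord <- c("DA", others)
  data.frame(analyte = ord, dff = unname(responses[ord]),
             normalized = unname(norm[ord]))
}

#' Nanosensor concentration from absorbance
#'
#' SWCNT mass concentration (mg/L) from the absorbance at 632 nm using the
#' extinction coefficient 0.036 (abs per mg/L per cm).
#'
#' @param a632 Absorbance at 632 nm.
#' @param path_cm Optical path length in cm (default 1).
#' @param extinction Extinction coefficient (default 0.036).
#' @return Concentration in mg/L.
#' @export
swcnt_concentration <- function(a632, path_cm = 1, extinction = 0.036) {
  stopifnot(a632 >= 0, path_cm > 0, extinction > 0)
  a632 / (extinction * path_cm)
}
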
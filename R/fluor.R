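#' Construct an emission spectrum
#'
#' Intrinsic tryptophan emission recorded under 280 nm excitation, on an
#' ascending wavelength grid (nominally 290-450 nm at 10 nm spacing).
#'
#' @param wavelength_nm Ascending wavelengths, nm.
#' @param intensity Non-negative intensities, arbitrary units.
#' @param excitation_nm Excitation wavelength, nm.
#' @param replicate,group Optional metadata labels.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm = 280,
                              replicate = NA, group = NA) {
  if (length(wavelength_nm) != length(intensity))
    stop_invalid("wavelength and intensity must have equal length")
  if (any(diff(wavelength_nm) <= 0))
    stop_invalid("wavelengths must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop_invalid("intensities must be finite and >= 0")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity),
                 excitation_nm = excitation_nm,
                 replicate = replicate, group = group),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat("Emission spectrum: ", length(x$wavelength_nm), " points, ",
      min(x$wavelength_nm), "-", max(x$wavelength_nm), " nm (excitation ",
      x$excitation_nm, " nm)\n", sep = "")
  invisible(x)
}

#' Intensity at (or near) a requested emission wavelength
#'
#' The emission grid is coarser (10 nm) than the 345 nm emission maximum,
#' so the default rule reads the nearest grid point, breaking ties toward
#' the longer wavelength (345 nm on the standard grid reads the 350 nm
#' node). A local-parabola mode interpolates the peak through the three
#' nodes bracketing the request.
#'
#' @param spectrum An `emission_spectrum`.
#' @param wavelength_nm Requested wavelength, nm; must lie within the
#'   recorded range.
#' @param method `"nearest"` (default) or `"parabolic"`.
#' @return Intensity (a.u.).
#' @export
peak_intensity <- function(spectrum, wavelength_nm = 345,
                           method = c("nearest", "parabolic")) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  method <- match.arg(method)
  wl <- spectrum$wavelength_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop_invalid("wavelength ", wavelength_nm, " nm outside the recorded ",
                 "range [", min(wl), ", ", max(wl), "] nm")
  d <- abs(wl - wavelength_nm)
  # ties broken toward the longer wavelength
  i <- max(which(d == min(d)))
  if (method == "nearest") return(spectrum$intensity[i])
  j <- max(2L, min(length(wl) - 1L, i))
  fit <- stats::lm(y ~ x + I(x^2),
                   data = data.frame(x = wl[(j - 1):(j + 1)],
                                     y = spectrum$intensity[(j - 1):(j + 1)]))
  unname(stats::predict(fit, data.frame(x = wavelength_nm)))
}

#' Fit a fluorescence calibration curve
#'
#' Ordinary least squares of peak intensity on known albumin
#' concentration, with a free intercept (the line is not constrained to
#' pass through zero). The linear detection range defaults to the
#' validated 0.125-2 mg/ml band.
#'
#' @param standards A data.frame with columns `conc_mg_ml` and `intensity`.
#' @param range_low,range_high Validated linear range, mg/ml.
#' @return An object of class `fluor_calibration` with components
#'   `slope`, `intercept`, `r_squared`, `range` and the underlying `lm`
#'   fit.
#' @examples
#' std <- data.frame(conc_mg_ml = c(0.125, 0.25, 0.5, 1, 2),
#'                   intensity = 2 * c(0.125, 0.25, 0.5, 1, 2) + 1)
#' fit <- fit_calibration(std)
#' coef(fit)
#' predict(fit, intensity = 5)
#' @export
fit_calibration <- function(standards, range_low = 0.125, range_high = 2) {
  stopifnot(is.data.frame(standards),
            all(c("conc_mg_ml", "intensity") %in% names(standards)))
  if (range_low >= range_high)
    stop_invalid("range_low must be < range_high")
  conc <- standards$conc_mg_ml
  if (length(unique(conc)) < 3L)
    stop_invalid("calibration needs >= 3 distinct concentrations")
  fit <- stats::lm(intensity ~ conc_mg_ml, data = standards)
  sst <- sum((standards$intensity - mean(standards$intensity))^2)
  r2 <- if (sst > 0) 1 - sum(stats::resid(fit)^2) / sst else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 range = c(low = range_low, high = range_high),
                 model = fit, n = nrow(standards)),
            class = "fluor_calibration")
}

#' @export
print.fluor_calibration <- function(x, ...) {
  cat("Fluorescence calibration (345 nm peak intensity vs mg/ml)\n")
  cat(sprintf("  intensity = %.6g * conc + %.6g   (r^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  linear range: %.3g-%.3g mg/ml\n",
              x$range["low"], x$range["high"]))
  invisible(x)
}

#' @export
coef.fluor_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict concentration from measured intensity
#'
#' Inverts the calibration line, `(mean intensity - intercept) / slope`.
#' Triplicate (or any replicate) intensities are averaged first.
#' Predictions outside the validated linear range are flagged as
#' extrapolated rather than rejected.
#'
#' @param object A `fluor_calibration`.
#' @param intensity Measured intensity, or a vector of replicate
#'   intensities to be averaged (one sample).
#' @param ... Unused.
#' @return A data.frame with `concentration_mg_ml` and `extrapolated`.
#' @export
predict.fluor_calibration <- function(object, intensity, ...) {
  if (object$slope <= 0)
    stop_invalid("invalid calibration: slope must be > 0")
  m <- mean(intensity)
  conc <- (m - object$intercept) / object$slope
  data.frame(concentration_mg_ml = conc,
             extrapolated = conc < object$range["low"] |
               conc > object$range["high"],
             row.names = NULL)
}

#' @rdname predict.fluor_calibration
#' @param curve A `fluor_calibration`.
#' @export
predict_concentration <- function(curve, intensity, ...) {
  predict(curve, intensity = intensity, ...)
}

#' Normalize a concentration to a standard
#'
#' @param concentration_mg_ml Concentration(s), mg/ml.
#' @param standard_mg_ml Reference standard concentration (default the
#'   1 mg/ml donor standard).
#' @return Dimensionless ratio(s).
#' @export
normalize_to_standard <- function(concentration_mg_ml, standard_mg_ml = 1) {
  if (!is_number(standard_mg_ml) || standard_mg_ml <= 0)
    stop_invalid("standard_mg_ml must be > 0")
  concentration_mg_ml / standard_mg_ml
}
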
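ftir_stages <- c("raw", "baselined", "smoothed", "averaged",
                 "second_derivative")

#' Construct an infrared spectrum
#'
#' Absorbance against a strictly increasing wavenumber grid (nominally
#' 400-4000 cm^-1 at 2 cm^-1 spacing). Every spectrum carries a processing
#' `stage`; pipeline functions enforce the processing order baseline ->
#' smooth -> average -> second derivative -> integrate and fail loudly on
#' out-of-order calls.
#'
#' @param wavenumber_cm1 Ascending wavenumbers, cm^-1.
#' @param absorbance Absorbance values, a.u.
#' @param stage Processing stage label.
#' @param group,replicate Optional metadata labels.
#' @param n_averaged Number of replicates behind an averaged spectrum.
#' @return An object of class `ir_spectrum`.
#' @export
ir_spectrum <- function(wavenumber_cm1, absorbance, stage = "raw",
                        group = NA, replicate = NA, n_averaged = 1L) {
  if (length(wavenumber_cm1) != length(absorbance))
    stop_invalid("wavenumber and absorbance must have equal length")
  if (any(diff(wavenumber_cm1) <= 0))
    stop_invalid("wavenumbers must be strictly increasing")
  if (any(!is.finite(absorbance)))
    stop_invalid("absorbance must be finite")
  stage <- match.arg(stage, ftir_stages)
  structure(list(wavenumber_cm1 = as.numeric(wavenumber_cm1),
                 absorbance = as.numeric(absorbance), stage = stage,
                 group = group, replicate = replicate,
                 n_averaged = n_averaged),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat("IR spectrum [", x$stage, "]: ", length(x$wavenumber_cm1),
      " points, ", min(x$wavenumber_cm1), "-", max(x$wavenumber_cm1),
      " cm^-1", sep = "")
  if (!is.na(x$group)) cat(", group ", x$group, sep = "")
  if (x$n_averaged > 1L) cat(", mean of n =", x$n_averaged)
  cat("\n")
  invisible(x)
}

#' @export
plot.ir_spectrum <- function(x, ...) {
  plot(x$wavenumber_cm1, x$absorbance, type = "l",
       xlim = rev(range(x$wavenumber_cm1)),
       xlab = expression(Wavenumber ~ (cm^-1)),
       ylab = if (x$stage == "second_derivative")
         "d2A/dv2 (a.u.)" else "Absorbance (a.u.)", ...)
  invisible(x)
}

require_stage <- function(spectrum, allowed, op) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (!spectrum$stage %in% allowed)
    stop_invalid(op, " expects a spectrum at stage ",
                 paste(allowed, collapse = " or "), ", got '",
                 spectrum$stage, "' (pipeline order is baseline -> ",
                 "smooth -> average -> second derivative)")
  invisible(spectrum)
}

#' Anchor-point baseline correction
#'
#' Subtracts a baseline passing through the spectrum's values at a set of
#' anchor wavenumbers (regions free of bands): piecewise-linear
#' interpolation between anchors by default, or a polynomial fitted
#' through them. Outside the outermost anchors the baseline is extended
#' flat (linear method).
#'
#' @param spectrum A raw `ir_spectrum`.
#' @param anchors_cm1 Anchor wavenumbers; each must lie within the
#'   spectral range. Anchor ordinates come from a local linear fit within
#'   `anchor_halfwidth_cm1` of each anchor, exact for flat and sloping
#'   baselines including at the spectrum edges.
#' @param method `"linear"` (default) or `"polynomial"`.
#' @param degree Polynomial degree for `method = "polynomial"`.
#' @param anchor_halfwidth_cm1 Half-width of the window used to read each
#'   anchor ordinate.
#' @return The baseline-corrected `ir_spectrum` (stage `"baselined"`).
#' @export
baseline_correct <- function(spectrum,
                             anchors_cm1 = c(400, 780, 1140, 1480, 1775,
                                             2000, 2350, 2700, 3960),
                             method = c("linear", "polynomial"),
                             degree = 3,
                             anchor_halfwidth_cm1 = 8) {
  require_stage(spectrum, "raw", "baseline_correct")
  method <- match.arg(method)
  wn <- spectrum$wavenumber_cm1
  if (any(anchors_cm1 < min(wn)) || any(anchors_cm1 > max(wn)))
    stop_invalid("baseline anchors outside the spectral range")
  anchors_cm1 <- sort(anchors_cm1)
  ay <- vapply(anchors_cm1, function(a) {
    sel <- abs(wn - a) <= anchor_halfwidth_cm1
    if (sum(sel) < 2L) return(spectrum$absorbance[which.min(abs(wn - a))])
    fit <- stats::lm.fit(cbind(1, wn[sel] - a),
                         spectrum$absorbance[sel])
    unname(fit$coefficients[1L])
  }, numeric(1))
  base <- if (method == "linear") {
    stats::approx(anchors_cm1, ay, xout = wn, rule = 2)$y
  } else {
    fit <- stats::lm(y ~ poly(x, degree, raw = TRUE),
                     data = data.frame(x = anchors_cm1, y = ay))
    unname(stats::predict(fit, data.frame(x = wn)))
  }
  out <- spectrum
  out$absorbance <- spectrum$absorbance - base
  out$stage <- "baselined"
  out
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing with the standard 9-point window
#' (order 2 by default, the common spectroscopy choice); edge points are
#' handled by polynomial fits on the truncated windows. Polynomials up to
#' the filter order are reproduced exactly.
#'
#' @param spectrum An `ir_spectrum` at stage `"baselined"` (or `"raw"` if
#'   no baseline correction is wanted).
#' @param window Odd window length in points (default 9).
#' @param order Polynomial order (< window).
#' @return The smoothed `ir_spectrum` (stage `"smoothed"`).
#' @export
savgol_smooth <- function(spectrum, window = 9, order = 2) {
  require_stage(spectrum, c("raw", "baselined"), "savgol_smooth")
  check_sg_args(spectrum, window, order)
  out <- spectrum
  out$absorbance <- as.numeric(
    signal::sgolayfilt(spectrum$absorbance, p = order, n = window, m = 0))
  out$stage <- "smoothed"
  out
}

check_sg_args <- function(spectrum, window, order) {
  if (window %% 2 != 1 || window < 3)
    stop_invalid("window must be odd and >= 3")
  if (order >= window) stop_invalid("order must be < window")
  if (length(spectrum$absorbance) < window)
    stop_invalid("spectrum shorter than the filter window")
  invisible(TRUE)
}

#' Average replicate spectra on a common grid
#'
#' Pointwise mean of n replicate spectra; grids must be identical (no
#' silent interpolation).
#'
#' @param spectra A list of `ir_spectrum` objects at stage `"smoothed"`.
#' @return The mean `ir_spectrum` (stage `"averaged"`, `n_averaged` set).
#' @export
average_group <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L)
  lapply(spectra, require_stage, allowed = "smoothed",
         op = "average_group")
  wn <- spectra[[1L]]$wavenumber_cm1
  for (s in spectra[-1L]) {
    if (length(s$wavenumber_cm1) != length(wn) ||
        any(s$wavenumber_cm1 != wn))
      stop_invalid("alignment error: replicate wavenumber grids differ; ",
                   "resample explicitly before averaging")
  }
  out <- spectra[[1L]]
  out$absorbance <- rowMeans(vapply(spectra, `[[`, numeric(length(wn)),
                                    "absorbance"))
  out$stage <- "averaged"
  out$replicate <- NA
  out$n_averaged <- length(spectra)
  out
}

#' Second-derivative transformation
#'
#' Savitzky-Golay second derivative with respect to wavenumber (same
#' window/order family as the smoothing step). Absorption maxima appear
#' as negative second-derivative peaks.
#'
#' @param spectrum An `ir_spectrum` at stage `"smoothed"` or `"averaged"`.
#' @param window,order Savitzky-Golay parameters (order must be >= 2).
#' @return The derivative `ir_spectrum` (stage `"second_derivative"`).
#' @export
second_derivative <- function(spectrum, window = 9, order = 2) {
  require_stage(spectrum, c("smoothed", "averaged"), "second_derivative")
  check_sg_args(spectrum, window, order)
  if (order < 2) stop_invalid("order must be >= 2 for a second derivative")
  dx <- diff(spectrum$wavenumber_cm1)
  if (max(abs(dx - dx[1L])) > 1e-8 * dx[1L])
    stop_invalid("second derivative requires an equally spaced grid")
  out <- spectrum
  out$absorbance <- as.numeric(
    signal::sgolayfilt(spectrum$absorbance, p = order, n = window, m = 2,
                       ts = dx[1L]))
  out$stage <- "second_derivative"
  out
}

#' Integrate a band region
#'
#' Trapezoidal integral over `[lo, hi]`: of the absolute second
#' derivative for a derivative-stage spectrum (the default reporting
#' mode), or of the absorbance itself for earlier stages.
#'
#' @param spectrum An `ir_spectrum`.
#' @param lo_cm1,hi_cm1 Integration limits, cm^-1, inside the spectral
#'   range.
#' @param mode `"second_derivative"` (integrates |d2A/dv2|; requires a
#'   derivative-stage spectrum) or `"absorbance"`.
#' @return Band area (a.u. cm^-1).
#' @export
integrate_band <- function(spectrum, lo_cm1, hi_cm1,
                           mode = c("second_derivative", "absorbance")) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  mode <- match.arg(mode)
  wn <- spectrum$wavenumber_cm1
  if (lo_cm1 >= hi_cm1) stop_invalid("band limits need lo < hi")
  if (lo_cm1 < min(wn) || hi_cm1 > max(wn))
    stop_invalid("band [", lo_cm1, ", ", hi_cm1,
                 "] outside the spectral range")
  if (mode == "second_derivative")
    require_stage(spectrum, "second_derivative", "integrate_band")
  sel <- wn >= lo_cm1 & wn <= hi_cm1
  if (sum(sel) < 2L) stop_invalid("band narrower than the grid spacing")
  y <- spectrum$absorbance[sel]
  if (mode == "second_derivative") y <- abs(y)
  trapz_integral(wn[sel], y)
}

#' Default band definition table
#'
#' The integration limits used throughout: the hydroxyl envelope split
#' into stretching/symmetric/asymmetric components, the unsaturated =CH
#' and CH2-rocking lipid bands, the water combination band near 2129
#' cm^-1, the thiol window, the strained carbonyl pair, and the amide
#' I/II/III regions. Limits are data, not code: the table ships as
#' `extdata/ftir_bands.csv` and any data.frame with the same columns can
#' be passed wherever a band table is accepted.
#'
#' @return A data.frame with columns `name`, `lo_cm1`, `hi_cm1`,
#'   `reference_set` (logical: membership of the reference denominator).
#' @export
default_bands <- function() {
  path <- system.file("extdata", "ftir_bands.csv", package = "corion",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Integrated band areas as percentages of a reference area
#'
#' Integrates every band in `bands` on the |second derivative| and
#' expresses each as a percentage of either the full-spectrum integrated
#' area (default: the "total integrated area" denominator) or of the sum
#' over the bands flagged `reference_set`.
#'
#' @param spectrum A `second_derivative`-stage `ir_spectrum`.
#' @param bands A band table (see [default_bands()]).
#' @param denominator `"full_spectrum"` or `"reference_set"`.
#' @return An object of class `band_area_report`: data.frame with `name`,
#'   `lo_cm1`, `hi_cm1`, `area`, `area_pct`.
#' @export
area_percentages <- function(spectrum, bands = default_bands(),
                             denominator = c("full_spectrum",
                                             "reference_set")) {
  require_stage(spectrum, "second_derivative", "area_percentages")
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(bands),
            all(c("name", "lo_cm1", "hi_cm1") %in% names(bands)))
  areas <- vapply(seq_len(nrow(bands)), function(i)
    integrate_band(spectrum, bands$lo_cm1[i], bands$hi_cm1[i]), numeric(1))
  ref_total <- if (denominator == "full_spectrum") {
    trapz_integral(spectrum$wavenumber_cm1, abs(spectrum$absorbance))
  } else {
    if (is.null(bands$reference_set) || !any(bands$reference_set))
      stop_invalid("no bands flagged as the reference set")
    sum(areas[as.logical(bands$reference_set)])
  }
  if (ref_total <= 0)
    stop_invalid("degenerate input: zero reference area")
  out <- data.frame(name = bands$name, lo_cm1 = bands$lo_cm1,
                    hi_cm1 = bands$hi_cm1, area = areas,
                    area_pct = 100 * areas / ref_total)
  structure(out, class = c("band_area_report", "data.frame"),
            denominator = denominator, group = spectrum$group,
            n_averaged = spectrum$n_averaged)
}

#' @export
print.band_area_report <- function(x, ...) {
  cat("Band-area report (denominator: ", attr(x, "denominator"), ")\n",
      sep = "")
  y <- x
  y$area <- signif(y$area, 4)
  y$area_pct <- round(y$area_pct, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Position of the dominant amide-I component
#'
#' Wavenumber of the most negative second-derivative point within the
#' amide-I region (absorption maxima are negative second-derivative
#' peaks).
#'
#' @param spectrum A `second_derivative`-stage `ir_spectrum`.
#' @param region Region limits, cm^-1 (default 1600-1700).
#' @return Wavenumber, cm^-1.
#' @export
amide_peak_position <- function(spectrum, region = c(1600, 1700)) {
  require_stage(spectrum, "second_derivative", "amide_peak_position")
  wn <- spectrum$wavenumber_cm1
  if (region[1L] < min(wn) || region[2L] > max(wn))
    stop_invalid("amide region outside the spectral range")
  sel <- which(wn >= region[1L] & wn <= region[2L])
  y <- spectrum$absorbance[sel]
  if (max(y) - min(y) < 1e-12 * max(1, abs(max(y))))
    stop_invalid("degenerate input: region is flat, no amide component")
  wn[sel[which.min(y)]]
}

#' Assign a protein secondary-structure motif to an amide-I position
#'
#' Bands above 1660 cm^-1 are read as beta-turns, 1650-1660 cm^-1 as
#' alpha-helix, and lower frequencies as beta-sheet/random-coil. The
#' boundary convention is closed on the helix side: exactly 1660 is
#' helix, exactly 1650 is helix.
#'
#' @param position_cm1 Amide-I component position(s), cm^-1, within
#'   1600-1700.
#' @return Character vector of motif labels.
#' @examples
#' assign_secondary_structure(c(1666, 1659, 1674))
#' @export
assign_secondary_structure <- function(position_cm1) {
  if (any(!is.finite(position_cm1)) ||
      any(position_cm1 < 1600 | position_cm1 > 1700))
    stop_invalid("amide-I positions must lie within [1600, 1700] cm^-1")
  ifelse(position_cm1 > 1660, "beta_turn",
         ifelse(position_cm1 >= 1650, "alpha_helix",
                "beta_sheet_random_coil"))
}

#' Water combination-band arithmetic
#'
#' The combination wavenumber is the sum of the bending and stretching
#' fundamentals, `v_comb = v_bend + v_stretch`. Note that the published
#' components (1640 + 3400 cm^-1) sum to 5040 cm^-1, which does not equal
#' the observed 2129 cm^-1 band; the formula is applied as stated and the
#' discrepancy is left to the caller.
#'
#' @param bend_cm1,stretch_cm1 Fundamental wavenumbers, cm^-1 (>= 0).
#' @return Combination wavenumber, cm^-1.
#' @export
water_combination_check <- function(bend_cm1, stretch_cm1) {
  if (any(bend_cm1 < 0) || any(stretch_cm1 < 0))
    stop_invalid("wavenumbers must be >= 0")
  bend_cm1 + stretch_cm1
}
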
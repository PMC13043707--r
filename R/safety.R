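#' Thermal-safety thresholds
#'
#' The ocular baseline band (32-36 degC), the caution threshold marking
#' the onset of reversible cellular stress (41 degC) and the damage
#' threshold for irreversible thermal injury (43 degC).
#'
#' @param ocular_low,ocular_high Ocular baseline band, degC.
#' @param caution Caution threshold, degC.
#' @param damage Damage threshold, degC.
#' @return An object of class `safety_thresholds`.
#' @export
safety_thresholds <- function(ocular_low = 32, ocular_high = 36,
                              caution = 41, damage = 43) {
  vals <- c(ocular_low = ocular_low, ocular_high = ocular_high,
            caution = caution, damage = damage)
  if (!all(vapply(vals, is_number, logical(1))))
    stop_invalid("thresholds must be single finite numbers")
  if (!(ocular_low < ocular_high && ocular_high < caution &&
        caution < damage))
    stop_invalid("thresholds must satisfy ocular_low < ocular_high ",
                 "< caution < damage")
  structure(as.list(vals), class = "safety_thresholds")
}

safety_zone_levels <- c("thermoneutral", "physiological", "caution", "damage")

#' Classify a temperature into a safety zone
#'
#' Zones are right-closed upward: `T <= ocular_high` is thermoneutral,
#' `ocular_high < T < caution` physiological, `caution <= T < damage`
#' caution, and `T >= damage` damage (a temperature exactly at a threshold
#' enters the stricter zone).
#'
#' @param T Temperature(s), degC.
#' @param thresholds A `safety_thresholds`.
#' @return An ordered factor with levels thermoneutral < physiological <
#'   caution < damage.
#' @examples
#' classify_temperature(c(34, 37.5, 43))
#' @export
classify_temperature <- function(T, thresholds = safety_thresholds()) {
  stopifnot(inherits(thresholds, "safety_thresholds"))
  if (!is.numeric(T) || any(!is.finite(T)))
    stop_invalid("temperatures must be finite numbers")
  cut(T, breaks = c(-Inf, thresholds$ocular_high, thresholds$caution,
                    thresholds$damage, Inf),
      labels = safety_zone_levels, right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE) ->
    z
  # cut() with right = FALSE puts T == ocular_high into the next band;
  # the documented convention keeps the baseline band closed above.
  z[T <= thresholds$ocular_high] <- safety_zone_levels[1L]
  z
}

#' Classify a solved temperature field
#'
#' Labels every (report time, layer) maximum and the surface maximum with
#' its safety zone.
#'
#' @param field A `bioheat_field`.
#' @param thresholds A `safety_thresholds`.
#' @return An object of class `safety_report`: a data.frame with columns
#'   `time_s`, `layer`, `max_C`, `zone` (the surface appears as layer
#'   `"surface"`).
#' @export
classify_field <- function(field, thresholds = safety_thresholds()) {
  stopifnot(inherits(field, "bioheat_field"))
  if (length(field$times_s) == 0L)
    stop_invalid("field holds no report times")
  rows <- lapply(field$times_s, function(t) {
    lm <- layer_max_temperatures(field, t)
    data.frame(time_s = t,
               layer = c("surface", names(lm)),
               max_C = c(surface_temperature(field, t), unname(lm)))
  })
  out <- do.call(rbind, rows)
  out$zone <- classify_temperature(out$max_C, thresholds)
  structure(out, class = c("safety_report", "data.frame"),
            current_mA = field$protocol$current_mA)
}

#' @export
print.safety_report <- function(x, ...) {
  cat("Thermal-safety report (", attr(x, "current_mA"), " mA)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Largest current whose surface stays below a requested zone
#'
#' Summarizes a sweep of solved fields into the safe operational window:
#' for each report time, the largest current whose surface classification
#' is strictly below `zone`.
#'
#' @param fields A list of `bioheat_field` objects (one per current).
#' @param zone The first disallowed zone (default `"physiological"`, i.e.
#'   the window of thermoneutral currents).
#' @param thresholds A `safety_thresholds`.
#' @return A data.frame with columns `time_s`, `max_safe_current_mA`
#'   (NA when no simulated current qualifies).
#' @export
safe_current_window <- function(fields, zone = "physiological",
                                thresholds = safety_thresholds()) {
  stopifnot(length(fields) >= 1L,
            all(vapply(fields, inherits, logical(1), "bioheat_field")))
  zone <- match.arg(zone, safety_zone_levels[-1L])
  times <- fields[[1L]]$times_s
  currents <- vapply(fields, function(f) f$protocol$current_mA, numeric(1))
  limit <- factor(zone, levels = safety_zone_levels, ordered = TRUE)
  out <- lapply(times, function(t) {
    ok <- vapply(fields, function(f)
      classify_temperature(surface_temperature(f, t), thresholds) < limit,
      logical(1))
    data.frame(time_s = t,
               max_safe_current_mA = if (any(ok)) max(currents[ok]) else NA_real_)
  })
  do.call(rbind, out)
}
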
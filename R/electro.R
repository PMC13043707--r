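#' Construct a layered corneal stack
#'
#' A `cornea_stack` holds the anterior-to-posterior sequence of corneal
#' layers (geometry, electrical conductivity, thermal constants) together
#' with the cross-sectional area exposed to current. Layers must tile the
#' depth axis contiguously starting at 0.
#'
#' @param layers A data.frame with one row per layer and columns
#'   `name`, `thickness_um`, `sigma_S_per_m`, `k_W_mK`, `rho_kg_m3`,
#'   `c_J_kgK`, and optionally `w_b_per_s`, `q_met_W_m3` (default 0).
#' @param area_cm2 Cross-sectional area in cm^2.
#' @return An object of class `cornea_stack`: the layer data.frame with
#'   added `position_start_um`/`position_end_um` columns and an `area_cm2`
#'   attribute.
#' @examples
#' stk <- default_cornea()
#' total_stack_resistance(stk)
#' @export
cornea_stack <- function(layers, area_cm2) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1L)
  needed <- c("name", "thickness_um", "sigma_S_per_m", "k_W_mK",
              "rho_kg_m3", "c_J_kgK")
  missing_cols <- setdiff(needed, names(layers))
  if (length(missing_cols) > 0L)
    stop_invalid("layers is missing columns: ",
                 paste(missing_cols, collapse = ", "))
  if (!is_number(area_cm2) || area_cm2 <= 0)
    stop_invalid("invalid geometry: area_cm2 must be a positive number")
  if (is.null(layers$w_b_per_s)) layers$w_b_per_s <- 0
  if (is.null(layers$q_met_W_m3)) layers$q_met_W_m3 <- 0

  with(layers, {
    if (any(thickness_um <= 0))
      stop_invalid("invalid geometry: all layer thicknesses must be > 0")
    if (any(sigma_S_per_m <= 0))
      stop_invalid("all electrical conductivities must be > 0")
    if (any(k_W_mK <= 0) || any(rho_kg_m3 <= 0) || any(c_J_kgK <= 0))
      stop_invalid("thermal constants k, rho, c must be > 0")
    if (any(w_b_per_s < 0) || any(q_met_W_m3 < 0))
      stop_invalid("perfusion rate and metabolic heat must be >= 0")
  })
  ends <- cumsum(layers$thickness_um)
  layers$position_start_um <- c(0, ends[-length(ends)])
  layers$position_end_um <- ends
  structure(layers, class = c("cornea_stack", "data.frame"),
            area_cm2 = area_cm2)
}

#' @export
print.cornea_stack <- function(x, ...) {
  cat("Corneal layer stack (", nrow(x), " layers, total ",
      sum(x$thickness_um), " um, area ",
      format(attr(x, "area_cm2"), digits = 6), " cm^2)\n", sep = "")
  print.data.frame(x[, c("name", "thickness_um", "position_start_um",
                         "position_end_um", "sigma_S_per_m", "k_W_mK")],
                   row.names = FALSE)
  invisible(x)
}

#' Cross-sectional area of a stack (cm^2)
#' @param stack A `cornea_stack`.
#' @return Area in cm^2.
#' @export
stack_area <- function(stack) {
  stopifnot(inherits(stack, "cornea_stack"))
  attr(stack, "area_cm2")
}

#' The default four-layer cornea
#'
#' Tear film 0-12 um (sigma 1.5 S/m), epithelium 12-62 um (0.0004 S/m),
#' stroma 62-492 um (0.25 S/m), endothelium 492-512 um (0.0066 S/m), with
#' the shipped calibrated thermal constants. The default area is
#' pi * (0.6 cm)^2 = 1.13097 cm^2, the disc area consistent with the
#' printed current densities (see [back_derived_area()] for the exact
#' printed-precision fit).
#'
#' @param area_cm2 Cross-sectional area in cm^2.
#' @return A `cornea_stack`.
#' @export
default_cornea <- function(area_cm2 = pi * 0.6^2) {
  cfg <- default_config()
  cornea_stack(cfg$layers, area_cm2 = area_cm2)
}

#' Construct a current protocol
#'
#' @param current_mA Applied constant current in mA (>= 0).
#' @param duration_s Exposure time in s (> 0).
#' @param report_times_s Times (s) at which depth profiles are reported;
#'   must lie in `[0, duration_s]`.
#' @return An object of class `current_protocol`.
#' @examples
#' current_protocol(0.5)
#' @export
current_protocol <- function(current_mA, duration_s = 60,
                             report_times_s = c(10, 30, 60)) {
  if (!is_number(current_mA) || current_mA < 0)
    stop_invalid("current_mA must be a single number >= 0")
  if (!is_number(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be > 0")
  report_times_s <- sort(unique(as.numeric(report_times_s)))
  if (any(report_times_s < 0) || any(report_times_s > duration_s))
    stop_invalid("report_times_s must lie within [0, duration_s]")
  structure(list(current_mA = current_mA, duration_s = duration_s,
                 report_times_s = report_times_s),
            class = "current_protocol")
}

#' @export
print.current_protocol <- function(x, ...) {
  cat("Iontophoresis protocol: ", x$current_mA, " mA for ", x$duration_s,
      " s (profiles at ", paste(x$report_times_s, collapse = ", "),
      " s)\n", sep = "")
  invisible(x)
}

#' Current density through the stack
#'
#' J = I / A. In a series stack the same density crosses every layer.
#'
#' @param protocol A `current_protocol`.
#' @param stack A `cornea_stack`.
#' @return Current density in mA/cm^2.
#' @examples
#' current_density(current_protocol(0.5), default_cornea(1.1310))
#' @export
current_density <- function(protocol, stack) {
  stopifnot(inherits(protocol, "current_protocol"))
  A <- stack_area(stack)
  if (!is_number(A) || A <= 0)
    stop_invalid("invalid geometry: stack area must be > 0")
  protocol$current_mA / A
}

#' Per-layer electrical resistance
#'
#' R = L / (sigma * A) per layer, computed in SI (L in m, sigma in S/m,
#' A in m^2).
#'
#' @param stack A `cornea_stack`.
#' @param layer Optional layer name or index; default all layers.
#' @return Named numeric vector of resistances in Ohm.
#' @export
layer_resistance <- function(stack, layer = NULL) {
  stopifnot(inherits(stack, "cornea_stack"))
  A_m2 <- stack_area(stack) * 1e-4
  if (A_m2 <= 0) stop_invalid("invalid geometry: stack area must be > 0")
  if (any(stack$sigma_S_per_m <= 0))
    stop_invalid("division domain error: zero electrical conductivity")
  R <- (stack$thickness_um * 1e-6) / (stack$sigma_S_per_m * A_m2)
  names(R) <- stack$name
  if (!is.null(layer)) R <- R[layer]
  R
}

#' Total series resistance of the stack
#'
#' @param stack A `cornea_stack`.
#' @return Resistance in Ohm (sum over layers; dominated by the epithelium
#'   for the default stack).
#' @export
total_stack_resistance <- function(stack) {
  stopifnot(inherits(stack, "cornea_stack"))
  if (nrow(stack) == 0L) stop_invalid("invalid geometry: empty stack")
  sum(layer_resistance(stack))
}

#' Ohmic voltage drop across each layer
#'
#' deltaV = I * R_layer with I in A. The drops sum to I times the total
#' stack resistance.
#'
#' @param stack A `cornea_stack`.
#' @param protocol A `current_protocol`.
#' @return Named numeric vector of voltage drops in V.
#' @export
voltage_drop <- function(stack, protocol) {
  stopifnot(inherits(protocol, "current_protocol"))
  (protocol$current_mA * 1e-3) * layer_resistance(stack)
}

#' Joule volumetric heat source per layer
#'
#' Q = scale * J^2 / sigma with J in A/m^2, the standard resistive
#' dissipation density, optionally rescaled by a dimensionless calibration
#' factor (the shipped thermal config carries the calibrated value; scale
#' 1 gives the raw physical source). Constant in time and piecewise
#' constant in depth for a constant-current protocol.
#'
#' @param stack A `cornea_stack`.
#' @param protocol A `current_protocol`.
#' @param scale Dimensionless source scaling factor (>= 0).
#' @return Named numeric vector, W/m^3 per layer.
#' @export
joule_source <- function(stack, protocol, scale = 1) {
  stopifnot(inherits(stack, "cornea_stack"),
            inherits(protocol, "current_protocol"))
  if (!is_number(scale) || scale < 0)
    stop_invalid("scale must be a single number >= 0")
  if (any(stack$sigma_S_per_m <= 0))
    stop_invalid("division domain error: zero electrical conductivity")
  J_A_m2 <- current_density(protocol, stack) * 10  # mA/cm^2 -> A/m^2
  Q <- scale * J_A_m2^2 / stack$sigma_S_per_m
  names(Q) <- stack$name
  Q
}

#' The printed current/current-density table
#'
#' The nine applied currents (mA) and the corresponding printed current
#' densities (mA/cm^2) reported for the ex vivo protocol; used as the input
#' for back-deriving the effective corneal area.
#'
#' @return A data.frame with columns `current_mA`, `density_mA_cm2`, and
#'   `printed_decimals` (the precision each density was reported at).
#' @export
printed_current_densities <- function() {
  data.frame(
    current_mA = c(0.5, 1, 2, 3, 4, 5, 6, 7, 500),
    density_mA_cm2 = c(0.442, 0.884, 1.768, 2.653, 3.537,
                       4.421, 5.305, 6.190, 442.1),
    printed_decimals = c(3, 3, 3, 3, 3, 3, 3, 3, 1)
  )
}

#' Back-derive the corneal cross-sectional area from printed densities
#'
#' The area is not reported directly; the stated 0.6 value is consistent
#' with a disc radius of 0.6 cm, not 0.6 mm. This function inverts the
#' printed (I, J) table: for each pair it computes the interval of areas A
#' for which round(I/A) reproduces J at its printed precision, intersects
#' the intervals, and returns the midpoint. An error is raised if the
#' intervals are inconsistent.
#'
#' @param table A data.frame as returned by [printed_current_densities()].
#' @return Area in cm^2 (scalar, attribute `interval_cm2` giving the full
#'   consistent interval).
#' @examples
#' A <- back_derived_area()
#' round(7 / A, 3)  # reproduces the printed 6.190
#' @export
back_derived_area <- function(table = printed_current_densities()) {
  stopifnot(all(c("current_mA", "density_mA_cm2") %in% names(table)))
  dec <- if (is.null(table$printed_decimals)) rep(3, nrow(table)) else
    table$printed_decimals
  half <- 0.5 * 10^(-dec)
  lo <- table$current_mA / (table$density_mA_cm2 + half)
  hi <- table$current_mA / (table$density_mA_cm2 - half)
  interval <- c(max(lo), min(hi))
  if (interval[1] >= interval[2])
    stop_invalid("printed densities are mutually inconsistent: ",
                 "no single area reproduces all of them")
  structure(mean(interval), interval_cm2 = interval)
}
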
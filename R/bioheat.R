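#' Thermal boundary conditions for the corneal stack
#'
#' Anterior (tear-film/air) face: Robin convective exchange
#' `-k dT/dx = h_conv (T - T_ambient) + e_evap`, i.e. convection toward the
#' ambient temperature plus a constant evaporative heat flux. Posterior
#' (endothelium/chamber) face: Robin exchange `-k dT/dx = h_post (T - T_body)`
#' representing perfusion-like coupling to the posterior bath. In the
#' shipped ex vivo configuration the posterior bath sits at the corneal
#' baseline temperature; set `T_body = 37` for an in vivo boundary.
#'
#' @param h_conv Anterior convection coefficient, W/(m^2 K), >= 0.
#' @param e_evap Anterior evaporative heat flux, W/m^2, >= 0.
#' @param T_ambient Ambient temperature at the anterior face, degC.
#' @param T_body Posterior bath / body temperature, degC.
#' @param h_post Posterior exchange coefficient, W/(m^2 K), >= 0.
#' @param rho_b_c_b Volumetric heat capacity of the perfusing fluid for the
#'   Pennes perfusion term, J/(m^3 K).
#' @return An object of class `thermal_boundary`.
#' @export
thermal_boundary <- function(h_conv, e_evap = 0, T_ambient, T_body,
                             h_post, rho_b_c_b = 3.8e6) {
  vals <- list(h_conv = h_conv, e_evap = e_evap, T_ambient = T_ambient,
               T_body = T_body, h_post = h_post, rho_b_c_b = rho_b_c_b)
  if (!all(vapply(vals, is_number, logical(1))))
    stop_invalid("all boundary parameters must be single finite numbers")
  if (h_conv < 0 || h_post < 0 || e_evap < 0 || rho_b_c_b <= 0)
    stop_invalid("h_conv, h_post, e_evap must be >= 0 and rho_b_c_b > 0")
  structure(vals, class = "thermal_boundary")
}

#' Solver control parameters
#'
#' @param dt Time step, s (> 0). Default 0.1 s, giving 600 steps over the
#'   default 60 s protocol.
#' @param dx_um Spatial step, um (> 0); must divide every layer interface
#'   position so interfaces fall on nodes.
#' @param theta Implicitness weight in `[0.5, 1]`: 1 = backward Euler
#'   (default), 0.5 = Crank-Nicolson. The micrometre-scale grid makes an
#'   explicit scheme unstable at dt = 0.1 s, so theta < 0.5 is refused.
#' @param T_baseline Initial (uniform) corneal temperature, degC; the
#'   physiological corneal baseline lies between 32 and 36 degC.
#' @param source_scale Dimensionless multiplier on the Joule volumetric
#'   source; 1 is the raw physical J^2/sigma, the shipped calibrated config
#'   carries the fitted value.
#' @return An object of class `solver_control`.
#' @export
solver_control <- function(dt = 0.1, dx_um = 2, theta = 1,
                           T_baseline = 34, source_scale = 1) {
  if (!is_number(dt) || dt <= 0) stop_invalid("dt must be > 0")
  if (!is_number(dx_um) || dx_um <= 0) stop_invalid("dx_um must be > 0")
  if (!is_number(theta) || theta < 0.5 || theta > 1)
    stop_invalid("theta must lie in [0.5, 1] (implicit scheme required)")
  if (!is_number(T_baseline))
    stop_invalid("T_baseline must be a single finite number")
  if (!is_number(source_scale) || source_scale < 0)
    stop_invalid("source_scale must be >= 0")
  structure(list(dt = dt, dx_um = dx_um, theta = theta,
                 T_baseline = T_baseline, source_scale = source_scale),
            class = "solver_control")
}

#' Discretize a corneal stack onto a finite-volume grid
#'
#' Nodes are spaced `dx_um` apart from the anterior surface to the
#' posterior face, with half-width control volumes at the two boundary
#' nodes. Material interfaces must coincide with nodes; a node lying
#' exactly on an interface is assigned to the posterior (starting) layer.
#' Face conductivities use the harmonic mean of the adjacent node values,
#' which conserves flux across material discontinuities.
#'
#' @param stack A `cornea_stack`.
#' @param control A `solver_control`.
#' @return A list with node positions (`x_um`), per-node layer labels and
#'   material properties, face conductivities and cell volumes (per unit
#'   area, m).
#' @export
build_grid <- function(stack, control = solver_control()) {
  stopifnot(inherits(stack, "cornea_stack"),
            inherits(control, "solver_control"))
  dx <- control$dx_um
  if (dx > min(stack$thickness_um))
    stop_invalid("dx_um = ", dx, " um exceeds the thinnest layer (",
                 min(stack$thickness_um), " um); choose dx_um <= ",
                 min(stack$thickness_um) / 3,
                 " so every layer holds at least 3 nodes")
  ends <- stack$position_end_um
  if (any(abs(ends / dx - round(ends / dx)) > 1e-9))
    stop_invalid("dx_um must divide every interface position (",
                 paste(ends, collapse = ", "), " um)")
  if (any(stack$thickness_um / dx + 1 < 3))
    stop_invalid("every layer must contain at least 3 nodes; reduce dx_um")
  total <- ends[length(ends)]
  x_um <- seq(0, total, by = dx)
  n <- length(x_um)
  idx <- findInterval(x_um, stack$position_start_um)
  list(
    x_um = x_um,
    n = n,
    dx_m = dx * 1e-6,
    layer = stack$name[idx],
    layer_index = idx,
    k = stack$k_W_mK[idx],
    rho = stack$rho_kg_m3[idx],
    c = stack$c_J_kgK[idx],
    sigma = stack$sigma_S_per_m[idx],
    w_b = stack$w_b_per_s[idx],
    q_met = stack$q_met_W_m3[idx],
    k_face = {
      ki <- stack$k_W_mK[idx]
      2 * ki[-n] * ki[-1] / (ki[-n] + ki[-1])
    },
    volume_m = c(dx * 1e-6 / 2, rep(dx * 1e-6, n - 2L), dx * 1e-6 / 2)
  )
}

# Solve tridiagonal system (Thomas algorithm). lower/upper have length n-1.
thomas_solve <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  denom <- diag[1L]
  if (abs(denom) < .Machine$double.xmin)
    stop_invalid("numerical failure: singular tridiagonal system (node 1)")
  cp[1L] <- upper[1L] / denom
  dp[1L] <- rhs[1L] / denom
  for (i in 2:n) {
    denom <- diag[i] - lower[i - 1L] * cp[i - 1L]
    if (abs(denom) < .Machine$double.xmin)
      stop_invalid("numerical failure: singular tridiagonal system (node ",
                   i, ")")
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# Assemble the constant-coefficient operator: cap dT/dt = -(A T) + b
# A is tridiagonal (lower, diag, upper); all quantities per unit area.
assemble_system <- function(grid, boundary, source_W_m3) {
  n <- grid$n
  g <- grid$k_face / grid$dx_m            # W/(m^2 K) internode conductance
  perf <- grid$w_b * boundary$rho_b_c_b * grid$volume_m
  dg <- c(g, 0) + c(0, g) + perf
  dg[1L] <- dg[1L] + boundary$h_conv
  dg[n] <- dg[n] + boundary$h_post
  b <- source_W_m3 * grid$volume_m + grid$q_met * grid$volume_m +
    perf * boundary$T_body
  b[1L] <- b[1L] + boundary$h_conv * boundary$T_ambient - boundary$e_evap
  b[n] <- b[n] + boundary$h_post * boundary$T_body
  list(lower = -g, diag = dg, upper = -g, b = b,
       cap = grid$rho * grid$c * grid$volume_m)
}

# One theta-weighted implicit step of the discrete Pennes system.
bioheat_step <- function(T_now, sys, dt, theta) {
  n <- length(T_now)
  AT <- sys$diag * T_now
  AT[-n] <- AT[-n] + sys$upper * T_now[-1L]
  AT[-1L] <- AT[-1L] + sys$lower * T_now[-n]
  rhs <- sys$cap / dt * T_now - (1 - theta) * AT + sys$b
  thomas_solve(theta * sys$lower, sys$cap / dt + theta * sys$diag,
               theta * sys$upper, rhs)
}

#' Solve the transient 1-D Pennes bioheat equation for a current protocol
#'
#' Marches `rho c dT/dt = d/dx(k dT/dx) + w_b rho_b c_b (T_body - T) +
#' Q_met + Q_joule` across the layered stack with a theta-weighted implicit
#' finite-volume scheme (unconditionally stable for theta >= 0.5), from a
#' uniform initial temperature `T_baseline`, capturing depth profiles at
#' the protocol's report times.
#'
#' @param stack A `cornea_stack`.
#' @param protocol A `current_protocol`.
#' @param boundary A `thermal_boundary`; default the shipped calibrated set.
#' @param control A `solver_control`; default the shipped calibrated set
#'   (dt = 0.1 s, dx = 2 um, backward Euler, calibrated source scale).
#' @param steady If `TRUE`, continue past `duration_s` until the largest
#'   per-step change falls below `steady_tol` (run-to-steady-state mode).
#' @param steady_tol Convergence tolerance, degC per step, for steady mode.
#' @param steady_max_steps Step cap for steady mode.
#' @return An object of class `bioheat_field`: report times, node depths,
#'   a (time x depth) temperature matrix, per-node layer labels, the step
#'   count, and the inputs.
#' @examples
#' fld <- solve_bioheat(default_cornea(), current_protocol(0.5))
#' surface_temperature(fld, 10)
#' @export
solve_bioheat <- function(stack, protocol,
                          boundary = default_boundary(),
                          control = default_control(),
                          steady = FALSE, steady_tol = 1e-6,
                          steady_max_steps = 2e5) {
  stopifnot(inherits(stack, "cornea_stack"),
            inherits(protocol, "current_protocol"),
            inherits(boundary, "thermal_boundary"),
            inherits(control, "solver_control"))
  grid <- build_grid(stack, control)
  Q_layer <- joule_source(stack, protocol, scale = control$source_scale)
  sys <- assemble_system(grid, boundary, Q_layer[grid$layer_index])

  dt <- control$dt
  n_steps <- round(protocol$duration_s / dt)
  if (abs(n_steps * dt - protocol$duration_s) > 1e-9 * protocol$duration_s)
    stop_invalid("dt must divide duration_s")
  report <- protocol$report_times_s
  report_steps <- round(report / dt)

  T_now <- rep(control$T_baseline, grid$n)
  snaps <- matrix(NA_real_, nrow = length(report), ncol = grid$n)
  if (any(report_steps == 0L))
    snaps[report_steps == 0L, ] <- T_now
  steps_done <- 0L
  for (s in seq_len(n_steps)) {
    T_now <- bioheat_step(T_now, sys, dt, control$theta)
    if (any(!is.finite(T_now)))
      stop_invalid("numerical failure: non-finite temperatures at step ", s)
    steps_done <- s
    hit <- which(report_steps == s)
    if (length(hit)) snaps[hit, ] <- rep(T_now, each = length(hit))
  }
  if (steady) {
    repeat {
      T_next <- bioheat_step(T_now, sys, dt, control$theta)
      steps_done <- steps_done + 1L
      dmax <- max(abs(T_next - T_now))
      T_now <- T_next
      if (dmax < steady_tol || steps_done >= steady_max_steps) break
    }
  }
  structure(list(
    times_s = report, depths_um = grid$x_um, T = snaps,
    layer_of_node = grid$layer, final_T = T_now, steps = steps_done,
    baseline_C = control$T_baseline, stack = stack, protocol = protocol,
    boundary = boundary, control = control
  ), class = "bioheat_field")
}

check_report_time <- function(field, t) {
  i <- match(t, field$times_s)
  if (is.na(i))
    stop_invalid("time ", t, " s was not captured; available: ",
                 paste(field$times_s, collapse = ", "), " s")
  i
}

anterior_region_nodes <- function(field) {
  first_two <- unique(field$layer_of_node)[1:2]
  field$layer_of_node %in% first_two[!is.na(first_two)]
}

#' Corneal surface temperature at a report time
#'
#' "Surface" follows the anterior-region-maximum convention: the maximum
#' temperature over the tear-film and epithelium nodes. The alternative
#' conventions (tear-film node at depth 0, or the tear/epithelium interface
#' node) are selectable.
#'
#' @param field A `bioheat_field`.
#' @param t A captured report time, s.
#' @param convention One of `"anterior_max"`, `"tear_node"`,
#'   `"epithelial_surface"`.
#' @return Temperature in degC.
#' @export
surface_temperature <- function(field, t,
                                convention = c("anterior_max", "tear_node",
                                               "epithelial_surface")) {
  stopifnot(inherits(field, "bioheat_field"))
  convention <- match.arg(convention)
  i <- check_report_time(field, t)
  Tt <- field$T[i, ]
  switch(convention,
    anterior_max = max(Tt[anterior_region_nodes(field)]),
    tear_node = Tt[1L],
    epithelial_surface = {
      j <- which(field$layer_of_node != field$layer_of_node[1L])[1L]
      Tt[j]
    })
}

#' Per-layer maximum temperatures at a report time
#'
#' Reports the maximum over the nodes of each layer, plus a
#' `posterior_stroma` entry: the maximum over the posterior half of the
#' stroma (the third layer of the default stack).
#'
#' @param field A `bioheat_field`.
#' @param t A captured report time, s.
#' @return Named numeric vector of maxima, degC.
#' @export
layer_max_temperatures <- function(field, t) {
  stopifnot(inherits(field, "bioheat_field"))
  i <- check_report_time(field, t)
  Tt <- field$T[i, ]
  out <- vapply(unique(field$layer_of_node),
                function(l) max(Tt[field$layer_of_node == l]), numeric(1))
  stroma <- field$stack$name[pmin(3L, nrow(field$stack))]
  srow <- match(stroma, field$stack$name)
  mid <- (field$stack$position_start_um[srow] +
            field$stack$position_end_um[srow]) / 2
  sel <- field$layer_of_node == stroma & field$depths_um >= mid
  if (any(sel)) out <- c(out, posterior_stroma = max(Tt[sel]))
  out
}

#' Surface temperature rise above baseline
#'
#' @param field A `bioheat_field`.
#' @param t A captured report time, s.
#' @param convention Surface convention, see [surface_temperature()].
#' @return Temperature rise in degC (surface temperature minus the
#'   configured baseline).
#' @export
delta_T <- function(field, t, convention = "anterior_max") {
  surface_temperature(field, t, convention) - field$baseline_C
}

#' @export
print.bioheat_field <- function(x, ...) {
  cat("Pennes bioheat solution: ", x$protocol$current_mA, " mA, ",
      x$protocol$duration_s, " s (", x$steps, " steps of ",
      x$control$dt, " s, ", length(x$depths_um), " nodes)\n", sep = "")
  for (t in x$times_s) {
    cat(sprintf("  t = %4g s: surface max %7.2f degC, deltaT %6.2f degC\n",
                t, surface_temperature(x, t), delta_T(x, t)))
  }
  invisible(x)
}

#' @export
summary.bioheat_field <- function(object, ...) {
  rows <- lapply(object$times_s, function(t) {
    lm <- layer_max_temperatures(object, t)
    data.frame(time_s = t, surface_max_C = surface_temperature(object, t),
               delta_T_C = delta_T(object, t),
               t(as.matrix(lm)), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.bioheat_field <- function(x, ...) {
  long <- expand.grid(depth_um = x$depths_um, time_s = x$times_s,
                      KEEP.OUT.ATTRS = FALSE)
  long <- long[, c("time_s", "depth_um")]
  long$layer <- rep(x$layer_of_node, times = length(x$times_s))
  long$temp_C <- as.vector(t(x$T))
  long
}

#' @export
plot.bioheat_field <- function(x, ..., col = NULL) {
  if (is.null(col)) col <- seq_along(x$times_s)
  matplot(x$depths_um, t(x$T), type = "l", lty = 1, col = col,
          xlab = "Depth from anterior surface (um)",
          ylab = "Temperature (degC)",
          main = sprintf("%g mA", x$protocol$current_mA), ...)
  iface <- x$stack$position_end_um[-nrow(x$stack)]
  abline(v = iface, col = "grey80", lty = 3)
  legend("topright", legend = paste(x$times_s, "s"), col = col, lty = 1,
         bty = "n")
  invisible(x)
}
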
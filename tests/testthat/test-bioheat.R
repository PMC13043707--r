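test_that("grid construction places interfaces on nodes", {
  g <- build_grid(default_cornea(), solver_control(dx_um = 2))
  expect_equal(g$n, 512 / 2 + 1)
  expect_true(all(c(12, 62, 492) %in% g$x_um))
  # interface nodes belong to the posterior (starting) layer
  expect_equal(g$layer[g$x_um == 12], "epithelium")
  expect_equal(g$layer[g$x_um == 492], "endothelium")
  expect_equal(g$layer[g$x_um == 512], "endothelium")
  # every layer holds at least 3 nodes
  expect_true(all(table(g$layer) >= 3))
})

test_that("grid refuses a spacing coarser than the thinnest layer", {
  expect_error(build_grid(default_cornea(), solver_control(dx_um = 20)),
               "thinnest layer")
  expect_error(build_grid(default_cornea(), solver_control(dx_um = 5)),
               "divide")
})

test_that("homogeneous slab discretizes to uniform properties", {
  g <- build_grid(slab_stack(), solver_control(dx_um = 2))
  expect_equal(length(unique(g$k)), 1L)
  expect_equal(length(unique(g$sigma)), 1L)
  expect_true(all(g$layer == "slab"))
})

test_that("boundary-equilibrated zero-current field stays put", {
  fld <- solve_bioheat(default_cornea(), current_protocol(0),
                       default_boundary(), default_control())
  expect_lt(max(abs(fld$T - 34)), 1e-8)
  expect_equal(delta_T(fld, 60), 0, tolerance = 1e-8)
  expect_equal(fld$steps, 600L)
})

test_that("insulated uniform slab heats at Q/(rho c) per unit time", {
  stk <- slab_stack(sigma = 1, rho = 1000, c = 4000)
  prot <- current_protocol(10, duration_s = 10, report_times_s = c(5, 10))
  ctl <- solver_control(dt = 0.1, dx_um = 2, T_baseline = 30)
  fld <- solve_bioheat(stk, prot, insulated_boundary(30), ctl)
  Q <- unname(joule_source(stk, prot)[1])          # W/m^3, uniform
  rate <- Q / (1000 * 4000)                        # degC per s
  expect_equal(max(abs(fld$T[1, ] - (30 + rate * 5))), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(fld$T[2, ] - (30 + rate * 10))), 0,
               tolerance = 1e-8)
})

test_that("insulated-slab enthalpy gain matches integrated source power", {
  stk <- slab_stack(sigma = 0.5, rho = 1050, c = 3600)
  prot <- current_protocol(5, duration_s = 10, report_times_s = 10)
  ctl <- solver_control(dt = 0.1, dx_um = 2, T_baseline = 34)
  fld <- solve_bioheat(stk, prot, insulated_boundary(34), ctl)
  g <- build_grid(stk, ctl)
  enthalpy <- sum(g$rho * g$c * g$volume_m * (fld$T[1, ] - 34))
  power <- unname(joule_source(stk, prot)[1]) * sum(g$volume_m)
  expect_equal(enthalpy, power * 10, tolerance = 1e-6)
})

test_that("fixed-end slab matches the analytic Fourier series", {
  k <- 0.02; rho <- 1000; cc <- 4000
  stk <- slab_stack(k = k, rho = rho, c = cc)
  alpha <- k / (rho * cc)
  # theta slightly above 0.5: damps the Crank-Nicolson ringing the stiff
  # pinned-boundary term would otherwise sustain, at second-order cost
  ctl <- solver_control(dt = 0.01, dx_um = 2, theta = 0.55,
                        T_baseline = 34)
  fld <- solve_bioheat(stk, current_protocol(0, 10, 10),
                       dirichlet_boundary(20), ctl)
  exact <- fourier_slab(fld$depths_um * 1e-6, 10, 500e-6, alpha, 34, 20)
  scale <- max(abs(exact - 20))
  expect_gt(scale, 1)  # still mid-transient, a real comparison
  expect_lt(max(abs(fld$T[1, ] - exact)) / scale, 1e-3)
})

test_that("implicit scheme is stable at dt = 0.1 s on a um-scale grid", {
  # explicit FTCS would need alpha*dt/dx^2 <= 0.5; here it is >> 1
  ctl <- default_control()
  g <- build_grid(default_cornea(), ctl)
  expect_gt(max(g$k / (g$rho * g$c)) * ctl$dt / g$dx_m^2, 10)
  fld <- solve_bioheat(default_cornea(), current_protocol(7),
                       default_boundary(), ctl)
  expect_true(all(is.finite(fld$T)))
  # no grid-scale oscillation: the profile has only its physical extrema
  # (anterior peak, minimum ahead of the self-heating endothelium, endo
  # interior maximum), never node-to-node ringing
  prof <- fld$T[3, ]
  d <- diff(prof)
  d <- d[abs(d) > 1e-10]
  expect_lte(sum(diff(sign(d)) != 0), 3)
})

test_that("solution converges under grid and step refinement", {
  coarse <- solve_bioheat(default_cornea(), current_protocol(7),
                          control = solver_control(dt = 0.1, dx_um = 2,
                                                   source_scale = 1.234e-3))
  fine <- solve_bioheat(default_cornea(), current_protocol(7),
                        control = solver_control(dt = 0.05, dx_um = 1,
                                                 source_scale = 1.234e-3))
  expect_lt(abs(surface_temperature(coarse, 60) -
                  surface_temperature(fine, 60)), 0.05)
})

test_that("surface conventions and report-time lookup behave", {
  fld <- solve_bioheat(default_cornea(), current_protocol(500))
  expect_gte(surface_temperature(fld, 10, "anterior_max"),
             surface_temperature(fld, 10, "tear_node"))
  expect_equal(surface_temperature(fld, 10, "epithelial_surface"),
               fld$T[1, which(fld$depths_um == 12)])
  expect_error(surface_temperature(fld, 17), "not captured")
  s <- summary(fld)
  expect_equal(nrow(s), 3L)
  expect_true(all(c("surface_max_C", "delta_T_C", "posterior_stroma") %in%
                    names(s)))
})

test_that("long-format export matches the field", {
  fld <- solve_bioheat(default_cornea(), current_protocol(1))
  d <- as.data.frame(fld)
  expect_equal(names(d), c("time_s", "depth_um", "layer", "temp_C"))
  expect_equal(nrow(d), 3 * length(fld$depths_um))
  expect_equal(d$temp_C[d$time_s == 30], unname(fld$T[2, ]))
})
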
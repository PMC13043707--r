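gauss_band <- function(wn, center, fwhm, height) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(wn - center)^2 / (2 * s^2))
}

test_that("pipeline order is enforced and fails loudly", {
  raw <- gen_ftir_spectrum("control", seed = 1)
  expect_error(second_derivative(raw), "pipeline order")
  expect_error(average_group(list(raw)), "pipeline order")
  sm <- savgol_smooth(baseline_correct(raw))
  expect_error(baseline_correct(sm), "pipeline order")
  expect_error(integrate_band(sm, 1600, 1700), "pipeline order")
  d2 <- second_derivative(sm)
  expect_error(savgol_smooth(d2), "pipeline order")
  expect_equal(d2$stage, "second_derivative")
})

test_that("baseline correction removes offsets and ramps exactly", {
  wn <- seq(400, 4000, 2)
  anchors <- c(400, 1200, 2000, 2800, 4000)
  sig <- gauss_band(wn, 2129, 26, 0.5)
  for (base in list(rep(0.7, length(wn)), 0.1 + 2e-4 * (wn - 400))) {
    sp <- ir_spectrum(wn, sig + base)
    out <- baseline_correct(sp, anchors_cm1 = anchors)
    expect_lt(max(abs(out$absorbance - sig)), 1e-8)
  }
})

test_that("band areas survive a curved baseline within 2 %", {
  wn <- seq(400, 4000, 2)
  bands <- data.frame(name = c("b1", "b2"),
                      center_cm1 = c(2129, 1240), fwhm_cm1 = c(26, 30),
                      fraction_pct = c(50, 50))
  sp <- gen_ftir_spectrum(bands = bands, noise_sd = 0,
                          baseline_drift = TRUE, seed = 3)
  out <- baseline_correct(sp)
  for (i in 1:2) {
    s <- bands$fwhm_cm1[i] / (2 * sqrt(2 * log(2)))
    h <- bands$fraction_pct[i] / 100 * s * exp(0.5) / 4
    analytic <- h * s * sqrt(2 * pi)
    got <- integrate_band(out, bands$center_cm1[i] - 5 * s,
                          bands$center_cm1[i] + 5 * s,
                          mode = "absorbance")
    expect_lt(abs(got - analytic) / analytic, 0.02)
  }
})

test_that("Savitzky-Golay smoothing is exact on polynomials", {
  wn <- seq(1000, 1400, 2)
  quad <- ir_spectrum(wn, 3e-6 * wn^2 - 5e-3 * wn + 7)
  out <- savgol_smooth(quad)
  expect_lt(max(abs(out$absorbance - quad$absorbance)), 1e-8)
  const <- savgol_smooth(ir_spectrum(wn, rep(0.4, length(wn))))
  expect_lt(max(abs(const$absorbance - 0.4)), 1e-12)
  expect_error(savgol_smooth(ir_spectrum(wn, rep(1, length(wn))),
                             window = 8), "odd")
  expect_error(savgol_smooth(ir_spectrum(wn[1:5], rep(1, 5))), "shorter")
})

test_that("smoothing shrinks white noise by the kernel norm", {
  set.seed(5)
  wn <- seq(400, 4000, 0.5)
  noise <- rnorm(length(wn))
  sm <- savgol_smooth(ir_spectrum(wn, noise))
  kernel <- signal::sgolay(p = 2, n = 9)[5, ]
  predicted <- sqrt(sum(kernel^2))
  interior <- sm$absorbance[10:(length(wn) - 10)]
  expect_equal(stats::sd(interior), predicted, tolerance = 0.05)
})

test_that("replicate averaging is a pointwise mean on a shared grid", {
  wn <- seq(400, 4000, 2)
  mk <- function(y) {
    s <- ir_spectrum(wn, y)
    s$stage <- "smoothed"
    s
  }
  a <- mk(gauss_band(wn, 1666, 24, 1))
  b <- mk(gauss_band(wn, 1666, 24, 3))
  avg <- average_group(list(a, b))
  expect_equal(avg$absorbance, (a$absorbance + b$absorbance) / 2)
  expect_equal(avg$n_averaged, 2L)
  expect_equal(average_group(list(a, a, a))$absorbance, a$absorbance)
  off <- mk(gauss_band(wn, 1666, 24, 1))
  off$wavenumber_cm1 <- wn + 1
  expect_error(average_group(list(a, off)), "alignment")
})

test_that("averaging n noisy replicates shrinks residual noise by sqrt(n)", {
  wn <- seq(400, 4000, 2)
  truth <- gauss_band(wn, 2920, 44, 1)
  reps <- lapply(1:10, function(i) {
    set.seed(300 + i)
    s <- ir_spectrum(wn, truth + rnorm(length(wn), sd = 0.01))
    s$stage <- "smoothed"
    s
  })
  avg <- average_group(reps)
  expect_equal(stats::sd(avg$absorbance - truth), 0.01 / sqrt(10),
               tolerance = 0.15)
})

test_that("second derivative localizes bands and kills linear signals", {
  wn <- seq(400, 4000, 2)
  mk <- function(y) { s <- ir_spectrum(wn, y); s$stage <- "smoothed"; s }
  d2 <- second_derivative(mk(gauss_band(wn, 1666, 30, 1)))
  expect_lte(abs(wn[which.min(d2$absorbance)] - 1666), 2)
  lin <- second_derivative(mk(2e-4 * wn + 0.1))
  expect_lt(max(abs(lin$absorbance)), 1e-10)
  # two bands separated by > 1.5 FWHM resolve at their centres
  two <- mk(gauss_band(wn, 1620, 30, 1) + gauss_band(wn, 1668, 30, 0.8))
  dd <- second_derivative(two)
  sel <- wn >= 1590 & wn <= 1700
  y <- dd$absorbance[sel]; x <- wn[sel]
  minima <- x[which(diff(sign(diff(y))) == 2) + 1]
  expect_equal(length(minima), 2L)
  expect_lte(abs(minima[1] - 1620), 2)
  expect_lte(abs(minima[2] - 1668), 2)
})

test_that("second derivative commutes with averaging (linearity)", {
  reps <- lapply(1:4, function(i)
    savgol_smooth(baseline_correct(gen_ftir_spectrum("control",
                                                     seed = 40 + i))))
  d2_of_avg <- second_derivative(average_group(reps))
  d2s <- lapply(reps, second_derivative)
  avg_of_d2 <- rowMeans(vapply(d2s, `[[`,
                               numeric(length(d2_of_avg$absorbance)),
                               "absorbance"))
  expect_lt(max(abs(d2_of_avg$absorbance - avg_of_d2)), 1e-10)
})

test_that("band integration is a trapezoidal integral with mode control", {
  wn <- seq(400, 4000, 2)
  zero <- ir_spectrum(wn, numeric(length(wn)))
  expect_equal(integrate_band(zero, 1000, 1200, mode = "absorbance"), 0)
  rect <- ir_spectrum(wn, as.numeric(wn >= 1000 & wn <= 1100))
  expect_equal(integrate_band(rect, 1000, 1100, mode = "absorbance"), 100)
  g <- ir_spectrum(wn, gauss_band(wn, 2129, 26, 0.5))
  s <- 26 / (2 * sqrt(2 * log(2)))
  expect_equal(integrate_band(g, 2129 - 6 * s, 2129 + 6 * s,
                              mode = "absorbance"),
               0.5 * s * sqrt(2 * pi), tolerance = 0.01)
  expect_error(integrate_band(g, 100, 200, mode = "absorbance"), "range")
  expect_error(integrate_band(g, 1200, 1100, mode = "absorbance"), "lo")
})

test_that("area percentages normalize to the chosen denominator", {
  wn <- seq(400, 4000, 2)
  mk_d2 <- function(y) {
    s <- ir_spectrum(wn, y); s$stage <- "second_derivative"; s
  }
  one <- data.frame(name = "b", lo_cm1 = 2000, hi_cm1 = 2260,
                    reference_set = TRUE)
  d2 <- mk_d2(gauss_band(wn, 2129, 26, 1))
  r1 <- area_percentages(d2, one, denominator = "reference_set")
  expect_equal(r1$area_pct, 100)
  two <- data.frame(name = c("a", "b"), lo_cm1 = c(1100, 2000),
                    hi_cm1 = c(1400, 2260), reference_set = TRUE)
  d2b <- mk_d2(gauss_band(wn, 1240, 26, 2) + gauss_band(wn, 2129, 26, 2))
  r2 <- area_percentages(d2b, two, denominator = "reference_set")
  expect_equal(r2$area_pct, c(50, 50), tolerance = 1e-6)
  expect_equal(sum(r2$area_pct), 100, tolerance = 1e-9)
  expect_error(area_percentages(mk_d2(numeric(length(wn))), two),
               "degenerate")
})

test_that("the full chain recovers the control preset", {
  d2 <- process_ftir_group("control", n = 10, seed = 7)
  expect_equal(amide_peak_position(d2), 1666, tolerance = 2)
  rep <- area_percentages(d2)
  pre <- ftir_preset("control")
  m <- merge(pre, as.data.frame(rep)[, c("name", "area_pct")], by = "name")
  expect_lt(max(abs(m$area_pct - m$fraction_pct)), 2)
  oh <- m[m$name %in% c("strOH", "asyOH", "syOH"), ]
  expect_equal(oh$area_pct[match(c("strOH", "asyOH", "syOH"), oh$name)],
               c(31.1, 4.7, 2.2), tolerance = 2)
})

test_that("amide-I positions map onto secondary-structure motifs", {
  expect_equal(assign_secondary_structure(1666), "beta_turn")
  expect_equal(assign_secondary_structure(1659), "alpha_helix")
  expect_equal(assign_secondary_structure(1674), "beta_turn")
  expect_equal(assign_secondary_structure(1640), "beta_sheet_random_coil")
  # documented boundary convention: 1650 and 1660 read as helix
  expect_equal(assign_secondary_structure(c(1650, 1660)),
               c("alpha_helix", "alpha_helix"))
  expect_error(assign_secondary_structure(1750), "1600")
  wn <- seq(400, 4000, 2)
  flat <- ir_spectrum(wn, numeric(length(wn)))
  flat$stage <- "second_derivative"
  expect_error(amide_peak_position(flat), "flat")
})

test_that("the water combination band is the sum of its fundamentals", {
  expect_equal(water_combination_check(1640, 3400), 5040)
  expect_equal(water_combination_check(0, 2129), 2129)
  expect_equal(water_combination_check(1640, 3400),
               water_combination_check(3400, 1640))
  # the printed components do not reproduce the observed 2129 cm^-1 band
  expect_false(water_combination_check(1640, 3400) == 2129)
})
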
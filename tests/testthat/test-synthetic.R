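test_that("emission generator is linear in concentration and seeded", {
  z <- gen_emission_spectrum(0, noise_sd_rel = 0)
  expect_true(all(z$intensity == 0))
  a <- gen_emission_spectrum(0.5, noise_sd_rel = 0)
  b <- gen_emission_spectrum(1.0, noise_sd_rel = 0)
  expect_equal(b$intensity, 2 * a$intensity, tolerance = 1e-12)
  # 345 nm lies between nodes: 340 and 350 nm carry the equal maxima
  expect_equal(a$intensity[a$wavelength_nm == 340],
               a$intensity[a$wavelength_nm == 350], tolerance = 1e-12)
  expect_equal(max(a$intensity), peak_intensity(a, 345))
  s1 <- gen_emission_spectrum(1, seed = 9)
  s2 <- gen_emission_spectrum(1, seed = 9)
  s3 <- gen_emission_spectrum(1, seed = 10)
  expect_identical(s1$intensity, s2$intensity)
  expect_false(identical(s1$intensity, s3$intensity))
  expect_error(gen_emission_spectrum(-1), ">= 0")
})

test_that("calibration-series generator round-trips through the fit", {
  std <- gen_calibration_series(noise_sd_rel = 0, slope = 120,
                                intercept = 3)
  fit <- fit_calibration(std)
  expect_equal(fit$slope, 120, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  single <- gen_calibration_series(concentrations_mg_ml = 1,
                                   noise_sd_rel = 0)
  expect_error(fit_calibration(single), "3 distinct")
})

test_that("seeded replicate fits show < 0.5 % slope bias at 2 % noise", {
  slopes <- vapply(seq_len(500), function(i)
    fit_calibration(gen_calibration_series(noise_sd_rel = 0.02,
                                           seed = i))$slope,
    numeric(1))
  expect_lt(abs(mean(slopes) - 100) / 100, 0.005)
})

test_that("noise-free FTIR bands match their closed-form areas", {
  bands <- ftir_preset("control")
  sp <- gen_ftir_spectrum(bands = bands, noise_sd = 0,
                          baseline_drift = FALSE)
  i <- which(bands$name == "water_combination")
  s <- bands$fwhm_cm1[i] / (2 * sqrt(2 * log(2)))
  h <- bands$fraction_pct[i] / 100 * s * exp(0.5) / 4
  got <- integrate_band(sp, 2129 - 5 * s, 2129 + 5 * s,
                        mode = "absorbance")
  expect_equal(got, h * s * sqrt(2 * pi), tolerance = 0.01)
  expect_error(gen_ftir_spectrum("no_such_preset"), "arg")
})

test_that("FTIR generator is reproducible and stage-valid by construction", {
  a <- gen_ftir_spectrum("low_current", seed = 4)
  b <- gen_ftir_spectrum("low_current", seed = 4)
  expect_identical(a$absorbance, b$absorbance)
  expect_equal(a$stage, "raw")
  expect_s3_class(baseline_correct(a), "ir_spectrum")
  expect_equal(length(a$wavenumber_cm1), 1801L)
})

test_that("group concentration generator honours its design", {
  des <- default_concentration_design()
  expect_equal(des$mean_mg_ml[des$group == "6"], 1.7)
  expect_equal(des$mean_mg_ml[des$group == "500"], 2.7)
  expect_true(all(des$n == 10))
  des0 <- des
  des0$sd_mg_ml <- 0
  d0 <- gen_group_concentrations(des0, seed = 1)
  expect_equal(as.numeric(tapply(d0$value, d0$group, mean)[des0$group]),
               des0$mean_mg_ml, tolerance = 1e-12)
  d1 <- gen_group_concentrations(seed = 2)
  d2 <- gen_group_concentrations(seed = 2)
  expect_identical(d1$value, d2$value)
  # truncation at zero
  hard <- data.frame(group = "x", mean_mg_ml = 0.05, sd_mg_ml = 0.5,
                     n = 200L)
  expect_true(all(gen_group_concentrations(hard, seed = 3)$value >= 0))
})

test_that("generators restore the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_emission_spectrum(1, seed = 77))
  invisible(gen_group_concentrations(seed = 78))
  expect_identical(.Random.seed, before)
})

test_that("config generator applies overrides and rejects unknown keys", {
  cfg <- gen_cornea_config()
  expect_identical(cfg, default_config())
  over <- gen_cornea_config(list(layers = list(
    epithelium = list(sigma_S_per_m = 5e-4))))
  expect_equal(over$layers$sigma_S_per_m[2], 5e-4)
  over$layers$sigma_S_per_m[2] <- 4e-4
  expect_identical(over, cfg)
  expect_error(gen_cornea_config(list(nope = 1)), "unknown config key")
  expect_error(gen_cornea_config(list(layers = list(iris = list(
    k_W_mK = 1)))), "unknown layer")
  expect_error(gen_cornea_config(list(layers = list(stroma = list(
    colour = 1)))), "unknown layer field")
})
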
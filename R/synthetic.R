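#' Generate a synthetic albumin emission spectrum
#'
#' Gaussian tryptophan emission centred at 345 nm on the standard
#' 290-450 nm, 10 nm grid, with peak intensity linear in concentration
#' (zero concentration gives a zero spectrum) and optional multiplicative
#' Gaussian noise. Deterministic for a fixed seed.
#'
#' @param concentration_mg_ml Albumin concentration, mg/ml (>= 0).
#' @param noise_sd_rel Relative (multiplicative) noise SD; 0 for
#'   noiseless.
#' @param seed Optional integer seed.
#' @param slope Peak intensity per mg/ml.
#' @param peak_nm Emission maximum, nm.
#' @param fwhm_nm Full width at half maximum of the emission band, nm.
#' @param wavelength_nm Emission grid, nm.
#' @param group,replicate Metadata labels.
#' @return An [emission_spectrum()].
#' @export
gen_emission_spectrum <- function(concentration_mg_ml, noise_sd_rel = 0.02,
                                  seed = NULL, slope = 100, peak_nm = 345,
                                  fwhm_nm = 60,
                                  wavelength_nm = seq(290, 450, by = 10),
                                  group = NA, replicate = NA) {
  if (!is_number(concentration_mg_ml) || concentration_mg_ml < 0)
    stop_invalid("concentration must be a single number >= 0")
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  base <- slope * concentration_mg_ml *
    exp(-(wavelength_nm - peak_nm)^2 / (2 * sigma^2))
  y <- with_seed(seed, {
    if (noise_sd_rel > 0)
      base * (1 + stats::rnorm(length(base), sd = noise_sd_rel))
    else base
  })
  emission_spectrum(wavelength_nm, pmax(y, 0), group = group,
                    replicate = replicate)
}

#' Generate a calibration standards table
#'
#' Serial dilution standards (default 2, 1, 0.5, 0.25, 0.125 mg/ml) with
#' intensity `slope * conc + intercept` plus multiplicative noise.
#'
#' @param concentrations_mg_ml Standard concentrations.
#' @param slope,intercept True line parameters.
#' @param noise_sd_rel Relative noise SD.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `conc_mg_ml`, `intensity`.
#' @export
gen_calibration_series <- function(concentrations_mg_ml =
                                     c(2, 1, 0.5, 0.25, 0.125),
                                   slope = 100, intercept = 5,
                                   noise_sd_rel = 0.02, seed = NULL) {
  if (length(concentrations_mg_ml) < 1L || any(concentrations_mg_ml < 0))
    stop_invalid("concentrations must be >= 0")
  mu <- slope * concentrations_mg_ml + intercept
  y <- with_seed(seed, {
    if (noise_sd_rel > 0)
      mu * (1 + stats::rnorm(length(mu), sd = noise_sd_rel))
    else mu
  })
  data.frame(conc_mg_ml = concentrations_mg_ml, intensity = y)
}

#' Band presets for the synthetic FTIR generator
#'
#' One row per Gaussian band: centre, FWHM and the band's nominal
#' fraction (percent) of the total absolute-second-derivative area. The
#' presets mirror the published group fingerprints: the control amide I
#' at 1666 cm^-1 with hydroxyl fractions 31.1/4.7/2.2 %, the low-current
#' preset with strained carbonyl (1929/1821 cm^-1) and thiol bands, the
#' mid-current and extreme presets with amide I at 1674 cm^-1, and the
#' high-current preset shifted to 1659 cm^-1. Shipped as
#' `extdata/ftir_presets.csv`.
#'
#' @param group Preset name: `"control"`, `"low_current"` (0.5-2 mA),
#'   `"mid_current"` (3-5 mA), `"high_current"` (6-7 mA) or `"extreme"`
#'   (500 mA).
#' @return A data.frame with columns `name`, `center_cm1`, `fwhm_cm1`,
#'   `fraction_pct`.
#' @export
ftir_preset <- function(group = c("control", "low_current", "mid_current",
                                  "high_current", "extreme")) {
  group <- match.arg(group)
  path <- system.file("extdata", "ftir_presets.csv", package = "corion",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tab[tab$group == group, c("name", "center_cm1", "fwhm_cm1",
                                   "fraction_pct")]
  if (nrow(out) == 0L) stop_invalid("unknown FTIR preset: ", group)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic whole-cornea FTIR spectrum
#'
#' A sum of Gaussian bands on the 400-4000 cm^-1, 2 cm^-1 grid, plus a
#' smooth baseline drift and additive Gaussian noise. Band amplitudes are
#' calibrated so that each band's analytic absolute-second-derivative
#' area is `fraction_pct` percent of `d2_total_area`; the full processing
#' chain therefore recovers `fraction_pct` as its area percentage.
#'
#' @param group Preset name (see [ftir_preset()]); ignored when `bands`
#'   is given.
#' @param bands Optional explicit band table (columns as
#'   [ftir_preset()]).
#' @param noise_sd Additive absorbance noise SD, a.u.
#' @param baseline_drift If `TRUE` (default) add a smooth curved baseline.
#' @param d2_total_area Total absolute-second-derivative area the band set
#'   is scaled to (a.u. cm^-1).
#' @param seed Optional integer seed.
#' @param wavenumber_cm1 Spectral grid.
#' @param replicate Metadata label.
#' @return A raw-stage [ir_spectrum()].
#' @export
gen_ftir_spectrum <- function(group = "control", bands = NULL,
                              noise_sd = 0.002, baseline_drift = TRUE,
                              d2_total_area = 1, seed = NULL,
                              wavenumber_cm1 = seq(400, 4000, by = 2),
                              replicate = NA) {
  if (is.null(bands)) bands <- ftir_preset(group)
  stopifnot(all(c("center_cm1", "fwhm_cm1", "fraction_pct") %in%
                  names(bands)))
  wn <- wavenumber_cm1
  sig <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    s <- bands$fwhm_cm1[i] / (2 * sqrt(2 * log(2)))
    # |d2| area of a Gaussian of height h, sd s is 4 h exp(-1/2) / s
    h <- bands$fraction_pct[i] / 100 * d2_total_area * s * exp(0.5) / 4
    sig <- sig + h * exp(-(wn - bands$center_cm1[i])^2 / (2 * s^2))
  }
  if (baseline_drift) {
    z <- (wn - min(wn)) / diff(range(wn))
    sig <- sig + 0.10 + 0.15 * z + 0.08 * z^2 +
      0.05 * sin(2 * pi * 1.3 * z)
  }
  y <- with_seed(seed, {
    if (noise_sd > 0) sig + stats::rnorm(length(wn), sd = noise_sd)
    else sig
  })
  ir_spectrum(wn, y, stage = "raw", group = group, replicate = replicate)
}

#' Default per-group concentration design
#'
#' Group means anchored to the published pattern: indistinguishable low
#' concentrations at <= 5 mA, 1.7 mg/ml at 6 and 7 mA, and 2.7 mg/ml at
#' the extreme 500 mA, with n = 10 corneas per group and SD 0.1 mg/ml.
#'
#' @return A data.frame with columns `group`, `mean_mg_ml`, `sd_mg_ml`,
#'   `n`.
#' @export
default_concentration_design <- function() {
  data.frame(
    group = c("0.5", "1", "2", "3", "4", "5", "6", "7", "500"),
    mean_mg_ml = c(0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 1.7, 1.7, 2.7),
    sd_mg_ml = 0.1,
    n = 10L
  )
}

#' Generate per-group albumin concentration samples
#'
#' Seeded normal samples per group, truncated at zero.
#'
#' @param design A design table (see [default_concentration_design()]).
#' @param seed Optional integer seed.
#' @return A long data.frame with columns `group`, `value` (mg/ml).
#' @export
gen_group_concentrations <- function(design = default_concentration_design(),
                                     seed = NULL) {
  stopifnot(is.data.frame(design),
            all(c("group", "mean_mg_ml", "sd_mg_ml", "n") %in%
                  names(design)))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      v <- stats::rnorm(design$n[i], design$mean_mg_ml[i],
                        design$sd_mg_ml[i])
      while (any(v < 0))  # resample below-zero draws (truncation)
        v[v < 0] <- stats::rnorm(sum(v < 0), design$mean_mg_ml[i],
                                 design$sd_mg_ml[i])
      data.frame(group = design$group[i], value = v)
    })
    do.call(rbind, rows)
  })
}

merge_config <- function(base, overrides, path = "") {
  for (key in names(overrides)) {
    if (!key %in% names(base))
      stop_invalid("unknown config key: ", path, key)
    if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
      if (!is.list(overrides[[key]]))
        stop_invalid("config key ", path, key, " expects a nested list")
      base[[key]] <- merge_config(base[[key]], overrides[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- overrides[[key]]
    }
  }
  base
}

#' Generate a cornea configuration, optionally with overrides
#'
#' Returns the shipped default configuration (layer tables, calibrated
#' thermal/boundary/solver parameters, protocol) with nested overrides
#' applied. Layer fields are overridden via
#' `list(layers = list(<layer name> = list(<field> = value)))`; all other
#' keys mirror the YAML structure. Unknown keys raise an error.
#'
#' @param overrides Nested named list of overrides.
#' @return A configuration list (see [read_cornea_config()]).
#' @examples
#' cfg <- gen_cornea_config(list(layers = list(
#'   epithelium = list(sigma_S_per_m = 5e-4))))
#' @export
gen_cornea_config <- function(overrides = list()) {
  cfg <- default_config()
  if (length(overrides) == 0L) return(cfg)
  lay_over <- overrides$layers
  overrides$layers <- NULL
  cfg_nolayers <- cfg
  cfg_nolayers$layers <- NULL
  cfg_new <- merge_config(cfg_nolayers, overrides)
  cfg_new$layers <- cfg$layers
  if (!is.null(lay_over)) {
    for (lname in names(lay_over)) {
      i <- match(lname, cfg_new$layers$name)
      if (is.na(i)) stop_invalid("unknown layer: ", lname)
      for (f in names(lay_over[[lname]])) {
        if (!f %in% names(cfg_new$layers))
          stop_invalid("unknown layer field: ", f)
        cfg_new$layers[[f]][i] <- lay_over[[lname]][[f]]
      }
    }
  }
  cfg_new[names(cfg)]
}
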
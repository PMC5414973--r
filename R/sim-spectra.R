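#' Generate synthetic sun and LED irradiance spectra
#'
#' Emulates the two calibration inputs: a smooth broadband sunlight curve
#' (scaled 5800-K blackbody shape, peaking near 150 uW cm^-2 nm^-1 at unit
#' scale) and a narrow unimodal LED line (Gaussian, sigma 10 nm) centered
#' on the excitation wavelength. Both are nonnegative and linear in their
#' scale factors.
#'
#' @param band_center LED peak wavelength, nm.
#' @param sun_scale,led_scale nonnegative multiplicative scales.
#' @param grid wavelength step, nm; grid spans 300--800 nm.
#' @return list with `sun` and `led` [irradiance_spectrum()]s.
#' @export
generate_irradiance_spectra <- function(band_center = 340, sun_scale = 1,
                                        led_scale = 1, grid = 1) {
  if (sun_scale < 0 || led_scale < 0) stop("scales must be nonnegative")
  wl <- seq(300, 800, by = grid)
  # blackbody spectral shape at 5800 K (units absorbed into the peak scale)
  Tk <- 5800
  lam_m <- wl * 1e-9
  bb <- lam_m^-5 / (exp(PLANCK_H * LIGHT_C / (lam_m * 1.380649e-23 * Tk)) - 1)
  sun <- sun_scale * 150 * bb / max(bb)
  led <- led_scale * 50 * exp(-(wl - band_center)^2 / (2 * 10^2))
  list(sun = irradiance_spectrum(wl, sun, source = "synthetic_sun"),
       led = irradiance_spectrum(wl, led, source = "synthetic_led"))
}

#' Default group reflectance profiles
#'
#' Percent-reflectance curves on a 300--800 nm grid with the study's
#' qualitative structure: adult females most reflective, adult males least,
#' and a 450--550 nm reflectivity bump present in female-like groups and
#' immatures but absent in adult males.
#'
#' @param grid wavelength step, nm.
#' @return named list of [spectrum_obj()]s, one per group.
#' @export
default_reflectance_profiles <- function(grid = 2) {
  wl <- seq(300, 800, by = grid)
  base <- function(level, bump) {
    level * (0.6 + 0.4 * (wl - 300) / 500) +
      bump * exp(-(wl - 500)^2 / (2 * 35^2))
  }
  lv <- c(adult_female = 55, adult_male = 18, penultimate_female = 40,
          penultimate_male = 28, immature = 42)
  bp <- c(adult_female = 15, adult_male = 0, penultimate_female = 12,
          penultimate_male = 4, immature = 12)
  setNames(lapply(names(lv), function(g) {
    spectrum_obj(wl, base(lv[[g]], bp[[g]]), kind = "reflectance",
                 metadata = list(group = g))
  }), names(lv))
}

#' Generate a nested set of synthetic reflectance readings
#'
#' Emulates the spectrometer protocol: per specimen, `measurements`
#' measurements each consisting of `readings_per_measurement` raw readings
#' (defaults 4 x 10, the probe held 2 mm from the specimen at 90 degrees,
#' 0.007-s integration), each reading a noisy copy of the specimen group's
#' profile.
#'
#' @param group_profiles named list of [spectrum_obj()] profiles sharing one
#'   wavelength grid (see [default_reflectance_profiles()]).
#' @param n_per_group named integer vector of specimens per group; defaults
#'   to the reflectance study sizes (15/5/3/9/2).
#' @param readings_per_measurement,measurements hierarchy counts, >= 1.
#' @param noise_sd per-reading noise standard deviation (percent units).
#' @param seed master seed.
#' @return object of class `reflectance_set`: shared grid plus a list of
#'   specimens, each with its group label and nested
#'   measurement -> reading spectra.
#' @export
generate_reflectance_curves <- function(group_profiles = default_reflectance_profiles(),
                                        n_per_group = c(adult_female = 15L,
                                                        adult_male = 5L,
                                                        penultimate_female = 3L,
                                                        penultimate_male = 9L,
                                                        immature = 2L),
                                        readings_per_measurement = 10L,
                                        measurements = 4L,
                                        noise_sd = 1,
                                        seed = 1L) {
  if (!is_count(readings_per_measurement) || !is_count(measurements)) {
    stop("hierarchy counts must be integers >= 1")
  }
  grid <- group_profiles[[1L]]$wavelengths
  for (p in group_profiles) {
    if (!isTRUE(all.equal(p$wavelengths, grid))) {
      stop("alignment error: group profiles on mismatched wavelength grids")
    }
  }
  specimens <- list()
  for (g in names(n_per_group)) {
    prof <- group_profiles[[g]]
    if (is.null(prof)) stop("no profile for group '", g, "'")
    for (i in seq_len(n_per_group[[g]])) {
      sid <- sprintf("%s_r%02d", g, i)
      sub <- derive_seed(seed, "reflectance", sid)
      meas <- withr::with_seed(sub, {
        lapply(seq_len(measurements), function(m) {
          lapply(seq_len(readings_per_measurement), function(r) {
            spectrum_obj(grid,
                         prof$values + rnorm(length(grid), 0, noise_sd),
                         kind = "reflectance",
                         metadata = list(specimen = sid, measurement = m,
                                         reading = r,
                                         integration_time_s = 0.007,
                                         probe_distance_mm = 2,
                                         angle_deg = 90))
          })
        })
      })
      specimens[[sid]] <- list(specimen_id = sid, group = g,
                               measurements = meas)
    }
  }
  structure(list(wavelengths = grid, specimens = specimens),
            class = "reflectance_set")
}
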
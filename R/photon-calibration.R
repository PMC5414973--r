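# SI exact values
PLANCK_H <- 6.62607015e-34   # J s
LIGHT_C  <- 2.99792458e8     # m / s

#' Absolute irradiance spectrum
#'
#' Wavelength-sampled absolute irradiance in uW cm^-2 nm^-1 on a strictly
#' increasing nm grid, as exported by a field spectrometer.
#'
#' @param wavelengths nm grid, strictly increasing.
#' @param irradiance nonnegative irradiance values, same length.
#' @param source free-text source label.
#' @export
irradiance_spectrum <- function(wavelengths, irradiance, source = "unknown") {
  if (length(wavelengths) != length(irradiance)) {
    stop("wavelengths and irradiance must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (any(irradiance < 0)) stop("input error: negative irradiance")
  structure(list(wavelengths = as.numeric(wavelengths),
                 irradiance = as.numeric(irradiance), source = source),
            class = "irradiance_spectrum")
}

#' Photon flux of an irradiance spectrum over a wavelength band
#'
#' Converts irradiance E (uW cm^-2 nm^-1) to photon rate via the per-photon
#' energy hc/lambda and integrates over the band by the trapezoidal rule on
#' the native grid, with linearly interpolated band endpoints:
#' flux = integral of E(lambda) * 1e-6 * (lambda * 1e-9) / (h c) d lambda,
#' in photons cm^-2 s^-1. Linear in the irradiance values.
#'
#' @param spectrum an [irradiance_spectrum()].
#' @param band `c(lambda_lo, lambda_hi)` in nm, within the grid.
#' @export
photon_flux <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "irradiance_spectrum"), length(band) == 2L)
  lo <- band[1L]; hi <- band[2L]
  if (!(lo < hi)) stop("band must satisfy lambda_lo < lambda_hi")
  wl <- spectrum$wavelengths
  if (lo < wl[1L] || hi > wl[length(wl)]) {
    stop("domain error: band [", lo, ", ", hi,
         "] nm outside the spectrum grid [", wl[1L], ", ", wl[length(wl)], "]")
  }
  inner <- wl > lo & wl < hi
  grid <- c(lo, wl[inner], hi)
  vals <- approx(wl, spectrum$irradiance, xout = grid)$y
  photons_per_nm <- vals * 1e-6 * (grid * 1e-9) / (PLANCK_H * LIGHT_C)
  pracma::trapz(grid, photons_per_nm)
}

#' Band over which an LED emits, defined by a fraction of its peak
#'
#' Alternative to a fixed band: the wavelength range where the LED's
#' irradiance exceeds `frac` of its maximum.
#'
#' @param led an [irradiance_spectrum()].
#' @param frac fraction of the peak (default 1%).
#' @export
led_support_band <- function(led, frac = 0.01) {
  pk <- max(led$irradiance)
  if (pk <= 0) stop("calibration error: LED spectrum is identically zero")
  on <- led$irradiance > frac * pk
  range(led$wavelengths[on])
}

#' Photon-equivalent LED exposure time
#'
#' How long an LED exposure delivers the same number of photons in a
#' wavelength band as a reference duration of sunlight:
#' `led_exposure_time = sun_reference_time * flux(sun) / flux(led)`.
#' The study's use case: equalling 0.1 s of June sunlight at 340 nm with a
#' 340-nm LED (a 117-s exposure at the instruments' measured flux ratio).
#'
#' @param led,sun [irradiance_spectrum()]s.
#' @param band `c(lambda_lo, lambda_hi)` nm; default 330--350, a 20-nm
#'   window around the 340-nm excitation line. Pass
#'   `led_support_band(led)` to integrate over the LED's own support.
#' @param sun_reference_time reference sun exposure in seconds.
#' @return object of class `exposure_result` with both photon fluxes
#'   (photons cm^-2 s^-1) and the equivalent LED exposure time (s).
#' @export
equivalent_exposure <- function(led, sun, band = c(330, 350),
                                sun_reference_time = 0.1) {
  sun_flux <- photon_flux(sun, band)
  led_flux <- photon_flux(led, band)
  if (led_flux <= 0) {
    stop("calibration error: zero LED photon flux in band [",
         band[1L], ", ", band[2L], "] nm; cannot equalize photon dose")
  }
  structure(list(
    band = band,
    sun_photon_flux = sun_flux, led_photon_flux = led_flux,
    sun_reference_time = sun_reference_time,
    led_exposure_time = sun_reference_time * sun_flux / led_flux
  ), class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat(sprintf("Photon-equivalent exposure over [%g, %g] nm\n",
              x$band[1L], x$band[2L]))
  cat(sprintf("  sun flux: %.4g photons cm^-2 s^-1\n", x$sun_photon_flux))
  cat(sprintf("  LED flux: %.4g photons cm^-2 s^-1\n", x$led_photon_flux))
  cat(sprintf("  %g s of sun == %.4g s of LED exposure\n",
              x$sun_reference_time, x$led_exposure_time))
  invisible(x)
}

#' Read / write two-column tab-delimited spectra
#'
#' Format: one header line, then `wavelength_nm<TAB>value` rows.
#'
#' @param path file path.
#' @param value_name header label of the value column.
#' @param wavelengths,values vectors to write.
#' @export
write_spectrum_tsv <- function(wavelengths, values, path,
                               value_name = "irradiance_uW_cm2_nm") {
  df <- data.frame(wavelength_nm = wavelengths, value = values)
  names(df)[2L] <- value_name
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  if (ncol(df) < 2L) stop("expected two tab-delimited columns in ", path)
  list(wavelengths = df[[1L]], values = df[[2L]], value_name = names(df)[2L])
}

#' @rdname write_spectrum_tsv
#' @export
read_irradiance_tsv <- function(path) {
  s <- read_spectrum_tsv(path)
  irradiance_spectrum(s$wavelengths, s$values, source = basename(path))
}
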
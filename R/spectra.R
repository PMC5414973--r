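#' Generic wavelength-sampled spectrum
#'
#' A reflectance (percent or relative) or emission (relative) curve on a
#' strictly increasing nm grid, with free-form acquisition metadata.
#'
#' @param wavelengths nm grid, strictly increasing.
#' @param values same-length numeric values.
#' @param kind `"reflectance"` or `"emission"`.
#' @param metadata named list (specimen, integration time, probe geometry...).
#' @export
spectrum_obj <- function(wavelengths, values,
                         kind = c("reflectance", "emission"),
                         metadata = list()) {
  kind <- match.arg(kind)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 values = as.numeric(values), kind = kind,
                 metadata = metadata),
            class = "spectrum_obj")
}

same_grid <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-12))

#' Hierarchical averaging of a reflectance set
#'
#' Wavelength-wise mean of the raw readings within each measurement, then
#' wavelength-wise mean of the measurement means per specimen -- unweighted
#' at both levels, so an unbalanced design (measurements with unequal
#' numbers of readings) still weights measurements equally rather than
#' pooling readings. Mismatched wavelength grids are an error; there is no
#' silent interpolation.
#'
#' @param set a `reflectance_set` (see [generate_reflectance_curves()]).
#' @return named list of per-specimen [spectrum_obj()]s.
#' @export
average_hierarchy <- function(set) {
  stopifnot(inherits(set, "reflectance_set"))
  grid <- set$wavelengths
  lapply(set$specimens, function(sp) {
    meas_means <- lapply(sp$measurements, function(m) {
      if (length(m) < 1L) stop("measurement with no readings")
      vals <- vapply(m, function(rd) {
        if (!same_grid(rd$wavelengths, grid)) {
          stop("alignment error: reading on a mismatched wavelength grid")
        }
        rd$values
      }, numeric(length(grid)))
      rowMeans(as.matrix(vals))
    })
    spec_mean <- rowMeans(do.call(cbind, meas_means))
    spectrum_obj(grid, spec_mean, kind = "reflectance",
                 metadata = list(specimen = sp$specimen_id, group = sp$group))
  })
}

#' Group-mean reflectance curves
#'
#' Unweighted wavelength-wise mean across the specimens within each group.
#'
#' @param specimen_spectra named list of per-specimen [spectrum_obj()]s.
#' @param groups group label per specimen (same length/order).
#' @return named list of per-group [spectrum_obj()]s.
#' @export
group_mean_reflectance <- function(specimen_spectra, groups) {
  if (length(specimen_spectra) != length(groups)) {
    stop("one group label per specimen spectrum is required")
  }
  if (length(specimen_spectra) == 0L) stop("usage error: no specimens")
  grid <- specimen_spectra[[1L]]$wavelengths
  out <- list()
  for (g in unique(groups)) {
    members <- specimen_spectra[groups == g]
    if (length(members) == 0L) stop("usage error: empty group '", g, "'")
    vals <- vapply(members, function(s) {
      if (!same_grid(s$wavelengths, grid)) {
        stop("alignment error: specimen spectra on mismatched grids")
      }
      s$values
    }, numeric(length(grid)))
    out[[g]] <- spectrum_obj(grid, rowMeans(as.matrix(vals)),
                             kind = "reflectance",
                             metadata = list(group = g,
                                             n = length(members)))
  }
  out
}

#' Max-normalize an emission spectrum
#'
#' Divides by the maximum so the peak equals 1; shape-preserving and
#' idempotent.
#'
#' @param spectrum a [spectrum_obj()].
#' @export
normalize_emission <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_obj"))
  mx <- max(spectrum$values)
  if (mx <= 0) stop("normalization error: spectrum maximum is not positive")
  spectrum_obj(spectrum$wavelengths, spectrum$values / mx,
               kind = "emission", metadata = spectrum$metadata)
}

#' Emission band at a fractional threshold
#'
#' Smallest and largest wavelengths at which the spectrum reaches
#' `threshold` times its maximum, with linear interpolation between grid
#' points; invariant under normalization.
#'
#' @param spectrum a [spectrum_obj()].
#' @param threshold fraction of the maximum, in (0, 1).
#' @return `c(lambda_lo, lambda_hi)` in nm.
#' @export
emission_band <- function(spectrum, threshold = 0.5) {
  stopifnot(inherits(spectrum, "spectrum_obj"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly between 0 and 1")
  }
  wl <- spectrum$wavelengths
  v <- spectrum$values
  cut <- threshold * max(v)
  above <- which(v >= cut)
  if (length(above) == 0L) stop("band error: threshold never reached")
  i <- above[1L]
  j <- above[length(above)]
  lo <- if (i == 1L) wl[1L] else {
    wl[i - 1L] + (cut - v[i - 1L]) / (v[i] - v[i - 1L]) * (wl[i] - wl[i - 1L])
  }
  hi <- if (j == length(wl)) wl[length(wl)] else {
    wl[j] + (cut - v[j]) / (v[j + 1L] - v[j]) * (wl[j + 1L] - wl[j])
  }
  c(lo, hi)
}
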
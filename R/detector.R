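#' Raster scan configuration
#'
#' Describes one raster-scanned XRF acquisition: pixel pitch, per-pixel dwell
#' time, and the field size in pixels. Typical settings are 500 nm / 100 ms
#' for coarse localization scans, 300 nm / 200 ms for whole-filament maps and
#' 100 nm / 200 ms for high-resolution region-of-interest maps.
#'
#' @param step_nm Pixel pitch in nanometres (> 0).
#' @param dwell_ms Per-pixel dwell time in milliseconds (> 0).
#' @param field_shape Integer vector `c(rows, cols)`.
#' @return An object of class `scan_config`.
#' @examples
#' scan_config(100, 200, c(64, 384))
#' @export
scan_config <- function(step_nm = 100, dwell_ms = 200, field_shape = c(64, 384)) {
  stopifnot(is.numeric(step_nm), length(step_nm) == 1, step_nm > 0,
            is.numeric(dwell_ms), length(dwell_ms) == 1, dwell_ms > 0,
            length(field_shape) == 2, all(field_shape >= 1))
  structure(
    list(step_nm = step_nm, dwell_ms = dwell_ms,
         field_shape = as.integer(field_shape)),
    class = "scan_config"
  )
}

#' Pixel area of a scan in square micrometres
#'
#' @param scan A `scan_config`.
#' @return Pixel area in um^2, i.e. `(step_nm / 1000)^2`.
#' @export
pixel_area_um2 <- function(scan) {
  (scan$step_nm / 1000)^2
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> %d x %d px, step %g nm (%.4g um^2/px), dwell %g ms\n",
              x$field_shape[1], x$field_shape[2], x$step_nm,
              pixel_area_um2(x), x$dwell_ms))
  invisible(x)
}

#' Energy-dispersive detector and excitation model
#'
#' Captures the pieces of the forward spectral model shared by simulation and
#' fitting: the incident photon energy (only lines below it are excitable),
#' the energy axis binning, the line-shape parameters of the exponentially
#' modified Gaussian detector response (Gaussian width `resolution_ev`,
#' exponential tail constant `tail_tau_ev`), a two-parameter exponential
#' continuum, a global flux scale, and a smooth monotone elemental
#' sensitivity curve in atomic number Z.
#'
#' The sensitivity curve `s0 * exp(slope * (Z - 13))` (counts per
#' ug/cm^2 per ms, before the flux scale) is a modelling convention: real
#' instruments calibrate sensitivity empirically against a thin-film
#' standard, and any fixed injective mapping supports a full
#' calibration round trip. Exponential-in-Z makes log-linear interpolation of
#' calibrated sensitivities exact.
#'
#' @param incident_kev Incident photon energy in keV.
#' @param bin_kev Energy bin width in keV.
#' @param resolution_ev Gaussian sigma of the line shape, in eV.
#' @param tail_tau_ev Exponential tail constant of the line shape, in eV.
#' @param continuum Named numeric `c(amplitude, decay_kev)`: continuum counts
#'   per bin per ms at E = 0 and its exponential decay constant in keV.
#' @param flux_scale Dimensionless global intensity factor.
#' @param sens_s0,sens_slope Parameters of the sensitivity curve in Z.
#' @return An object of class `detector_model` with an `energy_kev` axis of
#'   bin centres covering (0, incident_kev].
#' @export
detector_model <- function(incident_kev = 10, bin_kev = 0.02,
                           resolution_ev = 60, tail_tau_ev = 50,
                           continuum = c(amplitude = 0.02, decay_kev = 3),
                           flux_scale = 1,
                           sens_s0 = 1.0, sens_slope = 0.08) {
  stopifnot(incident_kev > 0, bin_kev > 0, resolution_ev > 0,
            tail_tau_ev > 0, flux_scale > 0, sens_s0 > 0)
  energy <- seq(bin_kev / 2, incident_kev, by = bin_kev)
  structure(
    list(incident_kev = incident_kev, bin_kev = bin_kev,
         energy_kev = energy,
         resolution_ev = resolution_ev, tail_tau_ev = tail_tau_ev,
         continuum = continuum, flux_scale = flux_scale,
         sens_s0 = sens_s0, sens_slope = sens_slope),
    class = "detector_model"
  )
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(paste0("<detector_model> %g keV incident, %d bins of %g keV, ",
                     "sigma %g eV, tau %g eV\n"),
              x$incident_kev, length(x$energy_kev), x$bin_kev,
              x$resolution_ev, x$tail_tau_ev))
  invisible(x)
}

#' True elemental sensitivity of a detector model
#'
#' Evaluates the detector's sensitivity curve (including the flux scale) for
#' a set of elements: fitted peak area per ug/cm^2 per ms dwell. This is the
#' quantity a thin-film calibration estimates empirically.
#'
#' @param det A `detector_model`.
#' @param elements Character vector of element symbols.
#' @return Named numeric vector of sensitivities.
#' @export
detector_sensitivity <- function(det, elements) {
  z <- element_z(elements)
  s <- det$flux_scale * det$sens_s0 * exp(det$sens_slope * (z - 13))
  names(s) <- elements
  s
}

#' Check that elements are excitable at the incident energy
#' @noRd
assert_excitable <- function(det, elements, catalog = line_catalog()) {
  cat <- catalog[match(elements, catalog$element), ]
  if (anyNA(cat$element)) {
    stop("element(s) absent from line catalog: ",
         paste(elements[is.na(match(elements, catalog$element))], collapse = ", "))
  }
  bad <- cat$element[cat$ka_kev >= det$incident_kev]
  if (length(bad) > 0) {
    stop("K-alpha above incident energy for: ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
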
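#' Calibrate elemental sensitivities from a thin-film standard
#'
#' Converts fluorescence peak areas to areal concentrations via the
#' peak-area to concentration ratios of a certified thin-film standard:
#' the standard's spectrum is background-stripped and peak-fitted with the
#' same machinery used for unknowns, and each certified element's
#' sensitivity is `fitted area / (nominal density x live time)`. Elements
#' not present on the standard get sensitivities by log-linear
#' interpolation in atomic number Z between the calibrated ones (the
#' elemental response of an XRF instrument varies smoothly with Z).
#'
#' @param standard Data frame with columns `element` and `density_ug_cm2`
#'   (certified areal densities, > 0).
#' @param spectrum Measured `xrf_spectrum` of the standard.
#' @param det A `detector_model`.
#' @param catalog Line catalog.
#' @param elements Additional element symbols to cover by interpolation.
#' @param n_iter,max_window_bins SNIP parameters.
#' @return Object of class `sensitivity_table`: tibble with `element`, `z`,
#'   `sensitivity` (area per ug/cm^2 per ms) and `source`
#'   ("fitted"/"interpolated").
#' @export
calibrate_sensitivities <- function(standard, spectrum,
                                    det = detector_model(),
                                    catalog = line_catalog(),
                                    elements = NULL,
                                    n_iter = 24, max_window_bins = 20) {
  stopifnot(all(c("element", "density_ug_cm2") %in% names(standard)),
            all(standard$density_ug_cm2 > 0),
            inherits(spectrum, "xrf_spectrum"))
  bg <- strip_background(spectrum, n_iter, max_window_bins)
  net <- xrf_spectrum(spectrum$energy_kev,
                      pmax(spectrum$counts - bg$counts, 0),
                      spectrum$live_time_ms)
  fit <- fit_element_peaks(net, standard$element, det, catalog)
  ok <- fit$areas$converged & fit$areas$ka_area > 0
  if (!any(ok)) stop("calibration failed: no element could be fitted")
  cal <- tibble::tibble(
    element = standard$element[ok],
    z = element_z(standard$element[ok]),
    sensitivity = fit$areas$ka_area[ok] /
      (standard$density_ug_cm2[ok] * spectrum$live_time_ms),
    source = "fitted")
  extra <- setdiff(elements, cal$element)
  if (length(extra) > 0) {
    if (nrow(cal) < 2) stop("need >= 2 calibrated elements to interpolate")
    zi <- element_z(extra)
    ls <- stats::approx(cal$z, log(cal$sensitivity), xout = zi, rule = 2)$y
    # linear extrapolation in log-sensitivity beyond the calibrated range
    out_lo <- zi < min(cal$z); out_hi <- zi > max(cal$z)
    if (any(out_lo | out_hi)) {
      fitlm <- stats::lm(log(sensitivity) ~ z, data = cal)
      ls[out_lo | out_hi] <- stats::predict(
        fitlm, newdata = data.frame(z = zi[out_lo | out_hi]))
    }
    cal <- dplyr::bind_rows(cal, tibble::tibble(
      element = extra, z = zi, sensitivity = exp(ls), source = "interpolated"))
  }
  cal <- dplyr::arrange(cal, .data$z)
  class(cal) <- c("sensitivity_table", class(cal))
  cal
}

#' Coerce a sensitivity table or named vector to a named vector
#' @noRd
sensitivity_vector <- function(sens) {
  if (inherits(sens, "sensitivity_table") ||
      (is.data.frame(sens) && all(c("element", "sensitivity") %in% names(sens)))) {
    stats::setNames(sens$sensitivity, sens$element)
  } else if (is.numeric(sens) && !is.null(names(sens))) {
    sens
  } else {
    stop("sens must be a sensitivity_table or a named numeric vector")
  }
}
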
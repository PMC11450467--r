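#' Expected (noiseless) count maps for a phantom
#'
#' Forward model without noise: expected counts per pixel are
#' `concentration x sensitivity x dwell`, with the sensitivity taken from
#' the detector model's elemental response curve.
#'
#' @param truth A `phantom_truth`.
#' @param scan A `scan_config` (defaults to the phantom's own).
#' @param det A `detector_model`.
#' @return Named list of expected-count matrices.
#' @export
expected_counts <- function(truth, scan = truth$scan, det = detector_model()) {
  sens <- detector_sensitivity(det, names(truth$maps))
  lapply(stats::setNames(names(truth$maps), names(truth$maps)), function(e) {
    v <- truth$maps[[e]]$values
    if (any(v < 0, na.rm = TRUE)) stop("negative concentration in truth map ", e)
    v * sens[[e]] * scan$dwell_ms
  })
}

#' Simulate Poisson-noised XRF count maps
#'
#' Each pixel count is drawn as Poisson with mean equal to the noiseless
#' forward value, so doubling the dwell time doubles the expected counts and
#' the relative noise scales as 1/sqrt(counts).
#'
#' @inheritParams expected_counts
#' @param seed Integer RNG seed.
#' @param noise Set `FALSE` to return the expectation itself.
#' @return Object of class `count_maps`: named list `counts` of matrices
#'   plus the scan, detector and seed used.
#' @export
simulate_counts <- function(truth, scan = truth$scan, det = detector_model(),
                            seed = 1, noise = TRUE) {
  lam <- expected_counts(truth, scan, det)
  counts <- if (noise) {
    withr::with_seed(as.integer(seed), lapply(lam, function(l) {
      matrix(stats::rpois(length(l), l), nrow(l), ncol(l))
    }))
  } else lam
  structure(list(counts = counts, scan = scan, det = det, seed = seed,
                 noise = noise),
            class = "count_maps")
}

#' Convert count maps back to concentration maps
#'
#' Inverts the counting forward model with known (or calibrated)
#' sensitivities; the fast path used when per-pixel spectra are not needed.
#'
#' @param cm A `count_maps` object.
#' @param sens Named numeric vector of sensitivities (area per ug/cm^2 per
#'   ms); defaults to the true detector curve.
#' @return Named list of `element_map`s.
#' @export
counts_to_maps <- function(cm, sens = NULL) {
  if (is.null(sens)) sens <- detector_sensitivity(cm$det, names(cm$counts))
  lapply(stats::setNames(names(cm$counts), names(cm$counts)), function(e) {
    element_map(e, cm$counts[[e]] / (sens[[e]] * cm$scan$dwell_ms),
                cm$scan$step_nm)
  })
}

#' Simulate a per-pixel spectrum cube
#'
#' Full spectral forward model: for every pixel, expected counts per energy
#' bin are a continuum plus, for each element, a K-alpha EMG peak and its
#' ratio-locked K-beta companion with total K-alpha area
#' `concentration x sensitivity x dwell`; Poisson noise is applied per bin.
#'
#' @inheritParams simulate_counts
#' @param catalog Line catalog (energies and K-beta/K-alpha ratios).
#' @return Object of class `spectrum_cube`: `counts` is an (n_pixels x
#'   n_bins) matrix in row-major pixel order with `field_shape` recording
#'   the grid, plus the energy axis, scan, detector and element list.
#' @export
simulate_spectra <- function(truth, scan = truth$scan, det = detector_model(),
                             catalog = line_catalog(), seed = 1, noise = TRUE) {
  elements <- names(truth$maps)
  assert_excitable(det, elements, catalog)
  sens <- detector_sensitivity(det, elements)
  D <- response_design(det, elements, catalog)    # bins x elements
  amp <- vapply(elements, function(e) {
    v <- truth$maps[[e]]$values
    if (any(v < 0, na.rm = TRUE)) stop("negative concentration in truth map ", e)
    as.vector(v) * sens[[e]] * scan$dwell_ms
  }, numeric(length(truth$maps[[1]]$values)))    # npx x elements
  lam <- amp %*% t(D)
  lam <- sweep(lam, 2, continuum_counts(det, scan$dwell_ms), "+")
  counts <- if (noise) {
    withr::with_seed(as.integer(seed),
                     matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam)))
  } else lam
  structure(list(counts = counts,
                 field_shape = dim(truth$maps[[1]]$values),
                 energy_kev = det$energy_kev,
                 scan = scan, det = det, elements = elements,
                 seed = seed, noise = noise),
            class = "spectrum_cube")
}

#' @export
print.spectrum_cube <- function(x, ...) {
  cat(sprintf("<spectrum_cube> %d x %d px, %d bins, elements: %s\n",
              x$field_shape[1], x$field_shape[2], length(x$energy_kev),
              paste(x$elements, collapse = ", ")))
  invisible(x)
}

#' Single spectrum container
#'
#' @param energy_kev Bin centres.
#' @param counts Nonnegative counts per bin.
#' @param live_time_ms Acquisition live time.
#' @return Object of class `xrf_spectrum`.
#' @export
xrf_spectrum <- function(energy_kev, counts, live_time_ms) {
  stopifnot(length(energy_kev) == length(counts), all(counts >= 0),
            live_time_ms > 0)
  structure(list(energy_kev = energy_kev, counts = counts,
                 live_time_ms = live_time_ms),
            class = "xrf_spectrum")
}

#' Simulate the measured spectrum of a thin-film calibration standard
#'
#' A calibration standard carries certified elemental areal densities; its
#' measured spectrum under the same detector model provides the peak-area to
#' concentration ratios used for quantification.
#'
#' @param standard Tibble/data.frame with columns `element`,
#'   `density_ug_cm2`.
#' @param det A `detector_model`.
#' @param catalog Line catalog.
#' @param live_time_ms Acquisition live time in ms.
#' @param seed RNG seed; `NULL` for a noiseless spectrum.
#' @return An `xrf_spectrum`.
#' @export
simulate_standard <- function(standard, det = detector_model(),
                              catalog = line_catalog(),
                              live_time_ms = 10000, seed = NULL) {
  stopifnot(all(c("element", "density_ug_cm2") %in% names(standard)),
            all(standard$density_ug_cm2 > 0))
  sens <- detector_sensitivity(det, standard$element)
  D <- response_design(det, standard$element, catalog)
  lam <- as.vector(D %*% (standard$density_ug_cm2 * sens * live_time_ms)) +
    continuum_counts(det, live_time_ms)
  counts <- if (is.null(seed)) lam else
    withr::with_seed(as.integer(seed), stats::rpois(length(lam), lam))
  xrf_spectrum(det$energy_kev, counts, live_time_ms)
}

#' Write a spectrum cube to HDF5
#'
#' Layout: `/spectra` as rows x cols x bins, `/energy_keV`, with scan
#' attributes at the root.
#'
#' @param cube A `spectrum_cube`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  arr <- array(cube$counts, dim = c(cube$field_shape, length(cube$energy_kev)))
  rhdf5::h5write(arr, path, "spectra")
  rhdf5::h5write(cube$energy_kev, path, "energy_keV")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(cube$scan$step_nm, fid, "step_nm")
  rhdf5::h5writeAttribute(cube$scan$dwell_ms, fid, "dwell_ms")
  rhdf5::h5writeAttribute(as.integer(cube$seed), fid, "seed")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}
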
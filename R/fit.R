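#' Ratio-constrained EMG peak fitting of a background-stripped spectrum
#'
#' Fits one exponentially modified Gaussian per element K-alpha line, each
#' with a K-beta companion locked to the catalog area ratio. The Gaussian
#' width and tail constant are detector properties shared by all peaks in a
#' spectrum; with the shape fixed the model is linear in the per-element
#' amplitudes, which are solved by least squares (negative solutions are
#' clamped to zero). When `fit_shape = TRUE` the shared (sigma, tau) pair is
#' profiled by Nelder-Mead on the residual sum of squares.
#'
#' @param spec An `xrf_spectrum` with the background already subtracted.
#' @param elements Elements to fit; all K-alpha lines must lie below the
#'   incident energy.
#' @param det A `detector_model` (shape starting values and energy axis).
#' @param catalog Line catalog.
#' @param fit_shape Profile (sigma, tau) or keep the detector defaults.
#' @return Object of class `peak_fit`: a tibble `areas` with columns
#'   `element`, `ka_area`, `kb_area`, `converged`; fitted `sigma`, `tau`
#'   (keV); `residual_rms`; and the fitted model curve.
#' @export
fit_element_peaks <- function(spec, elements, det = detector_model(),
                              catalog = line_catalog(), fit_shape = TRUE) {
  stopifnot(inherits(spec, "xrf_spectrum"))
  assert_excitable(det, elements, catalog)
  y <- spec$counts
  solve_amp <- function(sigma, tau) {
    D <- response_design(det, elements, catalog, sigma, tau)
    coef <- tryCatch(qr.coef(qr(D), y), error = function(e) rep(NA_real_, ncol(D)))
    list(coef = coef, D = D)
  }
  rss <- function(par) {
    s <- solve_amp(exp(par[1]), exp(par[2]))
    if (anyNA(s$coef)) return(sum(y^2))
    sum((y - s$D %*% s$coef)^2)
  }
  sigma <- det$resolution_ev / 1000
  tau <- det$tail_tau_ev / 1000
  conv_shape <- TRUE
  if (fit_shape && sum(y) > 0) {
    opt <- stats::optim(log(c(sigma, tau)), rss, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-8))
    sigma <- exp(opt$par[1]); tau <- exp(opt$par[2])
    conv_shape <- opt$convergence == 0
  }
  s <- solve_amp(sigma, tau)
  coef <- s$coef
  converged <- is.finite(coef) & conv_shape
  areas <- unname(ifelse(converged, pmax(coef, 0), NA_real_))
  cat_rows <- catalog[match(elements, catalog$element), ]
  fitted <- if (anyNA(coef)) rep(NA_real_, length(y)) else as.vector(s$D %*% coef)
  structure(list(
    areas = tibble::tibble(element = elements,
                           ka_area = areas,
                           kb_area = areas * cat_rows$kb_ka_ratio,
                           converged = unname(converged)),
    sigma = sigma, tau = tau,
    residual_rms = if (anyNA(fitted)) NA_real_ else sqrt(mean((y - fitted)^2)),
    fitted = fitted, energy_kev = spec$energy_kev
  ), class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit> sigma %.1f eV, tau %.1f eV, residual RMS %.3g\n",
              x$sigma * 1000, x$tau * 1000, x$residual_rms))
  print(x$areas)
  invisible(x)
}

#' Quantify a spectrum cube into elemental concentration maps
#'
#' The per-pixel quantification chain: SNIP background stripping of every
#' pixel spectrum, a shared line-shape (sigma, tau) profiled once on the
#' field-mean spectrum, per-pixel element amplitudes by linear least squares
#' against the ratio-constrained EMG design, and conversion of fitted
#' K-alpha areas to areal concentrations through the sensitivity table:
#' `concentration = area / (sensitivity x dwell)`.
#'
#' @param cube A `spectrum_cube`.
#' @param sens Sensitivity table from [calibrate_sensitivities()] (or a
#'   named numeric vector of area per ug/cm^2 per ms).
#' @param elements Elements to quantify (default: those in the table).
#' @param catalog Line catalog.
#' @param n_iter,max_window_bins SNIP parameters.
#' @param fit_shape Profile the line shape on the mean spectrum.
#' @return Named list of `element_map`s (attribute `fit`: sigma, tau,
#'   n_failed — pixels whose fit failed are NA and counted).
#' @export
quantify_map <- function(cube, sens, elements = NULL,
                         catalog = line_catalog(),
                         n_iter = 24, max_window_bins = 20,
                         fit_shape = TRUE) {
  stopifnot(inherits(cube, "spectrum_cube"))
  sv <- sensitivity_vector(sens)
  if (is.null(elements)) elements <- names(sv)
  if (!all(elements %in% names(sv))) {
    stop("no sensitivity for: ",
         paste(setdiff(elements, names(sv)), collapse = ", "))
  }
  det <- cube$det
  M <- cube$counts
  # shared line shape from the field-mean spectrum (high SNR: strip the mean,
  # never the mean of per-pixel-stripped residuals, which accumulates the
  # clipping bias of noisy spectra into a pedestal around the peaks)
  mean_raw <- colMeans(M)
  shape <- list(sigma = det$resolution_ev / 1000, tau = det$tail_tau_ev / 1000)
  if (fit_shape && sum(mean_raw) > 0) {
    # profile the shared (sigma, tau) on the raw field-mean spectrum with
    # smooth baseline columns in the model; fitting the raw mean avoids the
    # small peak distortion any pre-stripping would imprint on the width
    Blm <- cbind(1, exp(-cube$energy_kev / 3),
                 exp(-cube$energy_kev / 1))
    rss <- function(par) {
      Dm <- cbind(response_design(det, elements, catalog,
                                  exp(par[1]), exp(par[2])), Blm)
      cf <- tryCatch(qr.coef(qr(Dm), mean_raw), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) return(sum(mean_raw^2))
      sum((mean_raw - Dm %*% cf)^2)
    }
    opt <- stats::optim(log(c(shape$sigma, shape$tau)), rss,
                        method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    shape <- list(sigma = exp(opt$par[1]), tau = exp(opt$par[2]))
  }
  D <- response_design(det, elements, catalog, shape$sigma, shape$tau)
  XtXinv <- solve(crossprod(D))
  # Min-clipping a noisy spectrum leaves a small positive residual floor
  # that would otherwise leak into every peak area. Estimate it per pixel
  # from the off-peak bins only (smooth baseline shapes fitted where no
  # catalog line lives, so the correction cannot absorb peak counts) and
  # subtract its prediction across the full axis.
  cat_rows <- catalog[match(elements, catalog$element), ]
  lines <- c(cat_rows$ka_kev, cat_rows$kb_kev)
  halfwidth <- 4 * shape$sigma + 4 * shape$tau
  off_peak <- !Reduce(`|`, lapply(lines, function(l) {
    abs(cube$energy_kev - l) < halfwidth
  }))
  # exclude the low-energy region: the stripping operator's edge clamp
  # distorts the first bins, and no catalog K line lives below Al (1.49 keV)
  off_peak <- off_peak & cube$energy_kev > 1.2
  Bl <- cbind(1, exp(-cube$energy_kev / 3))
  Blo <- Bl[off_peak, ]
  BlP <- Blo %*% solve(crossprod(Blo))
  solve_pass <- function(B) {
    Y <- M - B
    # the residual floor is a property of the common continuum, so it is
    # estimated once from the field-mean residual; a per-pixel fit would
    # inject shared noise into every element's amplitude at that pixel,
    # correlating the recovered maps with each other
    floor_coef <- colMeans(Y)[off_peak] %*% BlP
    Y <- sweep(Y, 2, as.vector(Bl %*% t(floor_coef)), "-")
    Y %*% D %*% XtXinv
  }
  # Bootstrap the background by peak stripping, then refine: remove the
  # fitted peaks and take the smoothed peak-free residual as the new
  # background estimate. Once the peaks are out, the residual IS the
  # continuum (plus noise), so smoothing estimates it without the downward
  # drift min-clipping shows on low-count spectra; the loop converges
  # geometrically because smoothing attenuates any leftover peak-shaped
  # error before it can re-enter the amplitudes.
  coef <- solve_pass(snip_matrix(M, n_iter, max_window_bins))
  for (pass in 1:6) {
    peaks <- pmax(coef, 0) %*% t(D)
    coef <- solve_pass(smooth_bins(M - peaks, 31))
  }
  bad <- !is.finite(coef)
  n_failed <- sum(rowSums(bad) > 0)
  coef[bad] <- NA
  coef <- pmax(coef, 0)
  maps <- lapply(stats::setNames(seq_along(elements), elements), function(j) {
    conc <- coef[, j] / (sv[[elements[j]]] * cube$scan$dwell_ms)
    element_map(elements[j],
                matrix(conc, cube$field_shape[1], cube$field_shape[2]),
                cube$scan$step_nm)
  })
  attr(maps, "fit") <- list(sigma = shape$sigma, tau = shape$tau,
                            n_failed = n_failed)
  maps
}
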
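#' Parallel-beam projector configuration
#'
#' Angular grid and detector geometry for fluorescence tomography. The
#' default mirrors the acquisition this pipeline models: 51 projections
#' equally spaced over -82 to 70 degrees inclusive (3.04 degree spacing) —
#' an angular range short of 180 degrees, i.e. a missing wedge.
#'
#' @param angles_deg Strictly increasing projection angles in degrees,
#'   spanning less than 180.
#' @param n Slice side length in pixels (slices are square).
#' @param step_nm Pixel pitch (carried as metadata).
#' @param n_det Number of detector bins; default covers the slice diagonal.
#' @return Object of class `projector_config` with a precomputed sparse
#'   system matrix `A` ((n_angles x n_det) rows by n^2 columns).
#' @export
projector_config <- function(angles_deg = seq(-82, 70, length.out = 51),
                             n = 64, step_nm = 100, n_det = NULL) {
  stopifnot(all(diff(angles_deg) > 0), n >= 2)
  if (max(angles_deg) - min(angles_deg) >= 180) {
    stop("angular range must span less than 180 degrees")
  }
  if (is.null(n_det)) n_det <- 2L * ceiling(n * sqrt(2) / 2) + 3L
  A <- build_projector(n, angles_deg, n_det)
  structure(list(angles_deg = angles_deg, n = as.integer(n),
                 n_det = as.integer(n_det), step_nm = step_nm, A = A),
            class = "projector_config")
}

#' @export
print.projector_config <- function(x, ...) {
  cat(sprintf("<projector_config> %d angles in [%g, %g] deg, %d x %d slice, %d detector bins\n",
              length(x$angles_deg), min(x$angles_deg), max(x$angles_deg),
              x$n, x$n, x$n_det))
  invisible(x)
}

#' Sparse pixel-driven parallel-beam system matrix
#'
#' Each pixel centre projects onto the detector axis at
#' `t = x cos(theta) + y sin(theta)` and its value is split linearly
#' between the two adjacent detector bins. Forward projection and
#' backprojection share this one matrix (A and t(A)), so the adjoint
#' pairing SIRT depends on holds to machine precision by construction.
#'
#' @noRd
build_projector <- function(n, angles_deg, n_det) {
  c0 <- (n + 1) / 2
  det_c <- (n_det + 1) / 2
  # pixel centre coordinates; column-major order matching as.vector(slice)
  rows <- rep(seq_len(n), times = n)
  cols <- rep(seq_len(n), each = n)
  x <- cols - c0
  y <- c0 - rows
  trip_i <- vector("list", length(angles_deg))
  trip_j <- vector("list", length(angles_deg))
  trip_x <- vector("list", length(angles_deg))
  for (k in seq_along(angles_deg)) {
    th <- angles_deg[k] * pi / 180
    t <- x * cos(th) + y * sin(th) + det_c
    lo <- floor(t)
    w_hi <- t - lo
    offset <- (k - 1L) * n_det
    ok_lo <- lo >= 1 & lo <= n_det
    ok_hi <- (lo + 1) >= 1 & (lo + 1) <= n_det
    trip_i[[k]] <- c(offset + lo[ok_lo], offset + lo[ok_hi] + 1L)
    trip_j[[k]] <- c(which(ok_lo), which(ok_hi))
    trip_x[[k]] <- c((1 - w_hi)[ok_lo], w_hi[ok_hi])
  }
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x),
                       dims = c(length(angles_deg) * n_det, n * n))
}

#' Forward-project a slice into a sinogram
#'
#' @param slice Square numeric matrix (n x n concentrations).
#' @param config A `projector_config` with matching `n`.
#' @param element Optional element tag.
#' @return Object of class `sinogram_set`: `projections` is an
#'   (n_angles x n_det) matrix of line integrals.
#' @export
forward_project <- function(slice, config, element = NA_character_) {
  stopifnot(inherits(config, "projector_config"),
            nrow(slice) == config$n, ncol(slice) == config$n)
  p <- as.vector(config$A %*% as.vector(slice))
  structure(list(projections = matrix(p, length(config$angles_deg),
                                      config$n_det, byrow = TRUE),
                 element = element, config = config),
            class = "sinogram_set")
}

#' @export
print.sinogram_set <- function(x, ...) {
  cat(sprintf("<sinogram_set>%s %d angles x %d bins\n",
              if (is.na(x$element)) "" else paste0(" ", x$element),
              nrow(x$projections), ncol(x$projections)))
  invisible(x)
}

#' SIRT reconstruction of one slice
#'
#' Simultaneous Iterative Reconstruction Technique: the weighted Landweber
#' iteration
#'
#'   x <- x + C t(A) R (b - A x)
#'
#' with R and C the inverse row and column sums of the system matrix (rows
#' or columns with zero weight are masked out, never divided by). An
#' optional nonnegativity clamp is applied after each update — areal
#' concentrations cannot be negative. The weighted residual norm is
#' recorded per iteration and is non-increasing on consistent data.
#'
#' @param sino A `sinogram_set` (or plain angles x bins matrix).
#' @param config A `projector_config`; defaults to the sinogram's own.
#' @param n_iter Number of iterations.
#' @param nonneg Clamp negative pixels to zero each iteration.
#' @return Object of class `recon_slice`: `values` (n x n), `n_iter`,
#'   `residuals` (Euclidean norm of b - A x after each iteration).
#' @export
sirt_reconstruct <- function(sino, config = NULL, n_iter = 100, nonneg = TRUE) {
  if (inherits(sino, "sinogram_set")) {
    if (is.null(config)) config <- sino$config
    b <- as.vector(t(sino$projections))
  } else {
    stopifnot(!is.null(config))
    b <- as.vector(t(sino))
  }
  stopifnot(all(is.finite(b)))
  A <- config$A
  rs <- Matrix::rowSums(A)
  cs <- Matrix::colSums(A)
  R <- ifelse(rs > 0, 1 / rs, 0)
  C <- ifelse(cs > 0, 1 / cs, 0)
  x <- numeric(config$n^2)
  res <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    r <- b - as.vector(A %*% x)
    x <- x + C * as.vector(Matrix::crossprod(A, R * r))
    if (nonneg) x[x < 0] <- 0
    res[it] <- sqrt(sum((b - as.vector(A %*% x))^2))
  }
  structure(list(values = matrix(x, config$n, config$n),
                 n_iter = n_iter, residuals = res, nonneg = nonneg,
                 config = config),
            class = "recon_slice")
}

#' @export
print.recon_slice <- function(x, ...) {
  cat(sprintf("<recon_slice> %d x %d, %d iterations, final residual %.4g\n",
              nrow(x$values), ncol(x$values), x$n_iter,
              x$residuals[x$n_iter]))
  invisible(x)
}

#' Reconstruct a volume from per-row sinograms
#'
#' Raster-scanned fluorescence tomography acquires one sinogram per scan
#' row; each is reconstructed independently and the slices stacked.
#'
#' @param sinos List of `sinogram_set`s (or matrices) sharing one geometry.
#' @param config A `projector_config`; defaults to the first sinogram's.
#' @param n_iter,nonneg Passed to [sirt_reconstruct()].
#' @return Object of class `recon_volume`: `values` is an n x n x n_slices
#'   array plus the per-slice residual histories.
#' @export
reconstruct_volume <- function(sinos, config = NULL, n_iter = 100,
                               nonneg = TRUE) {
  stopifnot(length(sinos) >= 1)
  if (is.null(config) && inherits(sinos[[1]], "sinogram_set")) {
    config <- sinos[[1]]$config
  }
  for (s in sinos) {
    if (inherits(s, "sinogram_set") &&
        !isTRUE(all.equal(s$config$angles_deg, config$angles_deg))) {
      stop("inconsistent angle sets across sinograms")
    }
  }
  slices <- lapply(sinos, sirt_reconstruct, config = config,
                   n_iter = n_iter, nonneg = nonneg)
  structure(list(values = array(unlist(lapply(slices, function(s) s$values)),
                                dim = c(config$n, config$n, length(slices))),
                 residuals = lapply(slices, function(s) s$residuals),
                 n_iter = n_iter, config = config),
            class = "recon_volume")
}

#' Radial intensity profile of a slice about its centre
#'
#' Mean value in 1-pixel-wide radial annuli; used to compare shell-like
#' (peripheral) against core-like element arrangements in reconstructions.
#'
#' @param slice Numeric matrix (or `recon_slice`).
#' @return Tibble with `radius_px` (annulus midpoint) and `mean_value`.
#' @export
radial_profile <- function(slice) {
  v <- if (inherits(slice, "recon_slice")) slice$values else slice
  c0 <- (dim(v) + 1) / 2
  rr <- sqrt((row(v) - c0[1])^2 + (col(v) - c0[2])^2)
  bin <- floor(rr)
  prof <- tapply(as.vector(v), as.vector(bin), mean)
  tibble::tibble(radius_px = as.numeric(names(prof)) + 0.5,
                 mean_value = as.numeric(prof))
}
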
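#' Elemental areal-concentration map
#'
#' The native product of quantitative 2D XRF imaging: a rows x cols grid of
#' areal concentrations in ug/cm^2 for one element, together with the pixel
#' pitch. Missing pixels (failed per-pixel fits) are `NA`.
#'
#' @param element Element symbol.
#' @param values Numeric matrix, ug/cm^2; `NA` marks missing pixels; finite
#'   values must be >= 0.
#' @param step_nm Pixel pitch in nm.
#' @return An object of class `element_map`.
#' @export
element_map <- function(element, values, step_nm) {
  stopifnot(is.character(element), length(element) == 1,
            is.matrix(values), is.numeric(step_nm), step_nm > 0)
  if (any(values < 0, na.rm = TRUE)) {
    stop("element_map values must be nonnegative (or NA)")
  }
  structure(list(element = element, values = values, step_nm = step_nm),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<element_map> %s: %d x %d px @ %g nm; range [%.4g, %.4g] ug/cm^2, %d missing\n",
    x$element, nrow(x$values), ncol(x$values), x$step_nm,
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
    sum(!is.finite(x$values))))
  invisible(x)
}

#' @export
dim.element_map <- function(x) dim(x$values)

#' Write a set of element maps to an HDF5 bundle
#'
#' Layout: one dataset per element under `/maps/<El>` (missing pixels stored
#' as NaN), with `step_nm` and the element list stored as root attributes.
#'
#' @param maps Named list of `element_map` objects on a common grid.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(maps, path) {
  stopifnot(length(maps) > 0)
  shapes <- vapply(maps, function(m) dim(m$values), integer(2))
  if (!all(shapes == shapes[, 1])) stop("maps differ in shape")
  steps <- vapply(maps, function(m) m$step_nm, numeric(1))
  if (length(unique(steps)) != 1) stop("maps differ in step_nm")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "maps")
  for (m in maps) {
    v <- m$values
    v[is.na(v)] <- NaN
    rhdf5::h5write(v, path, paste0("maps/", m$element))
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(steps[[1]], fid, "step_nm")
  rhdf5::h5writeAttribute(vapply(maps, function(m) m$element, character(1)),
                          fid, "elements")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an element-map bundle written by [write_bundle()]
#'
#' @param path HDF5 file path.
#' @return Named list of `element_map` objects.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  if (is.null(attrs$step_nm)) {
    rhdf5::h5closeAll()
    stop("bundle is missing the required step_nm attribute: ", path)
  }
  step_nm <- as.numeric(attrs$step_nm)
  contents <- rhdf5::h5ls(path)
  els <- contents$name[contents$group == "/maps"]
  maps <- lapply(els, function(el) {
    v <- rhdf5::h5read(path, paste0("maps/", el))
    v[is.nan(v)] <- NA
    element_map(el, v, step_nm)
  })
  rhdf5::h5closeAll()
  names(maps) <- els
  maps[order(match(els, line_catalog()$element))]
}

#' Percentile-clipped display normalization
#'
#' Rescales a map to `[0, 1]` for display: the stated percentile of the
#' finite pixel values maps to 1 and higher values saturate, which enhances
#' contrast against a handful of bright outlier pixels. The convention is a
#' 98.0 percentile for plain display and 99.9 for cluster-emphasis images.
#' Clipping is display-only; quantification always operates on raw values.
#'
#' @param map An `element_map` (or plain numeric matrix).
#' @param clip_percentile Percentile in (0, 100]; values above it saturate.
#' @return Numeric matrix in `[0, 1]` (NA preserved).
#' @export
percentile_clip <- function(map, clip_percentile = 98) {
  stopifnot(clip_percentile > 0, clip_percentile <= 100)
  v <- if (inherits(map, "element_map")) map$values else map
  fin <- v[is.finite(v)]
  if (length(fin) == 0) stop("percentile_clip: map has no finite pixels")
  if (max(fin) == min(fin)) {
    out <- v
    out[is.finite(out)] <- 1
    return(out)
  }
  p <- stats::quantile(fin, clip_percentile / 100, names = FALSE, type = 7)
  if (p <= 0) p <- max(fin)  # degenerate: mass in upper tail only
  pmin(v, p) / p
}

#' Write a display image (16-bit PNG or TIFF)
#'
#' Saves a percentile-clipped map (or an RGB overlay array from
#' [export_overlay()]) as a 16-bit image. Only display products are ever
#' clipped; raw concentration maps on disk (see [write_bundle()]) are not.
#'
#' @param img An `element_map`, a numeric matrix in `[0, 1]`, or a
#'   rows x cols x 3 array in `[0, 1]`.
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param clip_percentile Applied when `img` is an `element_map`.
#' @return `path`, invisibly.
#' @export
write_display <- function(img, path, clip_percentile = 98) {
  if (inherits(img, "element_map")) img <- percentile_clip(img, clip_percentile)
  img[is.na(img)] <- 0
  if (any(img < 0 | img > 1)) stop("display image values must lie in [0, 1]")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package required")
    png::writePNG(img, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package required")
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else {
    stop("unsupported display format: .", ext)
  }
  invisible(path)
}

#' Three-element RGB overlay
#'
#' Stacks three display-normalized maps into an RGB array, the standard way
#' co-localization of elemental clusters is visualized. Each channel is
#' percentile-clipped independently.
#'
#' @param maps List of exactly three `element_map`s (R, G, B) on one grid.
#' @param clip_percentile Passed to [percentile_clip()].
#' @return rows x cols x 3 numeric array in `[0, 1]`.
#' @export
export_overlay <- function(maps, clip_percentile = 98) {
  stopifnot(length(maps) == 3)
  dims <- lapply(maps, function(m) dim(if (inherits(m, "element_map")) m$values else m))
  if (!identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("overlay channels differ in shape")
  }
  ch <- lapply(maps, function(m) {
    v <- if (inherits(m, "element_map")) m$values else m
    if (all(v == 0, na.rm = TRUE)) v else percentile_clip(m, clip_percentile)
  })
  array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dims[[1]], 3))
}
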
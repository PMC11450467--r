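#' Physical cluster area
#'
#' Pixel count times pixel size; at a 100 nm pitch one pixel is 0.01 um^2.
#'
#' @param roi An ROI row from [label_rois()], or a pixel count.
#' @param scan A `scan_config` (or a number taken as step_nm).
#' @return Area in um^2.
#' @examples
#' cluster_area(1, scan_config(100, 200, c(1, 1)))  # 0.01
#' @export
cluster_area <- function(roi, scan) {
  n <- if (is.numeric(roi)) roi else roi$n_pixels
  step <- if (inherits(scan, "scan_config")) scan$step_nm else scan
  n * (step / 1000)^2
}

#' Equivalent-circle diameter of an area
#'
#' @param area_um2 Area in um^2.
#' @return Diameter `2 * sqrt(area / pi)` in um.
#' @export
equiv_diameter <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Background-subtracted mean concentration of a region
#'
#' Averages a map over a region after subtracting the median of a
#' background (blank) region — by convention the off-cell substrate/ice
#' pixels. An empty background mask means no blank is available: the raw
#' mean is returned and flagged.
#'
#' @param map An `element_map`.
#' @param region_mask Logical mask of the region (nonempty).
#' @param background_mask Logical mask of blank pixels.
#' @return Tibble with `element`, `mean` (clamped at 0), `sd`, `n_pixels`,
#'   `background` (the subtracted value).
#' @export
region_mean_concentration <- function(map, region_mask, background_mask) {
  v <- map$values
  stopifnot(all(dim(v) == dim(region_mask)))
  reg <- v[region_mask]
  reg <- reg[is.finite(reg)]
  if (length(reg) == 0) stop("region_mean_concentration: empty region")
  bgv <- v[background_mask]
  bgv <- bgv[is.finite(bgv)]
  bg <- if (length(bgv) == 0) 0 else stats::median(bgv)
  tibble::tibble(element = map$element,
                 mean = max(mean(reg) - bg, 0),
                 sd = stats::sd(reg),
                 n_pixels = length(reg),
                 background = bg)
}

#' Pearson correlation of two element maps over an ROI bounding box
#'
#' Computed over all pixels of the ROI's bounding box (not just the
#' in-cluster pixels) so that anti-colocalization — one element high where
#' the other is low — remains detectable.
#'
#' @param map_a,map_b `element_map`s on a common grid.
#' @param roi An ROI row from [label_rois()].
#' @return Tibble with `element_a`, `element_b`, `label`, `pearson_r`,
#'   `n_pixels`, `defined` (FALSE when either map has zero variance in the
#'   box).
#' @export
roi_pearson <- function(map_a, map_b, roi) {
  va <- map_a$values; vb <- map_b$values
  stopifnot(all(dim(va) == dim(vb)))
  rows <- roi$rmin:(roi$rmax - 1L)
  cols <- roi$cmin:(roi$cmax - 1L)
  a <- as.vector(va[rows, cols]); b <- as.vector(vb[rows, cols])
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  defined <- length(a) >= 2 && stats::sd(a) > 0 && stats::sd(b) > 0
  tibble::tibble(element_a = map_a$element, element_b = map_b$element,
                 label = roi$label,
                 pearson_r = if (defined) stats::cor(a, b) else NA_real_,
                 n_pixels = length(a), defined = defined)
}

#' Relative overlap of two pixel sets
#'
#' Both normalizations of the intersection area are reported: the overlap
#' coefficient `|A n B| / min(|A|, |B|)` (reads through size mismatches —
#' a small cluster fully inside a large one scores 1) and the Jaccard index
#' `|A n B| / |A u B|`.
#'
#' @param roi_a,roi_b ROI rows from [label_rois()] (or (row, col) pixel
#'   matrices) on the same grid.
#' @return Tibble with `overlap_min`, `jaccard`, `n_a`, `n_b`,
#'   `n_intersect`. Symmetric in its arguments.
#' @export
overlap_fraction <- function(roi_a, roi_b) {
  pa <- roi_pixels(roi_a); pb <- roi_pixels(roi_b)
  ka <- paste(pa[, 1], pa[, 2]); kb <- paste(pb[, 1], pb[, 2])
  ni <- length(intersect(ka, kb))
  tibble::tibble(
    overlap_min = if (min(length(ka), length(kb)) == 0) 0
                  else ni / min(length(ka), length(kb)),
    jaccard = if (length(union(ka, kb)) == 0) 0
              else ni / length(union(ka, kb)),
    n_a = length(ka), n_b = length(kb), n_intersect = ni)
}

roi_pixels <- function(x) {
  if (is.matrix(x)) x
  else if (is.data.frame(x) && "pixels" %in% names(x)) x$pixels[[1]]
  else stop("expected an ROI row or a pixel matrix")
}

#' Classify a cluster into a colocalization family
#'
#' Applies the colocalization taxonomy of elemental clusters: a P/K core
#' exists where a P cluster and a K cluster mutually overlap (overlap
#' coefficient >= `min_overlap`); the core is tagged `PK_Ca` or `PK_Fe` by
#' which of Ca / Fe overlaps it (Ca wins ties, matching the peripheral
#' Ca-wrapped morphology), and clusters without a P/K core are `Ca_only` /
#' `Fe_only` or `unclassified`.
#'
#' @param pixels (row, col) matrix of the cluster's pixels.
#' @param masks Named list of logical cluster masks for (at least) P, K,
#'   Ca, Fe on the cluster's grid.
#' @param min_overlap Overlap-coefficient threshold.
#' @return A single family string: `PK_Ca`, `PK_Fe`, `Ca_only`, `Fe_only`
#'   or `unclassified`.
#' @export
classify_cluster <- function(pixels, masks, min_overlap = 0.5) {
  stopifnot(all(c("P", "K", "Ca", "Fe") %in% names(masks)))
  comp <- function(el) best_component(pixels, masks[[el]])
  pc <- comp("P"); kc <- comp("K")
  if (!is.null(pc) && !is.null(kc) &&
      overlap_fraction(pc, kc)$overlap_min >= min_overlap &&
      overlap_fraction(pixels, pc)$overlap_min >= min_overlap &&
      overlap_fraction(pixels, kc)$overlap_min >= min_overlap) {
    core <- intersect_pixels(pc, kc)
    cac <- best_component(core, masks[["Ca"]])
    if (!is.null(cac) && overlap_fraction(core, cac)$overlap_min >= min_overlap) {
      return("PK_Ca")
    }
    fec <- best_component(core, masks[["Fe"]])
    if (!is.null(fec) && overlap_fraction(core, fec)$overlap_min >= min_overlap) {
      return("PK_Fe")
    }
    return("unclassified")
  }
  for (el in c("Ca", "Fe")) {
    cc <- comp(el)
    if (!is.null(cc) && overlap_fraction(pixels, cc)$overlap_min >= min_overlap) {
      return(if (el == "Ca") "Ca_only" else "Fe_only")
    }
  }
  "unclassified"
}

#' Connected component of a mask with the largest intersection with pixels
#' @noRd
best_component <- function(pixels, mask) {
  if (!any(mask)) return(NULL)
  lab <- label_components(mask, 8)
  hit <- lab[pixels]
  hit <- hit[hit > 0]
  if (length(hit) == 0) return(NULL)
  l <- as.integer(names(which.max(table(hit))))
  px <- which(lab == l, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  px
}

intersect_pixels <- function(pa, pb) {
  ka <- paste(pa[, 1], pa[, 2])
  kb <- paste(pb[, 1], pb[, 2])
  pa[ka %in% kb, , drop = FALSE]
}
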
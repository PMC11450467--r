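#' One-dimensional k-means thresholding
#'
#' Partitions a vector of intensities into `k` classes minimizing the
#' within-class sum of squares. For `k = 2` (the cluster / non-cluster
#' split used throughout) the solution is computed exactly: in one
#' dimension the optimal partition is a split of the sorted values, found
#' in a single prefix-sum sweep over all n-1 ordered splits. This is the
#' fixed point Lloyd's algorithm aims for, obtained deterministically and
#' without initialization sensitivity (on low-contrast maps Lloyd can
#' stall inside the dominant intensity mode). For `k > 2` Lloyd iterations
#' from evenly spaced quantile seeds are used.
#'
#' The returned threshold is the midpoint of the two (top two, for
#' `k > 2`) sorted centroids — the intensity separating cluster from
#' non-cluster pixels in an elemental map.
#'
#' @param values Numeric vector (non-finite entries dropped).
#' @param k Number of classes (default 2: cluster vs non-cluster).
#' @param max_iter Iteration cap for the `k > 2` Lloyd path.
#' @return List with `centroids` (sorted), `threshold` (midpoint of the top
#'   two centroids), and `sizes`.
#' @examples
#' kmeans_1d(c(0, 0, 0, 10, 10, 10))$threshold  # 5
#' @export
kmeans_1d <- function(values, k = 2, max_iter = 100) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < k) {
    stop("kmeans_1d: degenerate input, fewer than k distinct values")
  }
  if (k == 2) {
    s <- sort(v)
    n <- length(s)
    cs <- cumsum(s); cs2 <- cumsum(s^2)
    i <- seq_len(n - 1)
    # within-class SSE of {s[1..i]} and {s[(i+1)..n]} via prefix sums
    sse_lo <- cs2[i] - cs[i]^2 / i
    sse_hi <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
    cut <- which.min(sse_lo + sse_hi)
    cent <- c(cs[cut] / cut, (cs[n] - cs[cut]) / (n - cut))
    return(list(centroids = cent, threshold = mean(cent),
                sizes = c(cut, n - cut)))
  }
  cent <- unname(stats::quantile(v, seq(0.25, 0.75, length.out = k), type = 7))
  if (length(unique(cent)) < k) cent <- seq(min(v), max(v), length.out = k)
  cent <- sort(cent)
  for (it in seq_len(max_iter)) {
    bounds <- (cent[-k] + cent[-1]) / 2
    asg <- findInterval(v, bounds) + 1L   # ties at a midpoint go upward
    newc <- sort(vapply(seq_len(k), function(j) {
      if (any(asg == j)) mean(v[asg == j]) else cent[j]
    }, numeric(1)))
    if (identical(newc, cent)) break
    cent <- newc
  }
  bounds <- (cent[-k] + cent[-1]) / 2
  asg <- findInterval(v, bounds) + 1L
  list(centroids = cent, threshold = mean(cent[c(k - 1, k)]),
       sizes = tabulate(asg, k))
}

#' Delineate the cytoplasm from a potassium map
#'
#' K is the most abundant cytosolic micronutrient, so its map outlines the
#' cells: pixels above the k-means threshold of the full field form the
#' foreground, which is then cleaned by a morphological closing of radius 1
#' and removal of connected components smaller than `min_component_px`.
#' The mask is invariant to positive rescaling of the map.
#'
#' @param k_map `element_map` of K (any element works in principle).
#' @param min_component_px Minimum component size kept, in pixels.
#' @return Logical matrix with attributes `element` and `threshold`
#'   (class `cytoplasm_mask`). Empty foreground gives a warning and an
#'   all-FALSE mask.
#' @export
cytoplasm_mask <- function(k_map, min_component_px = 25) {
  v <- k_map$values
  if (!any(is.finite(v))) stop("cytoplasm_mask: map has no finite pixels")
  fin <- v[is.finite(v)]
  if (length(unique(fin)) < 2) {
    warning("cytoplasm_mask: map is constant; returning empty mask")
    mask <- matrix(FALSE, nrow(v), ncol(v))
    return(structure(mask, element = k_map$element, threshold = NA_real_,
                     class = c("cytoplasm_mask", class(mask))))
  }
  th <- kmeans_1d(fin)$threshold
  fg <- !is.na(v) & v > th
  fg <- EBImage::closing(fg * 1, EBImage::makeBrush(3, "disc")) > 0
  lab <- label_components(fg, connectivity = 8)
  keep <- which(tabulate(lab) >= min_component_px)
  mask <- matrix(lab %in% keep, nrow(v), ncol(v))
  if (!any(mask)) warning("cytoplasm_mask: empty foreground")
  structure(mask, element = k_map$element, threshold = th,
            class = c("cytoplasm_mask", class(mask)))
}

#' Cluster/non-cluster split of a map by k-means
#'
#' Applies [kmeans_1d()] to the in-cytoplasm intensities only; the cluster
#' class is the upper centroid. The result is always contained in the
#' cytoplasm mask.
#'
#' @param map An `element_map`.
#' @param cyto Logical cytoplasm mask (same shape).
#' @return Logical matrix (attribute `threshold`; `degenerate = TRUE` with
#'   an empty mask when the in-mask values cannot be split).
#' @export
cluster_mask_kmeans <- function(map, cyto) {
  stopifnot(all(dim(map$values) == dim(cyto)))
  if (!any(cyto)) stop("cluster_mask_kmeans: empty cytoplasm mask")
  v <- map$values
  vin <- v[cyto]
  vin <- vin[is.finite(vin)]
  if (length(unique(vin)) < 2) {
    out <- matrix(FALSE, nrow(v), ncol(v))
    return(structure(out, threshold = NA_real_, degenerate = TRUE))
  }
  th <- kmeans_1d(vin)$threshold
  out <- cyto & !is.na(v) & v > th
  structure(out, threshold = th, degenerate = FALSE)
}

#' Cluster mask by fixed concentration threshold
#'
#' The second, independent boundary method: in-cytoplasm pixels at or above
#' a fixed areal concentration.
#'
#' @param map An `element_map`.
#' @param cyto Logical cytoplasm mask.
#' @param threshold Concentration threshold in ug/cm^2 (> 0).
#' @return Logical matrix.
#' @export
cluster_mask_fixed <- function(map, cyto, threshold) {
  stopifnot(threshold > 0, all(dim(map$values) == dim(cyto)))
  cyto & !is.na(map$values) & map$values >= threshold
}

#' Default fixed threshold: cytosol mean + 3 SD
#'
#' Computes the conventional fixed threshold from the data itself: the mean
#' plus three standard deviations of the cytosolic (non-cluster, in-mask)
#' intensities, with the cluster pixels identified by k-means first.
#'
#' @param map An `element_map`.
#' @param cyto Logical cytoplasm mask.
#' @return Threshold in ug/cm^2.
#' @export
fixed_threshold_default <- function(map, cyto) {
  km <- cluster_mask_kmeans(map, cyto)
  cytosol <- map$values[cyto & !km]
  cytosol <- cytosol[is.finite(cytosol)]
  mean(cytosol) + 3 * stats::sd(cytosol)
}

#' Two-method consensus cluster boundary
#'
#' Combining the k-means and fixed-threshold boundaries reduces the
#' concentration error contributed by ambiguous cluster-edge pixels: the
#' `core` (intersection) contains pixels both methods call cluster, and the
#' `band` (symmetric difference) flags the disputed boundary.
#'
#' @param m_kmeans,m_fixed Logical masks of the same shape.
#' @return List with logical `core` and `band`.
#' @export
consensus_mask <- function(m_kmeans, m_fixed) {
  stopifnot(all(dim(m_kmeans) == dim(m_fixed)))
  list(core = m_kmeans & m_fixed, band = xor(m_kmeans, m_fixed))
}

#' Connected-component labelling (4- or 8-connectivity)
#'
#' Labels are assigned in row-major discovery order, so the numbering is
#' deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)           # 4-connected base labelling
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab == 0) return(lab)
  parent <- seq_len(nlab)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (connectivity == 8 && nlab > 1) {
    r <- nrow(lab); c <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-r, -c]), as.vector(lab[-1, -1])),   # \ diagonal
      cbind(as.vector(lab[-1, -c]), as.vector(lab[-r, -1])))   # / diagonal
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      for (k in seq_len(nrow(pairs))) {
        a <- find_root(pairs[k, 1]); b <- find_root(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find_root, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  # renumber in row-major discovery order
  idx <- which(lab > 0)
  rowmaj <- (idx - 1) %% nrow(lab) * ncol(lab) + ((idx - 1) %/% nrow(lab))
  first_seen <- tapply(rowmaj, lab[idx], min)
  new_id <- rank(first_seen)
  remap <- integer(nlab)
  remap[as.integer(names(first_seen))] <- as.integer(new_id)
  lab[idx] <- remap[lab[idx]]
  lab
}

#' Label connected ROIs in a cluster mask
#'
#' Extracts the isolated regions of interest of a binary cluster mask as a
#' tidy table: one row per connected component with its pixel set, tight
#' half-open bounding box, centroid and area in pixels.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8: diagonal-touching pixels merge).
#' @param min_size Minimum component size in pixels (smaller ROIs dropped;
#'   default 2 — sub-resolution single-pixel hits are noise at a 100 nm
#'   pitch).
#' @param element,method Optional tags carried into the table.
#' @return Tibble with columns `label`, `element`, `method`, `n_pixels`,
#'   `rmin`, `rmax`, `cmin`, `cmax` (half-open: `rmax`/`cmax` exclusive),
#'   `centroid_row`, `centroid_col` and a `pixels` list-column of
#'   (row, col) matrices.
#' @export
label_rois <- function(mask, connectivity = 8, min_size = 2,
                       element = NA_character_, method = NA_character_) {
  lab <- label_components(mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0) {
    return(tibble::tibble(label = integer(), element = character(),
                          method = character(), n_pixels = integer(),
                          rmin = integer(), rmax = integer(),
                          cmin = integer(), cmax = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          pixels = list()))
  }
  rois <- lapply(seq_len(nlab), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    if (nrow(px) < min_size) return(NULL)
    tibble::tibble(label = l, element = element, method = method,
                   n_pixels = nrow(px),
                   rmin = min(px[, 1]), rmax = max(px[, 1]) + 1L,
                   cmin = min(px[, 2]), cmax = max(px[, 2]) + 1L,
                   centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
                   pixels = list(px))
  })
  out <- dplyr::bind_rows(rois)
  if (nrow(out) > 0) out$label <- seq_len(nrow(out))
  out
}
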
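test_that("two-class intensity split matches trivial and degenerate cases", {
  km <- kmeans_1d(c(0, 0, 0, 10, 10, 10))
  expect_equal(km$centroids, c(0, 10))
  expect_equal(km$threshold, 5)
  expect_equal(km$sizes, c(3, 3))
  expect_error(kmeans_1d(c(5, 5, 5)), "degenerate")
})

test_that("two-class split equals the exhaustive-split oracle on random instances", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      n <- sample(3:12, 1)
      v <- switch(sample(3, 1),
                  runif(n, 0, 10),
                  c(rnorm(ceiling(n / 2)), rnorm(floor(n / 2), 8)),
                  round(runif(n, 0, 5)))
      if (length(unique(v)) < 2) next
      km <- kmeans_1d(v)
      got <- split_sse(v, km$sizes[1])
      expect_equal(got, best_split_sse(v), tolerance = 1e-12)
    }
  })
  # agrees with stats::kmeans at its best over many restarts
  withr::with_seed(7, {
    v <- c(rnorm(40, 1), rnorm(10, 6))
    km <- kmeans_1d(v)
    ref <- stats::kmeans(v, 2, nstart = 25)
    expect_equal(sort(km$centroids), sort(as.vector(ref$centers)),
                 tolerance = 1e-8)
  })
})

test_that("cytoplasm delineation from K recovers the true cell footprint", {
  truth <- generate_filament(filament_preset(n_veg = 4), 3)
  maps <- counts_to_maps(simulate_counts(truth, seed = 31))
  cy <- cytoplasm_mask(maps[["K"]])
  expect_gte(jaccard(cy, truth$cytoplasm_mask), 0.90)
  # invariant to positive rescaling of the map
  scaled <- element_map("K", maps[["K"]]$values * 137.5, maps[["K"]]$step_nm)
  expect_identical(as.logical(cytoplasm_mask(scaled)), as.logical(cy))
  # all-zero map: empty mask with a warning
  z <- element_map("K", matrix(0, 8, 8), 100)
  expect_warning(zm <- cytoplasm_mask(z), "constant|empty")
  expect_false(any(zm))
})

test_that("k-means cluster masks recover registered clusters and stay in the cell", {
  truth <- generate_filament(filament_preset(n_veg = 4), 3)
  maps <- counts_to_maps(simulate_counts(truth, seed = 31))
  cy <- cytoplasm_mask(maps[["K"]])
  m_ca <- cluster_mask_kmeans(maps[["Ca"]], cy)
  expect_true(all(cy[m_ca]))                          # containment contract
  reg <- truth$registry[truth$registry$element == "Ca", ]
  # per-cluster pixel recovery: Jaccard within the cluster's padded
  # bounding box, so other clusters elsewhere in the field do not count
  jac <- vapply(seq_len(nrow(reg)), function(i) {
    px <- reg$pixels[[i]]
    rows <- max(1, min(px[, 1]) - 2):min(nrow(m_ca), max(px[, 1]) + 2)
    cols <- max(1, min(px[, 2]) - 2):min(ncol(m_ca), max(px[, 2]) + 2)
    tr <- mask_from_px(px, nrow(m_ca), ncol(m_ca))
    jaccard(m_ca[rows, cols], tr[rows, cols])
  }, numeric(1))
  expect_gte(mean(jac >= 0.8), 0.9)
  # degenerate input flagged
  flat <- element_map("Ca", matrix(1, nrow(cy), ncol(cy)), 100)
  dm <- cluster_mask_kmeans(flat, cy)
  expect_true(attr(dm, "degenerate"))
  expect_false(any(dm))
})

test_that("fixed thresholding behaves at its limits and recovers clusters", {
  truth <- generate_filament(filament_preset(n_veg = 4), 3)
  maps <- counts_to_maps(simulate_counts(truth, seed = 31))
  cy <- cytoplasm_mask(maps[["K"]])
  expect_false(any(cluster_mask_fixed(maps[["Ca"]], cy,
                                      max(maps[["Ca"]]$values) + 1)))
  expect_identical(as.logical(cluster_mask_fixed(maps[["Ca"]], cy, 1e-12)),
                   as.logical(cy & maps[["Ca"]]$values > 0))
  # truth cytosol mean + 3 SD recovers the registered Ca clusters
  thr <- 0.029 + 3 * stats::sd(maps[["Ca"]]$values[cy][maps[["Ca"]]$values[cy] < 0.5])
  fx <- cluster_mask_fixed(maps[["Ca"]], cy, thr)
  reg <- truth$registry[truth$registry$element == "Ca", ]
  jac <- vapply(seq_len(nrow(reg)), function(i) {
    px <- reg$pixels[[i]]
    rows <- max(1, min(px[, 1]) - 2):min(nrow(fx), max(px[, 1]) + 2)
    cols <- max(1, min(px[, 2]) - 2):min(ncol(fx), max(px[, 2]) + 2)
    tr <- mask_from_px(px, nrow(fx), ncol(fx))
    jaccard(fx[rows, cols], tr[rows, cols])
  }, numeric(1))
  expect_gte(mean(jac >= 0.8), 0.9)
})

test_that("consensus boundaries follow set algebra", {
  a <- matrix(FALSE, 5, 5); a[2:4, 2:4] <- TRUE
  inner <- matrix(FALSE, 5, 5); inner[3, 3] <- TRUE
  same <- consensus_mask(a, a)
  expect_identical(same$core, a)
  expect_false(any(same$band))
  b <- matrix(FALSE, 5, 5); b[1, 1] <- TRUE
  disj <- consensus_mask(a, b)
  expect_false(any(disj$core))
  expect_identical(disj$band, a | b)
  nest <- consensus_mask(a, inner)
  expect_identical(nest$core, inner)
  expect_identical(nest$band, a & !inner)
})

test_that("ROI labelling respects connectivity and reports tight boxes", {
  expect_equal(nrow(label_rois(matrix(FALSE, 4, 4))), 0)
  two <- matrix(FALSE, 6, 8)
  two[1:2, 1:2] <- TRUE
  two[4:5, 5:6] <- TRUE
  rois <- label_rois(two)
  expect_equal(nrow(rois), 2)
  expect_equal(rois$n_pixels, c(4L, 4L))
  expect_equal(rois$label, 1:2)
  expect_equal(unlist(rois[1, c("rmin", "rmax", "cmin", "cmax")]),
               c(rmin = 1, rmax = 3, cmin = 1, cmax = 3))   # half-open
  # diagonal-touching pixels merge under 8-connectivity, split under 4
  diagm <- matrix(FALSE, 3, 3)
  diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE; diagm[1, 2] <- TRUE
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(max(label_components(diag2, 8)), 1)
  expect_equal(max(label_components(diag2, 4)), 2)
  expect_equal(nrow(label_rois(diagm, connectivity = 8, min_size = 2)), 1)
  # (1,2) bridges the two diagonal pixels, so 4-connectivity also merges them
  expect_equal(label_rois(diagm, connectivity = 4, min_size = 1)$n_pixels, 3L)
})

test_that("ROI areas match an independent run-length recount", {
  withr::with_seed(12, {
    for (i in 1:20) {
      m <- matrix(runif(400) < 0.3, 20, 20)
      rois <- label_rois(m, min_size = 1)
      for (j in seq_len(nrow(rois))) {
        px <- rois$pixels[[j]]
        runlen <- sum(vapply(unique(px[, "row"]), function(r) {
          cols <- sort(px[px[, "row"] == r, "col"])
          sum(diff(c(-10, cols)) >= 1)   # every pixel counted once per run
        }, numeric(1)))
        expect_equal(rois$n_pixels[j], runlen)
      }
      expect_equal(sum(rois$n_pixels), sum(m))
    }
  })
})

test_that("the segmentation pipeline is scale-equivariant", {
  truth <- generate_filament(small_preset(), 9)
  maps <- counts_to_maps(simulate_counts(truth, seed = 91))
  cy <- cytoplasm_mask(maps[["K"]])
  for (c in c(0.02, 1, 513)) {
    sc <- lapply(maps, function(m) element_map(m$element, m$values * c, m$step_nm))
    cy2 <- cytoplasm_mask(sc[["K"]])
    expect_identical(as.logical(cy2), as.logical(cy))
    expect_identical(as.logical(cluster_mask_kmeans(sc[["Ca"]], cy2)),
                     as.logical(cluster_mask_kmeans(maps[["Ca"]], cy)))
  }
})
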
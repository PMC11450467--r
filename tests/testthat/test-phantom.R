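test_that("preset encodes the reference concentrations and cluster statistics", {
  cfg <- filament_preset()
  expect_equal(cfg$heterocyst_cytosol[["K"]], 0.452)
  expect_equal(cfg$heterocyst_cytosol[["Ca"]], 0.073)
  expect_equal(cfg$heterocyst_cytosol[["Fe"]], 0.095)
  expect_equal(cfg$vegetative_cytosol[["K"]], 0.277)
  expect_equal(cfg$vegetative_cytosol[["Ca"]], 0.029)
  expect_equal(cfg$vegetative_cytosol[["Fe"]], 0.027)
  expect_equal(cfg$ca_cluster_conc[["mean"]], 1.337)
  expect_equal(unname(cfg$k_diameter_um), c(0.99, 0.48))
  expect_equal(cfg$ca_area_um2[["mean"]], 0.310)
  expect_equal(cfg$p_area_um2[["mean"]], 0.180)
  expect_equal(cfg$fe_area_um2[["mean"]], 0.050)
  expect_equal(cfg$pk_count_range, c(2L, 4L))
  expect_equal(cfg$heterocyst_pk_count, 0L)
  expect_equal(cfg$envelope_nm, 345)
})

test_that("mean-matched truncated normal sampler hits its target mean", {
  withr::with_seed(11, {
    # hard truncation: the Fe-area regime where naive truncation would
    # inflate the mean by ~2x
    x <- rtnorm_mean(2e5, 0.050, 0.095, 0.02)
    expect_true(all(x > 0.02))
    expect_lt(abs(mean(x) - 0.050), 3 * sd(x) / sqrt(length(x)))
    # mild truncation
    y <- rtnorm_mean(2e5, 0.99, 0.48, 0.16)
    expect_lt(abs(mean(y) - 0.99), 3 * sd(y) / sqrt(length(y)))
  })
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- small_preset()
  a <- generate_filament(cfg, 5)
  b <- generate_filament(cfg, 5)
  expect_identical(a, b)
  c <- generate_filament(cfg, 6)
  expect_false(identical(a$registry, c$registry))
})

test_that("a zero-cluster config yields pure cytosol backgrounds", {
  truth <- generate_filament(flat_preset(), 3)
  expect_equal(nrow(truth$registry), 0)
  for (e in c("K", "Ca", "Fe")) {
    v <- truth$maps[[e]]$values
    veg <- truth$cell_label_map > 0 &
      matrix(truth$cells$kind[pmax(truth$cell_label_map, 1)] == "vegetative",
             nrow(v), ncol(v))
    expect_true(all(v[veg] == filament_preset()$vegetative_cytosol[[e]]))
  }
})

test_that("too small a field raises a geometry-overflow error", {
  cfg <- small_preset(field_shape = c(10, 20))
  expect_error(generate_filament(cfg, 1), "geometry overflow")
})

test_that("registry invariants hold: containment, nesting, disjointness, units", {
  cfg <- filament_preset(n_veg = 5)
  truth <- generate_filament(cfg, 8)
  reg <- truth$registry
  pxa <- pixel_area_um2(truth$scan)
  expect_true(all(abs(reg$area_um2 - reg$n_pixels * pxa) < 1e-12))
  for (i in seq_len(nrow(reg))) {
    cells_hit <- unique(truth$cell_label_map[reg$pixels[[i]]])
    expect_length(cells_hit, 1)            # inside exactly one cell
    expect_equal(cells_hit, reg$cell_id[i])
  }
  # heterocyst carries no P/K and no Ca clusters
  het <- truth$cells$cell_id[truth$cells$kind == "heterocyst"]
  expect_false(any(reg$cell_id == het & reg$element %in% c("P", "K", "Ca")))
  # Ca disk of each PK_Ca cluster contains the P core centroid, exceeds its
  # area, and shell/core/K-extent nest around a common centre
  ids <- unique(reg$record_id[reg$family == "PK_Ca" & reg$element == "Ca"])
  for (i in ids) {
    shell <- reg[reg$record_id == i, ]
    core <- reg[reg$record_id == i - 1, ]   # P footprint precedes its shell
    expect_equal(core$element, "P")
    ctr <- round(colMeans(core$pixels[[1]]))
    keys <- paste(shell$pixels[[1]][, 1], shell$pixels[[1]][, 2])
    expect_true(paste(ctr[1], ctr[2]) %in% keys)
    expect_gt(shell$area_um2, core$area_um2)
  }
  # footprints of one element never overlap within a map
  for (e in c("K", "P", "Ca", "Fe")) {
    px <- do.call(rbind, reg$pixels[reg$element == e])
    if (!is.null(px)) expect_false(any(duplicated(px)))
  }
  for (m in truth$maps) expect_true(all(m$values >= 0))
})

test_that("ground-truth maps conserve mass against an independent recount", {
  cfg <- filament_preset(n_veg = 4)
  truth <- generate_filament(cfg, 2)
  reg <- truth$registry
  for (e in names(truth$maps)) {
    analytic <- 0
    for (i in seq_len(nrow(truth$cells))) {
      conc <- if (truth$cells$kind[i] == "heterocyst") cfg$heterocyst_cytosol
              else cfg$vegetative_cytosol
      analytic <- analytic + conc[[e]] * sum(truth$cell_label_map == i)
    }
    if (e %in% names(cfg$envelope_conc)) {
      analytic <- analytic + cfg$envelope_conc[[e]] * sum(truth$envelope_mask)
    }
    rows <- reg[reg$element == e, ]
    if (nrow(rows)) analytic <- analytic + sum(rows$conc_boost * rows$n_pixels)
    expect_equal(sum(truth$maps[[e]]$values), analytic, tolerance = 1e-10)
  }
})

test_that("pooled K cluster diameters follow the configured distribution", {
  cfg <- filament_preset()
  diam <- c()
  s <- 0
  while (length(diam) < 500) {
    s <- s + 1
    reg <- generate_filament(cfg, 300 + s)$registry
    diam <- c(diam, equiv_diameter(reg$area_um2[reg$element == "K"]))
  }
  expect_lt(abs(mean(diam) - 0.99) / 0.99, 0.05)
})

test_that("count simulation follows the Poisson forward model", {
  truth <- generate_filament(flat_preset(), 4)
  det <- detector_model()
  lam <- expected_counts(truth, det = det)
  cm <- simulate_counts(truth, det = det, seed = 9)
  # expectation matches the noiseless forward value (3 SE over >= 1e4 px)
  for (e in c("K", "S")) {
    idx <- lam[[e]] > 0
    expect_gt(sum(idx), 4e3)
    se <- sqrt(sum(lam[[e]][idx])) / sum(idx)
    expect_lt(abs(mean(cm$counts[[e]][idx]) - mean(lam[[e]][idx])), 3 * se)
  }
  # doubling dwell doubles the mean
  scan2 <- scan_config(truth$scan$step_nm, truth$scan$dwell_ms * 2,
                       truth$scan$field_shape)
  cm2 <- simulate_counts(truth, scan2, det, seed = 10)
  idx <- lam[["K"]] > 0
  ratio <- mean(cm2$counts[["K"]][idx]) / mean(cm$counts[["K"]][idx])
  expect_lt(abs(ratio - 2), 6 * sqrt(2 / sum(lam[["K"]][idx])))
  # zero concentration gives all-zero counts
  expect_true(all(cm$counts[["K"]][lam[["K"]] == 0] == 0))
  # determinism and rejection of negative concentrations
  expect_identical(cm$counts, simulate_counts(truth, det = det, seed = 9)$counts)
  bad <- truth
  bad$maps[["K"]]$values[1, 1] <- -1
  expect_error(simulate_counts(bad, det = det, seed = 1), "negative")
})

test_that("noise-free spectra integrate to the injected areas and line ratios", {
  det <- detector_model()
  cfg <- flat_preset()
  truth <- generate_filament(cfg, 5)
  cube <- simulate_spectra(truth, det = det, seed = 1, noise = FALSE)
  E <- cube$energy_kev
  cont <- continuum_counts(det, truth$scan$dwell_ms)
  px <- which(truth$cytoplasm_mask)[1]
  spec <- cube$counts[px, ] - cont
  cat <- line_catalog("Fe")
  sens <- detector_sensitivity(det, "Fe")
  # isolated Fe K-alpha: numeric integral equals conc x sens x dwell to 0.1%
  ka <- sum(spec[E > 6.0 & E < 6.8])
  expected <- 0.027 * sens[["Fe"]] * truth$scan$dwell_ms
  expect_lt(abs(ka - expected) / expected, 0.001)
  # K-beta/K-alpha integral ratio equals the catalog ratio (1% window
  # tolerance: the K-alpha tail leaks a little across the window edge)
  kb <- sum(spec[E > 6.8 & E < 7.6])
  expect_lt(abs(kb / ka - cat$kb_ka_ratio), 0.01 * cat$kb_ka_ratio)
  # empty truth -> continuum-only spectra
  empty <- truth
  for (e in names(empty$maps)) empty$maps[[e]]$values[] <- 0
  cube0 <- simulate_spectra(empty, det = det, seed = 1, noise = FALSE)
  expect_equal(cube0$counts[1, ], cont, tolerance = 1e-12, ignore_attr = TRUE)
  # spectra are reproducible given the seed
  c1 <- simulate_spectra(truth, det = det, seed = 3)
  c2 <- simulate_spectra(truth, det = det, seed = 3)
  expect_identical(c1$counts, c2$counts)
})
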
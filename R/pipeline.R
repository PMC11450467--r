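#' Default thin-film calibration standard definition
#'
#' A synthetic multi-element thin-film standard spanning the catalog's Z
#' range, used when no certified standard is supplied. Densities are
#' plausible certified areal densities in ug/cm^2; the standard is an input
#' of the calibration, never a claim about any particular vendor foil.
#'
#' @return Tibble with `element`, `density_ug_cm2`.
#' @export
default_standard <- function() {
  tibble::tibble(element = c("Al", "Si", "S", "Ca", "Mn", "Cu", "Zn"),
                 density_ug_cm2 = c(0.80, 0.90, 1.00, 1.10, 0.90, 0.70, 0.60))
}

#' Simulate one filament experiment
#'
#' Convenience wrapper: generates a phantom filament and simulates its
#' measurement, either as per-element count maps (fast path) or as a full
#' per-pixel spectrum cube. Optionally writes the HDF5 artifacts and a JSON
#' run manifest.
#'
#' @param config A `phantom_config`.
#' @param seed Integer seed controlling both geometry and noise.
#' @param det A `detector_model`.
#' @param mode `"counts"` or `"spectra"`.
#' @param out_dir Optional output directory for HDF5 bundles + manifest.
#' @return List with `truth`, and `counts` + `maps` (counts mode) or
#'   `cube` (spectra mode), plus the `manifest`.
#' @export
simulate_experiment <- function(config = filament_preset(), seed = 1,
                                det = detector_model(),
                                mode = c("counts", "spectra"),
                                out_dir = NULL) {
  mode <- match.arg(mode)
  truth <- generate_filament(config, seed)
  out <- list(truth = truth)
  if (mode == "counts") {
    out$counts <- simulate_counts(truth, det = det, seed = seed + 1L)
    out$maps <- counts_to_maps(out$counts)
  } else {
    out$cube <- simulate_spectra(truth, det = det, seed = seed + 1L)
  }
  out$manifest <- run_manifest(seed, config, mode)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bundle(truth$maps, file.path(out_dir, "truth_maps.h5"))
    if (mode == "counts") {
      write_bundle(out$maps, file.path(out_dir, "recovered_maps.h5"))
    } else {
      write_cube(out$cube, file.path(out_dir, "spectra.h5"))
    }
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(dplyr::select(truth$registry, -"pixels"),
                     file.path(out_dir, "registry.csv"), row.names = FALSE)
  }
  out
}

#' Run manifest: seed, versions and configuration hash
#' @noRd
run_manifest <- function(seed, config, mode) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2)
  list(package = "xrfmap",
       version = as.character(utils::packageVersion("xrfmap")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = as.integer(seed), mode = mode,
       config_hash = unname(tools::md5sum(tmp)))
}

#' Full segmentation + morphometry + colocalization analysis of a map set
#'
#' Runs the whole 2D analysis the pipeline exists for: cytoplasm
#' delineation from K, per-element k-means cluster masks, ROI labelling,
#' cluster records (area, equivalent diameter, background-subtracted mean
#' concentrations, colocalization family), per-cell region concentrations,
#' per-ROI Pearson correlations (per-ROI and pooled), and pairwise overlap
#' fractions.
#'
#' @param maps Named list of `element_map`s; must contain K. Analysis
#'   elements default to the intersection of (P, K, Ca, Fe) with `maps`.
#' @param cell_label_map Optional integer matrix of cell labels (0 =
#'   background) enabling per-cell region concentrations. Cell-type
#'   assignment is an input, not an inference.
#' @param cell_kinds Optional character vector, kind of each cell id.
#' @param min_size Minimum ROI size in pixels.
#' @return Object of class `xrf_analysis`: list of tibbles `clusters`,
#'   `regions`, `correlations`, `correlations_pooled`, `overlaps`, plus the
#'   masks used.
#' @export
analyze_maps <- function(maps, cell_label_map = NULL, cell_kinds = NULL,
                         min_size = 2) {
  stopifnot("K" %in% names(maps))
  elements <- intersect(c("P", "K", "Ca", "Fe"), names(maps))
  cyto <- cytoplasm_mask(maps[["K"]])
  off <- !cyto
  masks <- lapply(stats::setNames(elements, elements), function(e) {
    cluster_mask_kmeans(maps[[e]], cyto)
  })
  rois <- purrr::map_dfr(elements, function(e) {
    label_rois(masks[[e]], connectivity = 8, min_size = min_size,
               element = e, method = "kmeans")
  })

  clusters <- purrr::map_dfr(seq_len(nrow(rois)), function(i) {
    roi <- rois[i, ]
    px <- roi$pixels[[1]]
    fam <- classify_cluster(px, masks)
    cell_id <- if (is.null(cell_label_map)) NA_integer_ else {
      hits <- cell_label_map[px]
      hits <- hits[hits > 0]
      if (length(hits)) as.integer(names(which.max(table(hits)))) else NA_integer_
    }
    area <- cluster_area(roi$n_pixels, maps[[1]]$step_nm)
    concs <- purrr::map_dbl(stats::setNames(elements, paste0("mean_", elements)),
      function(e) {
        reg <- matrix(FALSE, nrow(cyto), ncol(cyto)); reg[px] <- TRUE
        region_mean_concentration(maps[[e]], reg, off)$mean
      })
    dplyr::bind_cols(
      tibble::tibble(element = roi$element, label = roi$label,
                     cell_id = cell_id, family = fam,
                     n_pixels = roi$n_pixels, area_um2 = area,
                     equiv_diameter_um = equiv_diameter(area)),
      tibble::as_tibble(as.list(concs)))
  })

  regions <- NULL
  if (!is.null(cell_label_map)) {
    any_cluster <- Reduce(`|`, masks)
    regions <- purrr::map_dfr(sort(unique(cell_label_map[cell_label_map > 0])),
      function(cid) {
        cell_px <- cell_label_map == cid
        purrr::map_dfr(c("cytosol", "clusters"), function(rtype) {
          reg <- if (rtype == "cytosol") cell_px & cyto & !any_cluster
                 else cell_px & any_cluster
          if (!any(reg)) return(NULL)
          purrr::map_dfr(elements, function(e) {
            dplyr::bind_cols(
              tibble::tibble(cell_id = cid,
                             kind = if (is.null(cell_kinds)) NA_character_
                                    else cell_kinds[cid],
                             region = rtype),
              region_mean_concentration(maps[[e]], reg, off))
          })
        })
      })
  }

  pairs <- utils::combn(elements, 2, simplify = FALSE)
  correlations <- purrr::map_dfr(pairs, function(p) {
    ra <- rois[rois$element == p[1], ]
    if (nrow(ra) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(ra)), function(i) {
      roi_pearson(maps[[p[1]]], maps[[p[2]]], ra[i, ])
    })
  })
  correlations_pooled <- purrr::map_dfr(pairs, function(p) {
    ra <- rois[rois$element == p[1], ]
    if (nrow(ra) == 0) return(NULL)
    idx <- unique(unlist(lapply(seq_len(nrow(ra)), function(i) {
      r <- ra[i, ]
      as.vector(outer(r$rmin:(r$rmax - 1L),
                      (r$cmin:(r$cmax - 1L) - 1L) * nrow(cyto), `+`))
    })))
    a <- maps[[p[1]]]$values[idx]; b <- maps[[p[2]]]$values[idx]
    keep <- is.finite(a) & is.finite(b)
    defined <- sum(keep) >= 2 && stats::sd(a[keep]) > 0 && stats::sd(b[keep]) > 0
    tibble::tibble(element_a = p[1], element_b = p[2],
                   pearson_r = if (defined) stats::cor(a[keep], b[keep]) else NA_real_,
                   n_pixels = sum(keep), defined = defined)
  })

  overlaps <- purrr::map_dfr(pairs, function(p) {
    ra <- rois[rois$element == p[1], ]
    rb <- rois[rois$element == p[2], ]
    if (nrow(ra) == 0 || nrow(rb) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(ra)), function(i) {
      ov <- purrr::map_dfr(seq_len(nrow(rb)), function(j) {
        overlap_fraction(ra[i, ], rb[j, ])
      })
      best <- which.max(ov$n_intersect)
      dplyr::bind_cols(tibble::tibble(element_a = p[1], element_b = p[2],
                                      label_a = ra$label[i],
                                      label_b = rb$label[best]),
                       ov[best, ])
    })
  })

  structure(list(clusters = clusters, regions = regions,
                 correlations = correlations,
                 correlations_pooled = correlations_pooled,
                 overlaps = overlaps,
                 cytoplasm = cyto, cluster_masks = masks, rois = rois),
            class = "xrf_analysis")
}

#' @export
print.xrf_analysis <- function(x, ...) {
  cat(sprintf("<xrf_analysis> %d cluster(s) across %s\n",
              nrow(x$clusters),
              paste(names(x$cluster_masks), collapse = "/")))
  invisible(x)
}

#' Recover the preset's ground truth through the full pipeline
#'
#' The end-to-end recovery harness: (1) one filament is simulated as a full
#' spectrum cube, calibrated against a simulated thin-film standard,
#' quantified, segmented, and its region/cluster concentrations measured;
#' (2) `n_filaments` further filaments are simulated through the counting
#' forward model and segmented to pool cluster morphometry (K equivalent
#' diameters, Fe areas) over hundreds of clusters. Recovered values are
#' reported next to the generating ground truth.
#'
#' @param seed Base integer seed; sub-seeds are derived deterministically.
#' @param config A `phantom_config`.
#' @param det A `detector_model`.
#' @param n_filaments Number of filaments in the pooled morphometry run.
#' @return List: `summary` (tibble quantity / recovered / truth / n),
#'   `analysis` (the spectral filament's `xrf_analysis`), `pooled`
#'   (tibble of pooled cluster sizes), `manifest`.
#' @export
recover_preset <- function(seed = 1, config = filament_preset(),
                           det = detector_model(), n_filaments = 20) {
  seed <- as.integer(seed)
  # --- spectral filament: calibration + quantification + concentrations ---
  truth <- generate_filament(config, seed)
  cube <- simulate_spectra(truth, det = det, seed = seed + 101L)
  std <- default_standard()
  std_spec <- simulate_standard(std, det, live_time_ms = 20000,
                                seed = seed + 202L)
  sens <- calibrate_sensitivities(std, std_spec, det,
                                  elements = names(truth$maps))
  maps <- quantify_map(cube, sens)
  cell_kinds <- truth$cells$kind
  ana <- analyze_maps(maps[intersect(c("P", "K", "Ca", "Fe"), names(maps))],
                      cell_label_map = truth$cell_label_map,
                      cell_kinds = cell_kinds)

  cyto <- ana$cytoplasm
  # consensus Ca-cluster concentration (two-method boundary)
  fx_th <- fixed_threshold_default(maps[["Ca"]], cyto)
  cons <- consensus_mask(ana$cluster_masks[["Ca"]],
                         cluster_mask_fixed(maps[["Ca"]], cyto, fx_th))
  ca_conc <- region_mean_concentration(maps[["Ca"]], cons$core, !cyto)

  regions <- ana$regions
  cyt_reg <- regions[regions$region == "cytosol", ]
  het <- cyt_reg[cyt_reg$kind == "heterocyst", ]
  veg <- cyt_reg[cyt_reg$kind == "vegetative", ]
  veg_mean <- function(el) mean(veg$mean[veg$element == el])
  het_mean <- function(el) mean(het$mean[het$element == el])

  # --- pooled runs over many filaments (counting forward model): cluster
  # morphometry for K and Fe, and the two-method consensus Ca concentration.
  # Pooling is essential for the concentration inside Ca-rich clusters: one
  # filament holds only ~10-15 Ca clusters, so with a between-cluster SD of
  # 0.64 ug/cm^2 the single-filament mean carries ~11% sampling noise.
  ca_core_vals <- list()
  pooled <- purrr::map_dfr(seq_len(n_filaments), function(i) {
    si <- seed + 1000L + 7L * i
    tr <- generate_filament(config, si)
    cm <- simulate_counts(tr, det = det, seed = si + 1L)
    mp <- counts_to_maps(cm)
    cy <- cytoplasm_mask(mp[["K"]])
    if (!any(cy)) return(NULL)
    km_ca <- cluster_mask_kmeans(mp[["Ca"]], cy)
    if (!attr(km_ca, "degenerate")) {
      fx <- cluster_mask_fixed(mp[["Ca"]], cy,
                               fixed_threshold_default(mp[["Ca"]], cy))
      core <- consensus_mask(km_ca, fx)$core
      bg <- stats::median(mp[["Ca"]]$values[!cy], na.rm = TRUE)
      ca_core_vals[[i]] <<- mp[["Ca"]]$values[core] - bg
    }
    purrr::map_dfr(c("K", "Fe"), function(e) {
      rois <- label_rois(cluster_mask_kmeans(mp[[e]], cy), element = e,
                         method = "kmeans")
      if (nrow(rois) == 0) return(NULL)
      area <- cluster_area(rois$n_pixels, tr$scan)
      tibble::tibble(filament = i, element = e, label = rois$label,
                     area_um2 = area, equiv_diameter_um = equiv_diameter(area))
    })
  })
  ca_core_vals <- unlist(ca_core_vals)

  truth_reg <- truth$registry
  summary <- tibble::tibble(
    quantity = c("heterocyst_cytosol_K", "heterocyst_cytosol_Ca",
                 "heterocyst_cytosol_Fe", "vegetative_cytosol_K",
                 "vegetative_cytosol_Ca", "vegetative_cytosol_Fe",
                 "ca_cluster_conc_consensus",
                 "k_cluster_diameter_um", "fe_cluster_area_um2"),
    recovered = c(het_mean("K"), het_mean("Ca"), het_mean("Fe"),
                  veg_mean("K"), veg_mean("Ca"), veg_mean("Fe"),
                  mean(ca_core_vals),
                  mean(pooled$equiv_diameter_um[pooled$element == "K"]),
                  mean(pooled$area_um2[pooled$element == "Fe"])),
    truth = c(config$heterocyst_cytosol[["K"]],
              config$heterocyst_cytosol[["Ca"]],
              config$heterocyst_cytosol[["Fe"]],
              config$vegetative_cytosol[["K"]],
              config$vegetative_cytosol[["Ca"]],
              config$vegetative_cytosol[["Fe"]],
              config$ca_cluster_conc[["mean"]],
              config$k_diameter_um[["mean"]],
              config$fe_area_um2[["mean"]]),
    n = c(rep(nrow(het) / max(1, length(unique(het$element))), 3) |> round(),
          rep(nrow(veg) / max(1, length(unique(veg$element))), 3) |> round(),
          length(ca_core_vals),
          sum(pooled$element == "K"), sum(pooled$element == "Fe")))

  list(summary = summary, analysis = ana, pooled = pooled,
       ca_consensus = ca_conc, sens = sens,
       manifest = run_manifest(seed, config, "recover"))
}
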
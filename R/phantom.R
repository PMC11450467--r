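#' Truncated-normal sampler with mean matching
#'
#' Draws from a normal truncated below at `lower` whose *realized* (post
#' truncation) mean equals `mean`. The underlying location parameter is
#' solved numerically, because for distributions whose nominal spread is
#' comparable to the mean (for example the small, highly dispersed Fe
#' cluster areas) naive truncation would inflate the population mean well
#' above the targeted value. Sampling uses the inverse-CDF construction, so
#' it is exact and O(1) per draw regardless of how hard the truncation bites.
#'
#' @param n Number of draws.
#' @param mean Target mean of the truncated distribution.
#' @param sd Scale of the underlying normal.
#' @param lower Truncation bound; must be < mean.
#' @return Numeric vector of `n` draws, all > `lower`.
#' @export
rtnorm_mean <- function(n, mean, sd, lower) {
  stopifnot(sd > 0, lower < mean)
  mu <- tnorm_location(mean, sd, lower)
  a <- stats::pnorm((lower - mu) / sd)
  stats::qnorm(a + stats::runif(n) * (1 - a)) * sd + mu
}

#' Location parameter giving a target truncated mean
#' @noRd
tnorm_location <- function(target, sd, lower) {
  realized <- function(mu) {
    alpha <- (lower - mu) / sd
    lambda <- stats::dnorm(alpha) / stats::pnorm(alpha, lower.tail = FALSE)
    mu + sd * lambda - target
  }
  stats::uniroot(realized, lower = target - 12 * sd, upper = target + sd,
                 tol = 1e-10)$root
}

um_to_px <- function(um, step_nm) um * 1000 / step_nm

#' Filament phantom configuration preset
#'
#' Builds the default configuration of the synthetic *Anabaena*-like
#' filament: a horizontal chain of elliptical vegetative cells with one
#' round heterocyst of equal area mid-filament, a Cl-bearing envelope
#' sheath, cytosolic K/Ca/Fe/P/S/Cl backgrounds, and four cluster families
#' (P/K cores wrapped by Ca-rich disks, P/K cores with associated Fe blobs,
#' isolated Ca disks, isolated irregular Fe blobs).
#'
#' The preset's ground-truth parameters are the reference measurements for
#' nitrogen-starved *Anabaena* sp.: heterocyst cytosol K 0.452, Ca 0.073,
#' Fe 0.095 ug/cm^2; vegetative cytosol K 0.277, Ca 0.029, Fe 0.027;
#' Ca-rich cluster concentration 1.337 ug/cm^2 (SD 0.64); K cluster
#' diameter 0.99 um (SD 0.48); mean footprint areas Ca 0.310, P 0.180,
#' Fe 0.050 um^2; 2-4 P/K clusters per vegetative cell and none in the
#' heterocyst; a 345 nm envelope. Cytosolic S and Cl levels are free
#' choices (no reference value exists) defaulting to 0.30 and 0.02
#' ug/cm^2. The nominal K cluster *area* of 0.200 um^2 is retained as
#' metadata; it is geometrically incompatible with the 0.99 um diameter
#' distribution that drives the K footprint (see the methods vignette).
#'
#' @param n_veg Number of vegetative cells (4-10 typical).
#' @param heterocyst Include a mid-filament heterocyst?
#' @param step_nm,dwell_ms Scan settings.
#' @param field_shape Optional `c(rows, cols)`; computed from the geometry
#'   when `NULL`. Too small a field raises a geometry-overflow error at
#'   generation time.
#' @param pk_count_range Integer range of P/K clusters per vegetative cell.
#' @param ca_only_range,fe_only_range Ranges for isolated Ca / Fe clusters
#'   per vegetative cell (Fe also in the heterocyst; Ca and P/K never).
#' @param s_cytosol,cl_cytosol Cytosolic S and Cl in ug/cm^2.
#' @return An object of class `phantom_config`.
#' @examples
#' cfg <- filament_preset(n_veg = 4)
#' cfg$heterocyst_cytosol[["K"]]
#' @export
filament_preset <- function(n_veg = 6, heterocyst = TRUE,
                            step_nm = 100, dwell_ms = 200,
                            field_shape = NULL,
                            pk_count_range = c(2, 4),
                            ca_only_range = c(0, 2),
                            fe_only_range = c(1, 2),
                            s_cytosol = 0.30, cl_cytosol = 0.02) {
  structure(list(
    n_veg = n_veg,
    heterocyst = heterocyst,
    step_nm = step_nm,
    dwell_ms = dwell_ms,
    field_shape = field_shape,
    cell_axes_um = c(a = 2.5, b = 1.75),   # semi-axes of vegetative cells
    envelope_nm = 345,
    envelope_conc = c(Cl = 0.25),
    vegetative_cytosol = c(K = 0.277, Ca = 0.029, Fe = 0.027,
                           P = 0.05, S = s_cytosol, Cl = cl_cytosol),
    heterocyst_cytosol = c(K = 0.452, Ca = 0.073, Fe = 0.095,
                           P = 0.05, S = s_cytosol, Cl = cl_cytosol),
    pk_count_range = as.integer(pk_count_range),
    ca_only_range = as.integer(ca_only_range),
    fe_only_range = as.integer(fe_only_range),
    heterocyst_pk_count = 0L,
    frac_pk_ca = 0.5,
    k_diameter_um = c(mean = 0.99, sd = 0.48),
    k_area_um2_nominal = 0.200,
    p_area_um2 = c(mean = 0.180, sd = 0.08),
    ca_area_um2 = c(mean = 0.310, sd = 0.10),    # mean = p core + increment
    fe_area_um2 = c(mean = 0.050, sd = 0.095),
    ca_cluster_conc = c(mean = 1.337, sd = 0.64),
    ca_conc_floor = 0.75,
    conc_boost = c(K = 0.5, P = 0.8, Fe = 0.8),
    min_cluster_px = 2L
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d vegetative cell(s)%s, step %g nm, dwell %g ms\n",
              x$n_veg, if (x$heterocyst) " + 1 heterocyst" else "",
              x$step_nm, x$dwell_ms))
  invisible(x)
}

# --- geometry helpers -------------------------------------------------------

#' Nearest-n pixel disk around a centre (deterministic tie-break, row-major)
#' @noRd
disk_pixels <- function(center, n, rows, cols) {
  r0 <- center[1]; c0 <- center[2]
  rad <- ceiling(sqrt(n / pi)) + 2
  rr <- max(1, floor(r0 - rad)):min(rows, ceiling(r0 + rad))
  cc <- max(1, floor(c0 - rad)):min(cols, ceiling(c0 + rad))
  grid <- expand.grid(row = rr, col = cc)
  d2 <- (grid$row - r0)^2 + (grid$col - c0)^2
  ord <- order(d2, grid$row, grid$col)
  sel <- grid[ord[seq_len(min(n, nrow(grid)))], ]
  cbind(row = sel$row, col = sel$col)
}

#' Irregular blob by seeded random-walk aggregation
#' @noRd
blob_pixels <- function(center, n, inside) {
  rows <- nrow(inside); cols <- ncol(inside)
  cur <- round(center)
  seen <- matrix(FALSE, rows, cols)
  px <- matrix(integer(0), ncol = 2)
  if (inside[cur[1], cur[2]]) {
    seen[cur[1], cur[2]] <- TRUE
    px <- rbind(px, cur)
  }
  steps <- matrix(c(-1L, 0L, 1L, 0L, 0L, -1L, 0L, 1L), ncol = 2, byrow = TRUE)
  iter <- 0
  while (nrow(px) < n && iter < 200 * n) {
    iter <- iter + 1
    s <- steps[sample.int(4, 1), ]
    cand <- cur + s
    if (cand[1] < 1 || cand[1] > rows || cand[2] < 1 || cand[2] > cols) next
    if (!inside[cand[1], cand[2]]) next
    cur <- cand
    if (!seen[cur[1], cur[2]]) {
      seen[cur[1], cur[2]] <- TRUE
      px <- rbind(px, cur)
    }
  }
  colnames(px) <- c("row", "col")
  px
}

#' Logical ellipse mask
#' @noRd
ellipse_mask <- function(rows, cols, center, a, b) {
  cr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((cc - center[2]) / a)^2 + ((cr - center[1]) / b)^2 <= 1
}

pix_index <- function(px, rows) (px[, "col"] - 1L) * rows + px[, "row"]

# --- generator --------------------------------------------------------------

#' Generate a synthetic filament with ground truth
#'
#' Renders the configured filament on the scan grid and returns the full
#' ground truth: noiseless elemental maps (ug/cm^2), the cytoplasm and
#' envelope masks, a per-cell label map, and a cluster registry recording
#' every cluster footprint (family, host cell, pixels, boost, true mean
#' concentration). The output is deterministic given `(config, seed)`.
#'
#' Cluster footprints of one element never overlap each other, and every
#' footprint lies inside exactly one cell. Ca-rich disks of the PK_Ca
#' family always contain their P/K core and exceed it in area (a 3D Ca
#' shell projects to a filled disk in an areal map).
#'
#' @param config A `phantom_config` from [filament_preset()].
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_truth`.
#' @examples
#' truth <- generate_filament(filament_preset(n_veg = 4), seed = 1)
#' names(truth$maps)
#' @export
generate_filament <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(as.integer(seed), generate_filament_impl(config, seed))
}

#' @noRd
generate_filament_impl <- function(config, seed) {
  step <- config$step_nm
  a <- um_to_px(config$cell_axes_um[["a"]], step)
  b <- um_to_px(config$cell_axes_um[["b"]], step)
  r_het <- sqrt(a * b)              # circle of equal area
  t_env <- um_to_px(config$envelope_nm / 1000, step)
  margin <- ceiling(t_env) + 4

  kinds <- rep("vegetative", config$n_veg)
  if (config$heterocyst) {
    kinds <- append(kinds, "heterocyst", after = ceiling(config$n_veg / 2))
  }
  half_w <- ifelse(kinds == "heterocyst", r_het, a)
  centers_c <- margin + cumsum(2 * half_w) - half_w

  need_rows <- ceiling(2 * max(b, r_het) + 2 * margin)
  need_cols <- ceiling(centers_c[length(centers_c)] +
                         half_w[length(half_w)] + margin)
  shape <- config$field_shape
  if (is.null(shape)) shape <- c(need_rows, need_cols)
  rows <- shape[1]; cols <- shape[2]
  if (rows < need_rows || cols < need_cols) {
    stop(sprintf("geometry overflow: field %d x %d cannot hold %d cell(s) (need %d x %d)",
                 rows, cols, length(kinds), need_rows, need_cols))
  }
  center_r <- rows / 2 + 0.5

  elements <- union(names(config$vegetative_cytosol), names(config$envelope_conc))
  maps <- stats::setNames(
    lapply(elements, function(e) matrix(0, rows, cols)), elements)
  cell_label <- matrix(0L, rows, cols)
  cyto <- matrix(FALSE, rows, cols)
  env_mask <- matrix(FALSE, rows, cols)

  cells <- tibble::tibble(cell_id = seq_along(kinds), kind = kinds,
                          center_row = center_r, center_col = centers_c,
                          a_px = ifelse(kinds == "heterocyst", r_het, a),
                          b_px = ifelse(kinds == "heterocyst", r_het, b))

  for (i in seq_len(nrow(cells))) {
    m <- ellipse_mask(rows, cols, c(center_r, centers_c[i]),
                      cells$a_px[i], cells$b_px[i])
    outer <- ellipse_mask(rows, cols, c(center_r, centers_c[i]),
                          cells$a_px[i] + t_env, cells$b_px[i] + t_env)
    env_mask <- env_mask | (outer & !m)
    cell_label[m] <- i
    cyto <- cyto | m
    conc <- if (kinds[i] == "heterocyst") config$heterocyst_cytosol
            else config$vegetative_cytosol
    for (e in names(conc)) maps[[e]][m] <- maps[[e]][m] + conc[[e]]
  }
  env_mask <- env_mask & !cyto  # envelopes never claim cytoplasm of a neighbour
  for (e in names(config$envelope_conc)) {
    maps[[e]][env_mask] <- maps[[e]][env_mask] + config$envelope_conc[[e]]
  }

  # --- clusters ---
  pxa <- (step / 1000)^2
  min_area <- config$min_cluster_px * pxa
  registry <- list()
  cid <- 0L

  draw_count <- function(range) {
    if (range[1] == range[2]) range[1] else sample(seq(range[1], range[2]), 1)
  }

  place_center <- function(cell, r_need, peripheral) {
    u_max <- 1 - (r_need + 1.5) / cell$b_px
    if (u_max <= 0.05) return(NULL)
    for (try in 1:120) {
      u <- if (peripheral) stats::runif(1, 0.55 * u_max, u_max)
           else sqrt(stats::runif(1)) * u_max   # ~uniform over the interior
      phi <- stats::runif(1, 0, 2 * pi)
      ctr <- c(cell$center_row + u * cell$b_px * sin(phi),
               cell$center_col + u * cell$a_px * cos(phi))
      ok <- TRUE
      for (p in placed) {
        if (sum((ctr - p$center)^2) < (r_need + p$radius + 2)^2) { ok <- FALSE; break }
      }
      if (ok) return(ctr)
    }
    # fallback: anywhere in the cell, so crowding cannot bias cluster sizes
    for (try in 1:80) {
      u <- sqrt(stats::runif(1)) * u_max
      phi <- stats::runif(1, 0, 2 * pi)
      ctr <- c(cell$center_row + u * cell$b_px * sin(phi),
               cell$center_col + u * cell$a_px * cos(phi))
      ok <- TRUE
      for (p in placed) {
        if (sum((ctr - p$center)^2) < (r_need + p$radius + 1)^2) { ok <- FALSE; break }
      }
      if (ok) return(ctr)
    }
    NULL
  }

  add_record <- function(cell_id, family, element, px, boost, cyt_conc) {
    cid <<- cid + 1L
    registry[[cid]] <<- tibble::tibble(
      record_id = cid, cell_id = cell_id, family = family, element = element,
      n_pixels = nrow(px), area_um2 = nrow(px) * pxa,
      conc_boost = boost, true_mean_conc = cyt_conc + boost,
      pixels = list(px))
    idx <- pix_index(px, rows)
    maps[[element]][idx] <<- maps[[element]][idx] + boost
  }

  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    veg <- cell$kind == "vegetative"
    cyt <- if (veg) config$vegetative_cytosol else config$heterocyst_cytosol
    cell_mask <- cell_label == i
    placed <- list()

    n_pk <- if (veg) draw_count(config$pk_count_range) else config$heterocyst_pk_count
    n_ca <- if (veg) draw_count(config$ca_only_range) else 0L
    n_fe <- draw_count(config$fe_only_range)

    pk_specs <- lapply(seq_len(n_pk), function(k) {
      d_k <- rtnorm_mean(1, config$k_diameter_um[["mean"]],
                         config$k_diameter_um[["sd"]],
                         2 * sqrt(min_area / pi))
      a_k <- pi * d_k^2 / 4
      a_p <- rtnorm_mean(1, config$p_area_um2[["mean"]],
                         config$p_area_um2[["sd"]], min_area)
      a_p <- min(a_p, 0.8 * a_k)
      with_ca <- stats::runif(1) < config$frac_pk_ca
      a_sh <- if (with_ca) {
        a_p + rtnorm_mean(1, config$ca_area_um2[["mean"]] - config$p_area_um2[["mean"]],
                          config$ca_area_um2[["sd"]], min_area)
      } else 0
      list(a_k = a_k, a_p = a_p, a_sh = a_sh, with_ca = with_ca)
    })
    # place largest footprints first so crowding does not bias sizes down
    ord <- order(vapply(pk_specs, function(s) max(s$a_k, s$a_sh), numeric(1)),
                 decreasing = TRUE)
    for (spec in pk_specs[ord]) {
      a_k <- spec$a_k; a_p <- spec$a_p; a_sh <- spec$a_sh
      with_ca <- spec$with_ca
      n_k <- max(config$min_cluster_px, round(a_k / pxa))
      n_p <- max(config$min_cluster_px, round(a_p / pxa))
      n_s <- max(config$min_cluster_px, round(a_sh / pxa))
      r_need <- sqrt(max(n_k, n_s) / pi) + 1
      ctr <- place_center(cell, r_need, peripheral = with_ca)
      if (is.null(ctr)) next
      placed[[length(placed) + 1]] <- list(center = ctr, radius = r_need)
      fam <- if (with_ca) "PK_Ca" else "PK_Fe"
      add_record(i, fam, "K", disk_pixels(ctr, n_k, rows, cols),
                 config$conc_boost[["K"]], cyt[["K"]])
      add_record(i, fam, "P", disk_pixels(ctr, n_p, rows, cols),
                 config$conc_boost[["P"]], cyt[["P"]])
      if (with_ca) {
        c_ca <- rtnorm_mean(1, config$ca_cluster_conc[["mean"]],
                            config$ca_cluster_conc[["sd"]], config$ca_conc_floor)
        add_record(i, fam, "Ca", disk_pixels(ctr, n_s, rows, cols),
                   c_ca - cyt[["Ca"]], cyt[["Ca"]])
      } else {
        a_fe <- rtnorm_mean(1, config$fe_area_um2[["mean"]],
                            config$fe_area_um2[["sd"]], min_area)
        px <- blob_pixels(ctr, max(config$min_cluster_px, round(a_fe / pxa)),
                          cell_mask)
        if (nrow(px) >= config$min_cluster_px) {
          add_record(i, fam, "Fe", px, config$conc_boost[["Fe"]], cyt[["Fe"]])
        }
      }
    }

    for (k in seq_len(n_ca)) {
      a_ca <- rtnorm_mean(1, config$ca_area_um2[["mean"]],
                          config$ca_area_um2[["sd"]], min_area)
      n_c <- max(config$min_cluster_px, round(a_ca / pxa))
      r_need <- sqrt(n_c / pi) + 1
      ctr <- place_center(cell, r_need, peripheral = TRUE)
      if (is.null(ctr)) next
      placed[[length(placed) + 1]] <- list(center = ctr, radius = r_need)
      c_ca <- rtnorm_mean(1, config$ca_cluster_conc[["mean"]],
                          config$ca_cluster_conc[["sd"]], config$ca_conc_floor)
      add_record(i, "Ca_only", "Ca", disk_pixels(ctr, n_c, rows, cols),
                 c_ca - cyt[["Ca"]], cyt[["Ca"]])
    }

    for (k in seq_len(n_fe)) {
      a_fe <- rtnorm_mean(1, config$fe_area_um2[["mean"]],
                          config$fe_area_um2[["sd"]], min_area)
      n_f <- max(config$min_cluster_px, round(a_fe / pxa))
      r_need <- sqrt(n_f / pi) + 2
      ctr <- place_center(cell, r_need, peripheral = FALSE)
      if (is.null(ctr)) next
      placed[[length(placed) + 1]] <- list(center = ctr, radius = r_need)
      px <- blob_pixels(ctr, n_f, cell_mask)
      if (nrow(px) >= config$min_cluster_px) {
        add_record(i, "Fe_only", "Fe", px, config$conc_boost[["Fe"]], cyt[["Fe"]])
      }
    }
  }

  registry <- if (length(registry)) dplyr::bind_rows(registry) else
    tibble::tibble(record_id = integer(), cell_id = integer(),
                   family = character(), element = character(),
                   n_pixels = integer(), area_um2 = numeric(),
                   conc_boost = numeric(), true_mean_conc = numeric(),
                   pixels = list())

  scan <- scan_config(step, config$dwell_ms, c(rows, cols))
  structure(list(
    maps = stats::setNames(
      lapply(elements, function(e) element_map(e, maps[[e]], step)), elements),
    cytoplasm_mask = cyto, envelope_mask = env_mask,
    cell_label_map = cell_label, cells = cells,
    registry = registry, config = config, scan = scan, seed = seed
  ), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d cell(s), %d cluster footprint(s), %d x %d px, seed %s\n",
              nrow(x$cells), nrow(x$registry),
              nrow(x$cell_label_map), ncol(x$cell_label_map),
              format(x$seed)))
  invisible(x)
}
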
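#' Configure a synthetic moso-bamboo stand
#'
#' The simulator emulates small square inventory plots of moso bamboo
#' (Phyllostachys edulis): scattered tapered culms with drooping tops,
#' half-ellipsoid crown shells that overlap at typical planting densities,
#' and a sloped, gently undulating ground surface. Defaults describe a
#' 10 m x 10 m plot on hilly terrain at commercial stand density.
#'
#' @param plot_size_m plot edge lengths, metres (length-2 or scalar).
#' @param n_plants number of bamboo plants (0 allowed: bare ground).
#' @param dbh_mean_m,dbh_sd_m diameter-at-breast-height distribution (m);
#'   draws are truncated to +/- 2.5 sd and to positive values.
#' @param height_mean_m,height_sd_m plant height distribution (m); heights
#'   follow a power-law allometry on DBH with multiplicative lognormal noise,
#'   so taller plants are also thicker.
#' @param crown_radius_m nominal crown radius (m); per-plant radii vary +/-15%.
#' @param crown_depth_frac fraction of plant height occupied by the crown.
#' @param min_spacing_m minimum distance between culm bases (m).
#' @param ground_slope_deg terrain slope (degrees).
#' @param tip_sway_mean_m mean horizontal displacement of the drooping culm
#'   tip relative to the base (m); moso tops nod, which displaces the apex
#'   from the surveyed base position.
#' @param lean_sd_deg standard deviation of the culm lean angle (degrees).
#' @param seed integer seed; identical seeds give bit-identical stands.
#' @return a `stand_config` list.
#' @export
stand_config <- function(plot_size_m = c(10, 10),
                         n_plants = 45,
                         dbh_mean_m = 0.09, dbh_sd_m = 0.012,
                         height_mean_m = 13.5, height_sd_m = 1.0,
                         crown_radius_m = 0.9,
                         crown_depth_frac = 0.35,
                         min_spacing_m = 0.85,
                         ground_slope_deg = 10,
                         tip_sway_mean_m = 0.3,
                         lean_sd_deg = 0.8,
                         seed = 1L) {
  if (length(plot_size_m) == 1) plot_size_m <- rep(plot_size_m, 2)
  cfg <- list(
    plot_size_m = as.numeric(plot_size_m), n_plants = as.integer(n_plants),
    dbh_mean_m = dbh_mean_m, dbh_sd_m = dbh_sd_m,
    height_mean_m = height_mean_m, height_sd_m = height_sd_m,
    crown_radius_m = crown_radius_m, crown_depth_frac = crown_depth_frac,
    min_spacing_m = min_spacing_m, ground_slope_deg = ground_slope_deg,
    tip_sway_mean_m = tip_sway_mean_m, lean_sd_deg = lean_sd_deg,
    seed = as.integer(seed)
  )
  if (cfg$n_plants < 0) abort("n_plants must be >= 0")
  if (cfg$min_spacing_m <= 0) abort("min_spacing_m must be > 0")
  if (cfg$crown_depth_frac <= 0 || cfg$crown_depth_frac >= 1)
    abort("crown_depth_frac must be in (0, 1)")
  for (f in c("plot_size_m", "dbh_mean_m", "dbh_sd_m", "height_mean_m",
              "crown_radius_m")) {
    if (any(cfg[[f]] <= 0)) abort(sprintf("%s must be > 0", f))
  }
  structure(cfg, class = "stand_config")
}

#' Generate the ground truth for a synthetic stand
#'
#' Places culm bases by rejection sampling under the minimum-spacing
#' constraint, draws correlated DBH and height, assigns per-plant crown
#' geometry, lean and tip droop, and fixes the analytic ground surface
#' (inclined plane plus low-amplitude smooth undulations) and the four
#' plot-corner survey targets.
#'
#' @param config a [stand_config()].
#' @return a `bamboo_stand` object: list with `plants` (tibble: id, x, y,
#'   dbh_m, height_m, crown geometry, lean and tip terms, apex position),
#'   `ground` (analytic surface parameters), `corners` (four targets) and
#'   the `config` used.
#' @export
generate_stand <- function(config = stand_config()) {
  stopifnot(inherits(config, "stand_config"))
  withr::with_seed(config$seed, {
    W <- config$plot_size_m[1]
    L <- config$plot_size_m[2]

    # ground: plane of the configured slope along a random azimuth + bumps
    az <- runif(1, 0, 2 * pi)
    g <- tan(config$ground_slope_deg * pi / 180)
    ground <- list(
      z0 = runif(1, 40, 60),
      gx = g * cos(az), gy = g * sin(az),
      bumps = tibble::tibble(
        amp = c(0.04, 0.03),
        wx = c(cos(runif(1, 0, pi)), cos(runif(1, 0, pi))),
        wy = c(sin(runif(1, 0, pi)), sin(runif(1, 0, pi))),
        lambda = runif(2, 3, 7),
        phase = runif(2, 0, 2 * pi)
      )
    )

    n <- config$n_plants
    margin <- min(0.3, W / 4, L / 4)
    xs <- numeric(0); ys <- numeric(0)
    attempts <- 0L
    max_attempts <- max(2000L, 400L * max(n, 1L))
    while (length(xs) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "could not place %d plants with min_spacing_m = %.2f in a %.0fx%.0f plot",
          n, config$min_spacing_m, W, L))
      }
      cx <- runif(1, margin, W - margin)
      cy <- runif(1, margin, L - margin)
      if (length(xs) == 0 ||
          min((xs - cx)^2 + (ys - cy)^2) >= config$min_spacing_m^2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }

    dbh <- rnorm(n, config$dbh_mean_m, config$dbh_sd_m)
    dbh <- pmin(pmax(dbh, config$dbh_mean_m - 2.5 * config$dbh_sd_m),
                config$dbh_mean_m + 2.5 * config$dbh_sd_m)
    dbh <- pmax(dbh, 0.02)
    # allometric height: H ~ Hbar * (D / Dbar)^0.51 with lognormal residual
    rel_from_dbh <- 0.51 * config$dbh_sd_m / config$dbh_mean_m
    rel_target <- config$height_sd_m / config$height_mean_m
    sdlog <- sqrt(max(rel_target^2 - rel_from_dbh^2, 1e-6))
    height <- config$height_mean_m * (dbh / config$dbh_mean_m)^0.51 *
      rlnorm(n, 0, sdlog)
    height <- pmax(height, 1.5) # keep the breast-height slice meaningful

    lean_angle <- abs(rnorm(n, 0, config$lean_sd_deg)) * pi / 180
    lean_az <- runif(n, 0, 2 * pi)
    tip_mag <- pmax(rnorm(n, config$tip_sway_mean_m, config$tip_sway_mean_m / 3), 0)
    tip_az <- runif(n, 0, 2 * pi)

    plants <- tibble::tibble(
      id = seq_len(n),
      x = xs, y = ys,
      dbh_m = dbh,
      height_m = height,
      crown_radius_m = config$crown_radius_m * runif(n, 0.85, 1.15),
      crown_depth_frac = config$crown_depth_frac,
      lean_dx = tan(lean_angle) * cos(lean_az),
      lean_dy = tan(lean_angle) * sin(lean_az),
      tip_dx = tip_mag * cos(tip_az),
      tip_dy = tip_mag * sin(tip_az)
    )
    plants$apex_x <- plants$x + plants$lean_dx * plants$height_m + plants$tip_dx
    plants$apex_y <- plants$y + plants$lean_dy * plants$height_m + plants$tip_dy

    corners <- tibble::tibble(
      target_id = paste0("T", 1:4),
      x = c(0, W, W, 0), y = c(0, 0, L, L)
    )

    stand <- structure(
      list(plants = plants, ground = ground, corners = corners, config = config),
      class = "bamboo_stand"
    )
    stand$corners$z <- ground_height(stand, stand$corners$x, stand$corners$y)
    stand
  })
}

#' @export
print.bamboo_stand <- function(x, ...) {
  cat(sprintf(
    "# Synthetic bamboo stand: %d plants on %.0f x %.0f m, slope %.0f deg\n",
    nrow(x$plants), x$config$plot_size_m[1], x$config$plot_size_m[2],
    x$config$ground_slope_deg))
  if (nrow(x$plants) > 0) {
    cat(sprintf("#   DBH %.3f-%.3f m, height %.1f-%.1f m\n",
                min(x$plants$dbh_m), max(x$plants$dbh_m),
                min(x$plants$height_m), max(x$plants$height_m)))
  }
  invisible(x)
}

#' Evaluate the analytic ground surface of a stand
#'
#' @param stand a `bamboo_stand`.
#' @param x,y coordinates (m) in the projected frame.
#' @return ground elevation (m) at each (x, y).
#' @export
ground_height <- function(stand, x, y) {
  g <- stand$ground
  z <- g$z0 + g$gx * x + g$gy * y
  for (i in seq_len(nrow(g$bumps))) {
    b <- g$bumps[i, ]
    z <- z + b$amp * sin(2 * pi * (x * b$wx + y * b$wy) / b$lambda + b$phase)
  }
  z
}

#' Culm centreline and taper radius of a truth plant
#'
#' The culm rises from the surveyed base along a small constant lean; inside
#' the crown it bends quadratically towards the drooping tip. The taper
#' radius is DBH/2 below breast height (1.3 m) and decreases linearly to
#' zero at the apex. Exposed so tests can check rendered points against the
#' exact surface.
#'
#' @param stand a `bamboo_stand`.
#' @param id plant id.
#' @param h heights above the base (m), in `[0, height_m]`.
#' @return tibble with the centreline `x`, `y`, absolute `z` and taper
#'   `radius` at each `h`.
#' @export
culm_axis <- function(stand, id, h) {
  p <- stand$plants[stand$plants$id == id, ]
  if (nrow(p) != 1) abort(sprintf("no plant with id %s", id))
  H <- p$height_m
  h <- pmin(pmax(h, 0), H)
  crown_base <- H * (1 - p$crown_depth_frac)
  bend <- ifelse(h <= crown_base, 0,
                 ((h - crown_base) / (H - crown_base))^2)
  base_z <- ground_height(stand, p$x, p$y)
  r0 <- p$dbh_m / 2
  radius <- if (H > 1.3) {
    ifelse(h <= 1.3, r0, r0 * (H - h) / (H - 1.3))
  } else {
    rep(r0, length(h))
  }
  tibble::tibble(
    h = h,
    x = p$x + p$lean_dx * h + p$tip_dx * bend,
    y = p$y + p$lean_dy * h + p$tip_dy * bend,
    z = base_z + h,
    radius = pmax(radius, 0)
  )
}

#' Configure a simulated laser scanner
#'
#' Sampling is modelled per surface class: candidate points are drawn on the
#' culm taper surface, the crown shell and the ground at the given surface
#' densities, then thinned by a logistic retention profile in normalized
#' height u = h/H. For ALS (top-down scanning) retention rises with height,
#' so crowns are dense and culms sparse; for TLS (bottom-up) it falls with
#' height, so culms are dense and crown tops sparse. TLS culms additionally
#' carry an azimuthal shadow (arc facing away from the plot centre) because
#' a culm hides its far side from the scanner.
#'
#' @param mode `"als"` or `"tls"`.
#' @param culm_density_pts_per_m2 candidate density on culm surfaces.
#' @param crown_density_pts_per_m2 candidate density on crown shells.
#' @param ground_density_pts_per_m2 point density on the ground.
#' @param noise_sd_m isotropic Gaussian coordinate noise (m).
#' @param ret_midpoint,ret_scale,ret_min,ret_max logistic retention profile
#'   parameters (in normalized height).
#' @param azimuth_gap_deg width of the unobserved azimuth arc on each culm
#'   (degrees; TLS only).
#' @param leaf_occlusion_prob probability that a culm carries a local leaf
#'   cluster blocking an additional azimuth arc of its surface within
#'   `leaf_occlusion_band_m` (TLS only; low branches and leaves shade
#'   patches of the culm near breast height).
#' @param leaf_occlusion_band_m height band affected by the leaf cluster.
#' @param top_ceiling_range for bottom-up scanning, each plant's returns cut
#'   off above a per-plant ceiling drawn uniformly from this range of
#'   normalized height (the beam rarely reaches the outer canopy through
#'   the foliage below it); `NULL` disables the ceiling.
#' @param seed integer seed for the renderer.
#' @return a `scanner_config` list.
#' @export
scanner_config <- function(mode = c("als", "tls"),
                           culm_density_pts_per_m2 = NULL,
                           crown_density_pts_per_m2 = NULL,
                           ground_density_pts_per_m2 = NULL,
                           noise_sd_m = NULL,
                           ret_midpoint = NULL, ret_scale = NULL,
                           ret_min = NULL, ret_max = 1,
                           azimuth_gap_deg = NULL,
                           leaf_occlusion_prob = NULL,
                           leaf_occlusion_band_m = c(1.0, 1.6),
                           top_ceiling_range = NULL,
                           seed = 1L) {
  mode <- match.arg(mode)
  def <- if (mode == "als") {
    list(culm = 2000, crown = 65, ground = 90, noise = 0.01,
         mid = 0.60, scale = 0.15, min = 0.04, gap = 0, leaf = 0,
         ceiling = NULL)
  } else {
    # bottom-up scanning: dense culms, upper canopy sparse to empty
    list(culm = 2000, crown = 65, ground = 400, noise = 0.003,
         mid = 0.65, scale = 0.07, min = 0.005, gap = 120, leaf = 0.5,
         ceiling = c(0.85, 0.95))
  }
  cfg <- list(
    mode = mode,
    culm_density_pts_per_m2 = culm_density_pts_per_m2 %||% def$culm,
    crown_density_pts_per_m2 = crown_density_pts_per_m2 %||% def$crown,
    ground_density_pts_per_m2 = ground_density_pts_per_m2 %||% def$ground,
    noise_sd_m = noise_sd_m %||% def$noise,
    ret_midpoint = ret_midpoint %||% def$mid,
    ret_scale = ret_scale %||% def$scale,
    ret_min = ret_min %||% def$min,
    ret_max = ret_max,
    azimuth_gap_deg = azimuth_gap_deg %||% def$gap,
    leaf_occlusion_prob = leaf_occlusion_prob %||% def$leaf,
    leaf_occlusion_band_m = leaf_occlusion_band_m,
    top_ceiling_range = top_ceiling_range %||% def$ceiling,
    seed = as.integer(seed)
  )
  if (cfg$culm_density_pts_per_m2 < 0 || cfg$crown_density_pts_per_m2 < 0 ||
      cfg$ground_density_pts_per_m2 < 0) abort("densities must be >= 0")
  if (cfg$noise_sd_m < 0) abort("noise_sd_m must be >= 0")
  structure(cfg, class = "scanner_config")
}

# retention probability at normalized height u for a scanner
retention_prob <- function(scanner, u) {
  p <- stats::plogis((u - scanner$ret_midpoint) / scanner$ret_scale)
  if (scanner$mode == "tls") p <- 1 - p
  scanner$ret_min + (scanner$ret_max - scanner$ret_min) * p
}

# draw candidate points on one plant's culm surface
sample_culm_surface <- function(stand, plant, scanner, centre_xy,
                                ceiling = 1) {
  H <- plant$height_m
  r0 <- plant$dbh_m / 2
  lower <- min(1.3, H)
  area <- 2 * pi * r0 * (lower + max(H - lower, 0) / 2)
  gap_frac <- scanner$azimuth_gap_deg / 360
  n_cand <- stats::rpois(1, area * scanner$culm_density_pts_per_m2 * (1 - gap_frac))
  if (n_cand == 0) return(NULL)
  # height density proportional to taper radius: rejection from uniform
  h <- runif(3 * n_cand + 20, 0, H)
  r_rel <- ifelse(h <= lower, 1, (H - h) / max(H - lower, 1e-9))
  h <- h[runif(length(h)) < r_rel][seq_len(n_cand)]
  h <- h[!is.na(h)]
  if (length(h) == 0) return(NULL)
  # azimuthal shadow faces away from the scanner (plot centre)
  if (gap_frac > 0) {
    shadow <- atan2(plant$y - centre_xy[2], plant$x - centre_xy[1])
    half <- scanner$azimuth_gap_deg / 2 * pi / 180
    span <- 2 * pi - 2 * half
    phi <- shadow + half + runif(length(h), 0, span)
  } else {
    phi <- runif(length(h), 0, 2 * pi)
  }
  ax <- culm_axis(stand, plant$id, h)
  keep <- runif(length(h)) < retention_prob(scanner, h / H) & h <= ceiling * H
  # local leaf cluster shading an extra azimuth arc near breast height
  if (scanner$leaf_occlusion_prob > 0 &&
      runif(1) < scanner$leaf_occlusion_prob) {
    occ_centre <- runif(1, 0, 2 * pi)
    occ_half <- runif(1, 45, 90) * pi / 180
    band <- scanner$leaf_occlusion_band_m
    dphi <- abs(((phi - occ_centre + pi) %% (2 * pi)) - pi)
    keep <- keep & !(h >= band[1] & h < band[2] & dphi <= occ_half)
  }
  if (!any(keep)) return(NULL)
  tibble::tibble(
    x = (ax$x + ax$radius * cos(phi))[keep],
    y = (ax$y + ax$radius * sin(phi))[keep],
    z = ax$z[keep],
    plant_id = plant$id,
    truth_class = "culm"
  )
}

# draw candidate points on one plant's crown. Bamboo foliage hangs on
# branches that emerge from nodes along the culm, so the crown is sampled
# as filaments radiating from the culm axis out to a half-ellipsoid
# envelope, plus a foliage tuft at the drooping tip. The envelope gives the
# crown-gap structure top-down segmentation exploits; the filaments carry
# the within-plant connectivity path-based crown assignment exploits.
sample_crown_surface <- function(stand, plant, scanner, ceiling = 1) {
  H <- plant$height_m
  a <- plant$crown_radius_m
  cdepth <- plant$crown_depth_frac * H
  crown_base <- H - cdepth
  # Thomsen approximation of the envelope (half-ellipsoid) surface area
  p <- 1.6075
  S <- 4 * pi * ((2 * a^p * cdepth^p + a^(2 * p)) / 3)^(1 / p) / 2
  n_cand <- stats::rpois(1, S * scanner$crown_density_pts_per_m2)
  if (n_cand == 0) return(NULL)
  n_tuft <- round(0.15 * n_cand)
  n_body <- n_cand - n_tuft

  n_br <- 12L + stats::rpois(1, 8)
  node_h <- runif(n_br, crown_base, crown_base + 0.85 * cdepth)
  phi_b <- runif(n_br, 0, 2 * pi)
  relh <- (node_h - crown_base) / cdepth
  r_tip <- a * sqrt(pmax(1 - relh^2, 0.04)) * runif(n_br, 0.75, 1.05)
  lift <- cdepth * runif(n_br, 0.05, 0.2) # branches arch slightly upward

  x <- numeric(0); y <- numeric(0); h <- numeric(0)
  if (n_body > 0) {
    br <- sample.int(n_br, n_body, replace = TRUE)
    t_ <- sqrt(runif(n_body)) # foliage concentrates towards branch tips
    ax <- culm_axis(stand, plant$id, node_h[br])
    jit <- 0.08
    x <- ax$x + t_ * r_tip[br] * cos(phi_b[br]) + rnorm(n_body, 0, jit)
    y <- ax$y + t_ * r_tip[br] * sin(phi_b[br]) + rnorm(n_body, 0, jit)
    h <- node_h[br] + t_ * lift[br] + rnorm(n_body, 0, jit)
  }
  if (n_tuft > 0) {
    x <- c(x, plant$apex_x + rnorm(n_tuft, 0, 0.12))
    y <- c(y, plant$apex_y + rnorm(n_tuft, 0, 0.12))
    h <- c(h, H - abs(rnorm(n_tuft, 0, 0.12)))
  }
  h <- pmin(h, H)
  base_z <- ground_height(stand, plant$x, plant$y)
  keep <- runif(length(h)) < retention_prob(scanner, h / H) & h <= ceiling * H
  if (!any(keep)) return(NULL)
  tibble::tibble(
    x = x[keep], y = y[keep], z = base_z + h[keep],
    plant_id = plant$id,
    truth_class = "crown"
  )
}

sample_ground_points <- function(stand, scanner) {
  W <- stand$config$plot_size_m[1]
  L <- stand$config$plot_size_m[2]
  pad <- 0.5
  n <- stats::rpois(1, (W + 2 * pad) * (L + 2 * pad) *
                      scanner$ground_density_pts_per_m2)
  if (n == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          plant_id = integer(), truth_class = character()))
  }
  x <- runif(n, -pad, W + pad)
  y <- runif(n, -pad, L + pad)
  tibble::tibble(x = x, y = y, z = ground_height(stand, x, y),
                 plant_id = NA_integer_, truth_class = "ground")
}

render_cloud <- function(stand, scanner) {
  withr::with_seed(scanner$seed, {
    centre <- stand$config$plot_size_m / 2
    n_pl <- nrow(stand$plants)
    ceilings <- if (is.null(scanner$top_ceiling_range)) {
      rep(1, n_pl)
    } else {
      runif(n_pl, scanner$top_ceiling_range[1], scanner$top_ceiling_range[2])
    }
    parts <- list(sample_ground_points(stand, scanner))
    for (i in seq_len(n_pl)) {
      plant <- stand$plants[i, ]
      parts <- c(parts,
                 list(sample_culm_surface(stand, plant, scanner, centre,
                                          ceilings[i])),
                 list(sample_crown_surface(stand, plant, scanner,
                                           ceilings[i])))
    }
    pts <- dplyr::bind_rows(parts)
    if (nrow(pts) > 0 && scanner$noise_sd_m > 0) {
      pts$x <- pts$x + rnorm(nrow(pts), 0, scanner$noise_sd_m)
      pts$y <- pts$y + rnorm(nrow(pts), 0, scanner$noise_sd_m)
      pts$z <- pts$z + rnorm(nrow(pts), 0, scanner$noise_sd_m)
    }
    pts$source <- scanner$mode
    pts
  })
}

#' Render an airborne (ALS) point cloud of a stand
#'
#' Produces a cloud in the projected frame with the canopy-dominated vertical
#' sampling profile of drone LiDAR over bamboo: dense crown shells, a sparse
#' culm layer shadowed by the canopy, and ground returns.
#'
#' @param stand a `bamboo_stand` from [generate_stand()].
#' @param scanner an ALS [scanner_config()].
#' @return a `bamboo_cloud` with truth columns `plant_id` and `truth_class`
#'   (for validation only; the pipeline never reads them).
#' @export
render_als <- function(stand, scanner = scanner_config("als")) {
  stopifnot(inherits(stand, "bamboo_stand"))
  if (scanner$mode != "als") abort("scanner mode must be 'als'")
  point_cloud(render_cloud(stand, scanner), frame = "projected")
}

#' Render a terrestrial (TLS) point cloud and its control points
#'
#' Produces a cloud in a local scanner frame obtained by pulling the
#' projected frame through the inverse of `true_transform`. Culms are densely
#' sampled (with an azimuthal shadow per culm), crown tops are sparse, and
#' the four plot-corner targets are returned as control pairs: exact local
#' coordinates against projected coordinates perturbed by GNSS-like noise.
#'
#' @param stand a `bamboo_stand`.
#' @param scanner a TLS [scanner_config()].
#' @param true_transform the [helmert_transform()] relating the local frame
#'   to the projected frame (local -> projected).
#' @param control_noise_sd_m sd of the Gaussian noise on the projected
#'   control coordinates (m), emulating RTK error under canopy.
#' @return list with `cloud` (local-frame `bamboo_cloud`) and `control`
#'   (tibble: target_id, local_x/y/z, proj_x/y/z).
#' @export
render_tls <- function(stand, scanner = scanner_config("tls"),
                       true_transform = helmert_transform(),
                       control_noise_sd_m = 0) {
  stopifnot(inherits(stand, "bamboo_stand"))
  if (scanner$mode != "tls") abort("scanner mode must be 'tls'")
  pts <- render_cloud(stand, scanner)
  local <- helmert_coords(as.matrix(pts[, c("x", "y", "z")]),
                          true_transform, inverse = TRUE)
  pts$x <- local[, 1]; pts$y <- local[, 2]; pts$z <- local[, 3]
  corners <- stand$corners
  local_c <- helmert_coords(as.matrix(corners[, c("x", "y", "z")]),
                            true_transform, inverse = TRUE)
  control <- withr::with_seed(scanner$seed + 1L, tibble::tibble(
    target_id = corners$target_id,
    local_x = local_c[, 1], local_y = local_c[, 2], local_z = local_c[, 3],
    proj_x = corners$x + rnorm(nrow(corners), 0, control_noise_sd_m),
    proj_y = corners$y + rnorm(nrow(corners), 0, control_noise_sd_m),
    proj_z = corners$z + rnorm(nrow(corners), 0, control_noise_sd_m)
  ))
  list(cloud = point_cloud(pts, frame = "local"), control = control)
}

#' Reference inventory of a synthetic stand
#'
#' The truth table in the layout of a field survey: one row per plant with
#' the surveyed base position, DBH and height.
#'
#' @param stand a `bamboo_stand`.
#' @return tibble with `plant_id`, `x`, `y`, `dbh_m`, `height_m`.
#' @export
stand_inventory <- function(stand) {
  tibble::tibble(
    plant_id = stand$plants$id,
    x = stand$plants$x, y = stand$plants$y,
    dbh_m = stand$plants$dbh_m, height_m = stand$plants$height_m
  )
}
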
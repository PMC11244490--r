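# shared fixtures: small, fast stand/scanner configurations for unit tests
# (acceptance tests use the package defaults, i.e. the full study conditions)

`%||%` <- function(a, b) if (is.null(a)) b else a

small_stand <- function(n = 6, seed = 7, spacing = 2.8, ...) {
  generate_stand(stand_config(n_plants = n, min_spacing_m = spacing,
                              dbh_mean_m = 0.10, dbh_sd_m = 0.005,
                              seed = seed, ...))
}

# reduced-density scanners so unit tests stay fast; culm density is kept high
# enough that the clustering thresholds scale simply (~1/4 of the default)
fast_als <- function(seed = 11, ...) {
  scanner_config("als", culm_density_pts_per_m2 = 500,
                 crown_density_pts_per_m2 = 30,
                 ground_density_pts_per_m2 = 40, seed = seed, ...)
}

fast_tls <- function(seed = 12, ...) {
  scanner_config("tls", culm_density_pts_per_m2 = 800,
                 crown_density_pts_per_m2 = 30,
                 ground_density_pts_per_m2 = 120,
                 leaf_occlusion_prob = 0, seed = seed, ...)
}

# min_points matched to fast_tls culm density: 0.28 m2 of band surface after
# the azimuthal shadow at 800 pts/m2 gives ~220 points per culm
fast_min_points <- 120

# cylinder slice sampler used as an exact-surface oracle
cylinder_slice <- function(n = 200, radius = 0.045, centre = c(2, 3),
                           z_range = c(1.2, 1.4), axis = c(0, 0, 1),
                           arc = c(0, 2 * pi), noise_sd = 0) {
  phi <- runif(n, arc[1], arc[2])
  t_ <- runif(n, -diff(z_range) / 2, diff(z_range) / 2)
  axis <- axis / sqrt(sum(axis^2))
  # orthonormal frame around the axis
  e1 <- c(axis[3], 0, -axis[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  c0 <- c(centre[1], centre[2], mean(z_range))
  pts <- t(c0 + t(outer(t_, axis) + radius * cos(phi) %o% e1 +
                    radius * sin(phi) %o% e2))
  pts <- pts + matrix(rnorm(3 * n, 0, noise_sd), ncol = 3)
  tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3])
}

# run the full default pipeline for a preset once per session and cache it
preset_run <- local({
  cache <- new.env(parent = emptyenv())
  function(preset = c("A1", "A2", "A3")) {
    preset <- match.arg(preset)
    if (is.null(cache[[preset]])) {
      n <- c(A1 = 37L, A2 = 45L, A3 = 52L)[[preset]]
      seed <- c(A1 = 101L, A2 = 102L, A3 = 103L)[[preset]]
      cache[[preset]] <- suppressWarnings(run_pipeline(
        pipeline_config(seed = seed, stand = stand_config(n_plants = n))))
    }
    cache[[preset]]
  }
})

# per-plant trait errors of one run (matched plants only)
trait_errors <- function(run, src, trait = c("height", "dbh")) {
  trait <- match.arg(trait)
  inv <- run$inventory
  summ <- run$summaries[[src]]
  m <- match_detections(summ, inv,
                        location = if (src == "als") "apex" else "base",
                        plot_area_m2 = 100)
  ref_col <- if (trait == "height") "height_m" else "dbh_m"
  ref <- inv[[ref_col]][match(m$pairs$plant_id, inv$plant_id)]
  est <- if (trait == "height") {
    summ$height_m[match(m$pairs$segment_id, summ$segment_id)]
  } else {
    dbh <- estimate_dbh(run$segments[[src]])
    dbh$dbh_m[match(m$pairs$segment_id, dbh$segment_id)]
  }
  (est - ref)[is.finite(est) & is.finite(ref)]
}
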
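#' Classify ground points by progressive TIN densification
#'
#' Classical progressive TIN densification: the lowest point of each coarse
#' seed-grid cell seeds a ground triangulation, then candidate points are
#' added iteratively when their vertical distance to the containing facet
#' and their angles to the facet vertices fall below thresholds. To keep the
#' triangulation small, densification runs on a spatially thinned candidate
#' set (the lowest point per fine cell, which is where ground returns live);
#' the final TIN then classifies every point of the cloud by its vertical
#' distance to the facet.
#'
#' @param cloud a `bamboo_cloud` in the projected frame, nonempty.
#' @param seed_cell_m seed-grid cell size (m): the initial terrain scale.
#' @param dist_threshold_m maximum vertical distance to the facet for a
#'   candidate to be accepted as ground during densification (m).
#' @param angle_threshold_deg maximum angle between the facet plane and the
#'   lines to the facet vertices (degrees).
#' @param mask_threshold_m final classification band: a point within this
#'   vertical distance of the densified TIN is labelled ground (m).
#' @param thin_cell_m fine-grid size for the candidate thinning (m).
#' @param max_iter densification iteration cap.
#' @return the cloud with a `classification` column (2 = ground,
#'   1 = non-ground) and attribute `ground_tin` (vertices + triangles).
#' @export
classify_ground <- function(cloud, seed_cell_m = 2, dist_threshold_m = 0.3,
                            angle_threshold_deg = 8, mask_threshold_m = 0.15,
                            thin_cell_m = 0.25, max_iter = 20) {
  cloud <- as_point_cloud(cloud)
  stopifnot_frame(cloud, "projected")
  if (nrow(cloud) == 0) abort("cannot classify an empty cloud")
  m <- coords_matrix(cloud)

  lowest_per_cell <- function(cell) {
    key <- paste(floor(m[, 1] / cell), floor(m[, 2] / cell))
    idx <- seq_len(nrow(m))
    split_idx <- split(idx, key)
    vapply(split_idx, function(i) i[which.min(m[i, 3])], integer(1))
  }

  cand <- sort(unname(lowest_per_cell(thin_cell_m)))
  seeds <- unique(unname(lowest_per_cell(seed_cell_m)))
  if (length(seeds) < 3) {
    abort(paste0("cloud covers fewer than 3 seed cells of ", seed_cell_m,
                 " m; cannot build a terrain TIN"))
  }
  # drop duplicated xy (degenerate for the triangulation)
  dedup <- function(ii) ii[!duplicated(m[ii, 1:2, drop = FALSE])]
  ground <- dedup(sort(seeds))
  cand <- setdiff(cand, ground)

  # virtual corner vertices keep the TIN hull covering the full extent, so
  # densification can reach border points above the outermost seeds; their
  # elevation tracks the nearest accepted ground point
  pad <- thin_cell_m
  xr <- range(m[, 1]); yr <- range(m[, 2])
  virt_xy <- cbind(c(xr[1] - pad, xr[2] + pad, xr[2] + pad, xr[1] - pad),
                   c(yr[1] - pad, yr[1] - pad, yr[2] + pad, yr[2] + pad))
  tin_of <- function(ground) {
    nn <- cpp_knn(m[ground, 1:2, drop = FALSE], virt_xy, 1L)
    gm <- rbind(m[ground, , drop = FALSE],
                cbind(virt_xy, m[ground[nn$idx[, 1]], 3]))
    list(vertices = gm, triangles = cpp_delaunay(gm[, 1:2, drop = FALSE]))
  }

  tan_thresh <- tan(angle_threshold_deg * pi / 180)
  tin <- tin_of(ground)
  for (iter in seq_len(max_iter)) {
    if (nrow(tin$triangles) == 0 || length(cand) == 0) break
    th <- cpp_tin_height(tin$vertices, tin$triangles,
                         m[cand, 1:2, drop = FALSE])
    dz <- m[cand, 3] - th$height
    inside <- !is.na(th$height)
    accept <- inside & dz < 0 & -dz < dist_threshold_m
    up <- which(inside & dz >= 0 & dz < dist_threshold_m)
    if (length(up) > 0) {
      # angle test against the three facet vertices
      ok <- rep(TRUE, length(up))
      for (j in 1:3) {
        v <- tin$vertices[tin$triangles[th$triangle[up], j], , drop = FALSE]
        dh <- sqrt((m[cand[up], 1] - v[, 1])^2 + (m[cand[up], 2] - v[, 2])^2)
        ok <- ok & (dz[up] <= tan_thresh * pmax(dh, 1e-6))
      }
      accept[up[ok]] <- TRUE
    }
    if (!any(accept, na.rm = TRUE)) break
    new_pts <- dedup(c(ground, cand[which(accept)]))
    added <- setdiff(new_pts, ground)
    if (length(added) == 0) break
    ground <- sort(new_pts)
    cand <- setdiff(cand, ground)
    tin <- tin_of(ground)
  }

  th_all <- cpp_tin_height(tin$vertices, tin$triangles, m[, 1:2, drop = FALSE])
  surf <- th_all$height
  # numerically outside even the padded hull: nearest TIN vertex
  out <- which(is.na(surf))
  if (length(out) > 0) {
    nn <- cpp_knn(m[ground, 1:2, drop = FALSE], m[out, 1:2, drop = FALSE], 1L)
    surf[out] <- m[ground[nn$idx[, 1]], 3]
  }
  is_ground <- abs(m[, 3] - surf) <= mask_threshold_m

  res <- tibble::as_tibble(cloud)
  res$classification <- ifelse(is_ground, 2L, 1L)
  res <- restore_cloud(res, cloud)
  attr(res, "ground_tin") <- tin
  res
}

#' Build a digital elevation model from classified ground points
#'
#' Grids the mean ground elevation on square cells; cells without ground
#' points are filled from the nearest populated cell so every in-extent cell
#' carries an elevation.
#'
#' @param cloud a cloud with a `classification` column (2 = ground), or any
#'   cloud whose every point should be treated as ground.
#' @param cell_size_m grid resolution (m).
#' @return a `bamboo_dem`: list with `origin`, `cell_size_m`, `nrow`,
#'   `ncol`, elevation matrix `z` (rows = y index) and logical `filled`.
#' @export
build_dem <- function(cloud, cell_size_m = 0.5) {
  cloud <- as_point_cloud(cloud)
  if (cell_size_m <= 0) abort("cell_size_m must be > 0")
  df <- tibble::as_tibble(cloud)
  if ("classification" %in% names(df)) {
    df <- df[df$classification == 2L, , drop = FALSE]
  }
  if (nrow(df) == 0) abort("no ground points to grid")
  origin <- c(floor(min(df$x) / cell_size_m) * cell_size_m,
              floor(min(df$y) / cell_size_m) * cell_size_m)
  ix <- floor((df$x - origin[1]) / cell_size_m) + 1
  iy <- floor((df$y - origin[2]) / cell_size_m) + 1
  ncol_ <- max(ix); nrow_ <- max(iy)
  lin <- iy + (ix - 1) * nrow_
  agg <- rowsum(cbind(df$z, 1), lin)
  z <- matrix(NA_real_, nrow_, ncol_)
  z[as.integer(rownames(agg))] <- agg[, 1] / agg[, 2]
  filled <- is.na(z)
  if (any(filled)) {
    have <- which(!filled, arr.ind = TRUE)
    need <- which(filled, arr.ind = TRUE)
    centres <- function(idx) cbind(origin[1] + (idx[, 2] - 0.5) * cell_size_m,
                                   origin[2] + (idx[, 1] - 0.5) * cell_size_m)
    nn <- cpp_knn(centres(have), centres(need), 1L)
    z[need] <- z[have[nn$idx[, 1], , drop = FALSE]]
  }
  structure(list(origin = origin, cell_size_m = cell_size_m,
                 nrow = nrow_, ncol = ncol_, z = z, filled = filled),
            class = "bamboo_dem")
}

#' @export
print.bamboo_dem <- function(x, ...) {
  cat(sprintf("# DEM: %d x %d cells of %.2f m, elevation %.2f-%.2f m\n",
              x$nrow, x$ncol, x$cell_size_m, min(x$z), max(x$z)))
  invisible(x)
}

#' Look up DEM elevations (nearest cell)
#'
#' @param dem a `bamboo_dem`.
#' @param x,y coordinates (m).
#' @param warn_outside warn when points fall outside the DEM footprint (they
#'   use the nearest edge cell).
#' @return elevations (m).
#' @export
dem_elevation <- function(dem, x, y, warn_outside = TRUE) {
  ix <- floor((x - dem$origin[1]) / dem$cell_size_m) + 1
  iy <- floor((y - dem$origin[2]) / dem$cell_size_m) + 1
  outside <- ix < 1 | ix > dem$ncol | iy < 1 | iy > dem$nrow
  if (any(outside) && warn_outside) {
    warn(sprintf("%d point(s) outside the DEM footprint use the nearest cell",
                 sum(outside)))
  }
  ix <- pmin(pmax(ix, 1), dem$ncol)
  iy <- pmin(pmax(iy, 1), dem$nrow)
  dem$z[cbind(iy, ix)]
}

#' Normalize point heights against a DEM
#'
#' Subtracts the DEM elevation of the containing cell from each point's
#' elevation, turning `z` into height above ground; `x` and `y` are
#' untouched, so the operation is inverted by adding the DEM back.
#'
#' @param cloud a `bamboo_cloud` in the projected frame.
#' @param dem a `bamboo_dem`.
#' @return the cloud with normalized `z` and the `normalized` flag set.
#' @export
normalize_heights <- function(cloud, dem) {
  cloud <- as_point_cloud(cloud)
  stopifnot(inherits(dem, "bamboo_dem"))
  if (is_normalized(cloud)) {
    warn("cloud is already normalized; returning unchanged")
    return(cloud)
  }
  out <- tibble::as_tibble(cloud)
  if (nrow(out) > 0) {
    out$z <- out$z - dem_elevation(dem, out$x, out$y)
  }
  new_point_cloud(out, cloud_frame(cloud), normalized = TRUE)
}

#' @rdname normalize_heights
#' @export
denormalize_heights <- function(cloud, dem) {
  cloud <- as_point_cloud(cloud)
  if (!is_normalized(cloud)) abort("cloud is not normalized")
  out <- tibble::as_tibble(cloud)
  if (nrow(out) > 0) {
    out$z <- out$z + dem_elevation(dem, out$x, out$y, warn_outside = FALSE)
  }
  new_point_cloud(out, cloud_frame(cloud), normalized = FALSE)
}

#' @export
tidy.bamboo_dem <- function(x, ...) {
  idx <- expand.grid(row = seq_len(x$nrow), col = seq_len(x$ncol))
  cx <- x$origin[1] + (idx$col - 0.5) * x$cell_size_m
  cy <- x$origin[2] + (idx$row - 0.5) * x$cell_size_m
  elev <- as.vector(x$z)
  fil <- as.vector(x$filled)
  tibble::tibble(x = cx, y = cy, elevation = elev, filled = fil)
}

#' @export
autoplot.bamboo_dem <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y, fill = .data$elevation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "elevation (m)") +
    ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Write / read a DEM as an ESRI ASCII grid
#'
#' @param dem a `bamboo_dem`.
#' @param path output path.
#' @export
write_dem_ascii <- function(dem, path) {
  hdr <- c(
    sprintf("ncols %d", dem$ncol),
    sprintf("nrows %d", dem$nrow),
    sprintf("xllcorner %.6f", dem$origin[1]),
    sprintf("yllcorner %.6f", dem$origin[2]),
    sprintf("cellsize %.6f", dem$cell_size_m),
    "NODATA_value -9999"
  )
  rows <- apply(dem$z[dem$nrow:1, , drop = FALSE], 1,
                function(r) paste(sprintf("%.4f", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
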
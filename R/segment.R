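#' Segment individual plants by top-down region growing (PCS)
#'
#' The point-cloud segmentation (PCS) strategy for canopy-dominated airborne
#' data: the globally highest point becomes the vertex (apex) of the first
#' plant, and the sweep proceeds downwards comparing each point's horizontal
#' distances to the vertices of the plants found so far. A point joins the
#' plant with the nearest vertex; a point farther than the spacing threshold
#' `d` from every vertex becomes the vertex of a new plant. The first
#' segment therefore always contains the global maximum. Points below
#' `min_z` (ground clutter and the culm layer, which airborne data barely
#' samples) are left unassigned.
#'
#' @param cloud a normalized `bamboo_cloud`.
#' @param d spacing threshold (m). Default NULL estimates the average plant
#'   spacing as sqrt(canopy area / number of detected canopy local maxima).
#' @param min_z minimum height above ground considered (m).
#' @param min_segment_size segments with fewer member points are dissolved
#'   (their points become unassigned); commission-prone fragments die here.
#' @return the cloud with a `segment_id` column (NA = unassigned); the
#'   threshold actually used is in attribute `pcs_d`.
#' @export
segment_pcs <- function(cloud, d = NULL, min_z = 2, min_segment_size = 50) {
  cloud <- as_point_cloud(cloud)
  if (!is_normalized(cloud)) abort("segment_pcs needs a height-normalized cloud")
  if (nrow(cloud) == 0) abort("cannot segment an empty cloud")
  df <- tibble::as_tibble(cloud)
  in_scope <- df$z >= min_z
  if ("classification" %in% names(df)) in_scope <- in_scope & df$classification != 2L
  if (!any(in_scope)) abort(paste0("no points above min_z = ", min_z, " m"))
  if (is.null(d)) d <- estimate_pcs_threshold(df[in_scope, ], min_z)
  if (d <= 0) abort("spacing threshold d must be > 0")

  idx <- which(in_scope)
  ord <- idx[order(-df$z[idx])]
  labels_sorted <- cpp_pcs_sweep(cbind(df$x[ord], df$y[ord]), d)

  seg <- rep(NA_integer_, nrow(df))
  seg[ord] <- labels_sorted
  seg <- drop_small_segments(seg, min_segment_size)

  out <- df
  out$segment_id <- as.integer(seg)
  out <- restore_cloud(out, cloud)
  attr(out, "pcs_d") <- d
  attr(out, "method") <- "pcs"
  out
}

# average-spacing heuristic: count local maxima of the 0.5 m canopy-top grid
estimate_pcs_threshold <- function(df, min_z) {
  cell <- 0.5
  ix <- floor(df$x / cell); iy <- floor(df$y / cell)
  key <- paste(ix, iy)
  top <- tapply(df$z, key, max)
  coords <- do.call(rbind, strsplit(names(top), " "))
  gx <- as.integer(coords[, 1]); gy <- as.integer(coords[, 2])
  lookup <- new.env()
  for (i in seq_along(top)) assign(paste(gx[i], gy[i]), top[[i]], envir = lookup)
  is_max <- vapply(seq_along(top), function(i) {
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      nb <- mget(paste(gx[i] + dx, gy[i] + dy), envir = lookup,
                 ifnotfound = list(-Inf))[[1]]
      if (nb > top[[i]]) return(FALSE)
    }
    TRUE
  }, logical(1))
  n_seeds <- max(sum(is_max), 1L)
  area <- diff(range(df$x)) * diff(range(df$y))
  max(sqrt(area / n_seeds), 1e-3)
}

drop_small_segments <- function(seg, min_segment_size) {
  if (all(is.na(seg))) return(structure(seg, kept_ids = integer()))
  sizes <- table(seg)
  keep_ids <- sort(as.integer(names(sizes)[sizes >= min_segment_size]))
  seg[!(seg %in% keep_ids)] <- NA_integer_
  # relabel consecutively, preserving the original ordering
  structure(as.integer(match(seg, keep_ids)), kept_ids = keep_ids)
}

#' Detect bamboo culms by density clustering
#'
#' Clusters the horizontal coordinates of points in the culm slice band
#' (below the living crown, above ground clutter) with DBSCAN. Dense
#' terrestrial sampling makes each culm a compact high-density cluster;
#' clusters below `min_points` dissolve into noise, which is why the sparse
#' airborne culm layer yields few or no culms.
#'
#' @param cloud a normalized `bamboo_cloud`.
#' @param min_points DBSCAN core threshold (points within the radius).
#' @param radius_m DBSCAN neighbourhood radius (m).
#' @param band_m culm slice band as `c(lower, upper)` height above ground.
#' @param on_empty `"error"` (default) or `"tolerate"`: behaviour when no
#'   cluster reaches `min_points`.
#' @return tibble with `culm_id`, `x`, `y` (cluster centroid) and
#'   `n_points`, ordered by first appearance.
#' @export
detect_culms <- function(cloud, min_points = 500, radius_m = 0.2,
                         band_m = c(0.5, 2.0), on_empty = c("error", "tolerate")) {
  cloud <- as_point_cloud(cloud)
  on_empty <- match.arg(on_empty)
  if (!is_normalized(cloud)) abort("detect_culms needs a height-normalized cloud")
  if (min_points < 1) abort("min_points must be >= 1")
  if (radius_m <= 0) abort("radius_m must be > 0")
  df <- tibble::as_tibble(cloud)
  sel <- df$z >= band_m[1] & df$z < band_m[2]
  if ("classification" %in% names(df)) sel <- sel & df$classification != 2L
  band <- df[sel, , drop = FALSE]
  empty_msg <- paste0(
    "no culm clusters found in the ", band_m[1], "-", band_m[2],
    " m band; review min_points/radius_m against this cloud's culm-layer density")
  if (nrow(band) == 0) {
    if (on_empty == "error") abort(empty_msg)
    return(tibble::tibble(culm_id = integer(), x = numeric(), y = numeric(),
                          n_points = integer()))
  }
  lab <- cpp_dbscan(cbind(band$x, band$y), radius_m, as.integer(min_points))
  if (all(lab == 0)) {
    if (on_empty == "error") abort(empty_msg)
    return(tibble::tibble(culm_id = integer(), x = numeric(), y = numeric(),
                          n_points = integer()))
  }
  hit <- lab > 0
  tibble::tibble(
    culm_id = sort(unique(lab[hit])),
  ) |>
    dplyr::mutate(
      x = tapply(band$x[hit], lab[hit], mean)[as.character(.data$culm_id)],
      y = tapply(band$y[hit], lab[hit], mean)[as.character(.data$culm_id)],
      n_points = as.integer(table(lab[hit])[as.character(.data$culm_id)])
    )
}

#' Segment individual plants by comparative shortest path (CSP)
#'
#' Culm-first segmentation for terrestrial and merged clouds: every
#' non-ground point is assigned to the culm it can reach by the shortest
#' path through the point cloud, the graph being a k-nearest-neighbour
#' graph over a voxel-thinned version of the cloud with Euclidean edge
#' weights. Crown points that interlock horizontally still route through
#' their own crown and culm, which is what makes the method robust where
#' nearest-culm assignment fails. Points unreachable from every culm fall
#' back to the horizontally nearest culm; ties break towards the lowest
#' culm id.
#'
#' @param cloud a normalized `bamboo_cloud`.
#' @param culms tibble from [detect_culms()], or NULL to detect here.
#' @param k neighbours per node in the path graph.
#' @param voxel_m voxel size for graph thinning (m).
#' @param min_points,radius_m,band_m forwarded to [detect_culms()].
#' @param min_segment_size segments with fewer member points dissolve.
#' @param min_z points below this height stay unassigned (ground clutter).
#' @return the cloud with a `segment_id` column; attribute `culms` maps
#'   segment ids to the culm positions that seeded them.
#' @export
segment_csp <- function(cloud, culms = NULL, k = 10, voxel_m = 0.05,
                        min_points = 500, radius_m = 0.2, band_m = c(0.5, 2.0),
                        min_segment_size = 50, min_z = 0.1) {
  cloud <- as_point_cloud(cloud)
  if (!is_normalized(cloud)) abort("segment_csp needs a height-normalized cloud")
  if (is.null(culms)) {
    culms <- detect_culms(cloud, min_points = min_points, radius_m = radius_m,
                          band_m = band_m)
  }
  if (nrow(culms) == 0) abort("segment_csp needs at least one culm cluster")
  df <- tibble::as_tibble(cloud)
  in_scope <- df$z >= min_z
  if ("classification" %in% names(df)) in_scope <- in_scope & df$classification != 2L
  idx <- which(in_scope)
  if (length(idx) == 0) abort("no non-ground points to segment")

  sub <- df[idx, c("x", "y", "z")]
  keep <- !duplicated(paste(floor(sub$x / voxel_m), floor(sub$y / voxel_m),
                            floor(sub$z / voxel_m)))
  nodes <- as.matrix(sub[keep, ])
  nn <- cpp_knn(nodes, nodes, as.integer(k + 1))

  n_nodes <- nrow(nodes)
  n_culms <- nrow(culms)
  from <- rep(seq_len(n_nodes), k)
  to <- as.vector(nn$idx[, -1, drop = FALSE])
  w <- as.vector(nn$dist[, -1, drop = FALSE])
  ok <- !is.na(to)
  from <- from[ok]; to <- to[ok]; w <- w[ok]

  # seed nodes: in the culm band and within the cluster radius of a culm
  in_band <- nodes[, 3] >= band_m[1] & nodes[, 3] < band_m[2]
  seed_edges_from <- integer(0)
  seed_edges_to <- integer(0)
  for (ci in seq_len(n_culms)) {
    d2 <- (nodes[, 1] - culms$x[ci])^2 + (nodes[, 2] - culms$y[ci])^2
    seeds <- which(in_band & d2 <= radius_m^2)
    if (length(seeds) == 0) seeds <- which.min(d2)
    seed_edges_from <- c(seed_edges_from, rep(n_nodes + ci, length(seeds)))
    seed_edges_to <- c(seed_edges_to, seeds)
  }

  g <- igraph::make_graph(rbind(c(from, seed_edges_from), c(to, seed_edges_to)),
                          n = n_nodes + n_culms, directed = FALSE)
  weights <- c(w, rep(1e-9, length(seed_edges_to)))
  dmat <- igraph::distances(g, v = n_nodes + seq_len(n_culms),
                            to = seq_len(n_nodes), weights = weights,
                            algorithm = "dijkstra")
  node_lab <- apply(dmat, 2, which.min) # ties -> lowest culm id
  unreach <- !is.finite(apply(dmat, 2, min))
  if (any(unreach)) {
    cx <- as.matrix(culms[, c("x", "y")])
    nnc <- cpp_knn(cx, nodes[unreach, 1:2, drop = FALSE], 1L)
    node_lab[unreach] <- nnc$idx[, 1]
  }

  # carry node labels back to every in-scope full-resolution point
  back <- cpp_knn(nodes, as.matrix(sub), 1L)
  seg <- rep(NA_integer_, nrow(df))
  seg[idx] <- as.integer(node_lab[back$idx[, 1]])
  seg <- drop_small_segments(seg, min_segment_size)

  kept_ids <- attr(seg, "kept_ids", exact = TRUE)
  out <- df
  out$segment_id <- as.integer(seg)
  out <- restore_cloud(out, cloud)
  # culm row i seeded pre-filter segment i; surviving segments were relabelled
  culm_map <- culms
  culm_map$segment_id <- match(seq_len(n_culms), kept_ids)
  attr(out, "culms") <- culm_map
  attr(out, "method") <- "csp"
  out
}

#' Double-pass CSP segmentation
#'
#' Runs culm detection and CSP assignment, then repeats culm detection
#' restricted to each first-pass segment and re-runs the assignment with
#' the enlarged culm set. Within an isolated segment the global noise floor
#' is unnecessary, so the restricted detection accepts clusters down to
#' half `min_points`; a culm that narrowly missed the global threshold (a
#' thin plant absorbed by its neighbour) is recovered and its segment
#' split. On stands where the first pass already finds every culm the
#' second pass is a fixed point.
#'
#' @inheritParams segment_csp
#' @return as [segment_csp()]; attribute `passes` records the culm count of
#'   each pass and `converged` whether the second pass changed anything.
#' @export
segment_csp_double <- function(cloud, k = 10, voxel_m = 0.05,
                               min_points = 500, radius_m = 0.2,
                               band_m = c(0.5, 2.0), min_segment_size = 50,
                               min_z = 0.1) {
  pass1 <- segment_csp(cloud, k = k, voxel_m = voxel_m,
                       min_points = min_points, radius_m = radius_m,
                       band_m = band_m, min_segment_size = min_segment_size,
                       min_z = min_z)
  culms1 <- attr(pass1, "culms")
  df <- tibble::as_tibble(pass1)
  culms2 <- list()
  for (sid in sort(unique(stats::na.omit(df$segment_id)))) {
    seg_cloud <- restore_cloud(df[!is.na(df$segment_id) & df$segment_id == sid, ],
                               pass1)
    found <- detect_culms(seg_cloud, min_points = max(ceiling(min_points / 2), 1),
                          radius_m = radius_m, band_m = band_m,
                          on_empty = "tolerate")
    if (nrow(found) == 0) {
      # keep the pass-1 culm for this segment
      found <- culms1[which(culms1$segment_id == sid), c("culm_id", "x", "y", "n_points")]
    }
    culms2[[length(culms2) + 1]] <- found
  }
  culms2 <- dplyr::bind_rows(culms2)
  if (nrow(culms2) == 0) culms2 <- culms1[, c("culm_id", "x", "y", "n_points")]
  culms2$culm_id <- seq_len(nrow(culms2))

  out <- segment_csp(cloud, culms = culms2, k = k, voxel_m = voxel_m,
                     band_m = band_m, radius_m = radius_m,
                     min_segment_size = min_segment_size, min_z = min_z)
  n1 <- length(unique(stats::na.omit(df$segment_id)))
  n2 <- length(unique(stats::na.omit(out$segment_id)))
  attr(out, "passes") <- c(pass1 = n1, pass2 = n2)
  attr(out, "converged") <- identical(df$segment_id,
                                      tibble::as_tibble(out)$segment_id)
  if (isTRUE(attr(out, "converged"))) {
    inform("second CSP pass changed nothing: segmentation converged")
  }
  attr(out, "method") <- "csp"
  out
}

#' Summarise a segmented cloud per plant
#'
#' One row per segment with the apex (highest member point), the plant
#' height (the apex's height above ground), the culm-base position (culm
#' centroid where CSP culms are attached to the result, otherwise the
#' horizontal position of the lowest member point) and the member count.
#'
#' @param cloud a segmented, normalized `bamboo_cloud`.
#' @return tibble with `segment_id`, `n_points`, `apex_x`, `apex_y`,
#'   `height_m`, `base_x`, `base_y`.
#' @export
segment_summary <- function(cloud) {
  df <- tibble::as_tibble(cloud)
  if (!"segment_id" %in% names(df)) abort("cloud has no segment_id column")
  df <- df[!is.na(df$segment_id), , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble(segment_id = integer(), n_points = integer(),
                          apex_x = numeric(), apex_y = numeric(),
                          height_m = numeric(), base_x = numeric(),
                          base_y = numeric()))
  }
  res <- df |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      apex_x = .data$x[which.max(.data$z)],
      apex_y = .data$y[which.max(.data$z)],
      height_m = max(.data$z),
      base_x = .data$x[which.min(.data$z)],
      base_y = .data$y[which.min(.data$z)],
      .groups = "drop"
    )
  culms <- attr(cloud, "culms")
  if (!is.null(culms) && "segment_id" %in% names(culms)) {
    cl <- culms[!is.na(culms$segment_id), , drop = FALSE]
    hit <- match(res$segment_id, cl$segment_id)
    res$base_x <- ifelse(is.na(hit), res$base_x, cl$x[hit])
    res$base_y <- ifelse(is.na(hit), res$base_y, cl$y[hit])
  }
  res
}

#' Plant height of one segment
#'
#' The vertical distance from the highest member point to the ground, i.e.
#' the maximum normalized height within the segment.
#'
#' @param cloud a segmented, normalized `bamboo_cloud`.
#' @param segment_id one segment id.
#' @return height in metres.
#' @export
extract_height <- function(cloud, segment_id) {
  df <- tibble::as_tibble(cloud)
  sel <- !is.na(df$segment_id) & df$segment_id == segment_id
  if (!any(sel)) abort(paste0("segment ", segment_id, " is empty or absent"))
  max(df$z[sel])
}
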
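#' Construct a point cloud tibble
#'
#' A point cloud is an ordinary tibble with numeric `x`, `y`, `z` columns
#' (metres) plus two attributes: the coordinate `frame` (`"local"` for raw
#' terrestrial scans, `"projected"` for the georeferenced frame shared with
#' airborne data) and a `normalized` flag set once `z` holds height above
#' ground rather than elevation. Optional columns travel with the points:
#' `classification` (ASPRS-style code, 2 = ground), `source` (`"als"` or
#' `"tls"`), `plant_id` (simulator ground-truth label) and `segment_id`
#' (assigned by segmentation). All tidyverse verbs work on it; use
#' [as_point_cloud()] to restore the metadata after manipulation.
#'
#' @param data data frame with at least `x`, `y`, `z` columns, or NULL for an
#'   empty cloud.
#' @param frame coordinate frame label, `"projected"` or `"local"`.
#' @param normalized logical; TRUE when `z` is height above ground.
#' @return a `bamboo_cloud` tibble.
#' @examples
#' pc <- point_cloud(data.frame(x = 0:2, y = 0, z = c(1, 5, 2)))
#' cloud_frame(pc)
#' @export
point_cloud <- function(data = NULL, frame = c("projected", "local"),
                        normalized = FALSE) {
  frame <- match.arg(frame)
  if (is.null(data)) {
    data <- tibble::tibble(x = numeric(), y = numeric(), z = numeric())
  }
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c("x", "y", "z"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("point cloud needs columns x, y, z; missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(vapply(data[c("x", "y", "z")], is.numeric, logical(1)))) {
    abort("x, y, z must be numeric")
  }
  coords <- as.matrix(data[, c("x", "y", "z")])
  if (nrow(data) > 0 && !all(is.finite(coords))) {
    bad <- which(rowSums(!is.finite(coords)) > 0)
    abort(paste0("non-finite coordinates at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else ""))
  }
  new_point_cloud(data, frame, normalized)
}

new_point_cloud <- function(data, frame, normalized) {
  structure(
    tibble::as_tibble(data),
    frame = frame,
    normalized = isTRUE(normalized),
    class = c("bamboo_cloud", class(tibble::tibble()))
  )
}

#' @rdname point_cloud
#' @param x object to convert or query.
#' @export
as_point_cloud <- function(x, frame = c("projected", "local"), normalized = FALSE) {
  if (inherits(x, "bamboo_cloud") && missing(frame) && missing(normalized)) return(x)
  if (inherits(x, "bamboo_cloud")) {
    if (missing(frame)) frame <- cloud_frame(x)
    if (missing(normalized)) normalized <- is_normalized(x)
  }
  point_cloud(x, frame = frame, normalized = normalized)
}

#' @rdname point_cloud
#' @export
cloud_frame <- function(x) attr(x, "frame") %||% "projected"

#' @rdname point_cloud
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# rebuild metadata after dplyr/tidyr calls stripped it
restore_cloud <- function(data, template) {
  new_point_cloud(data, cloud_frame(template), is_normalized(template))
}

coords_matrix <- function(cloud, dims = c("x", "y", "z")) {
  unname(as.matrix(as.data.frame(cloud)[, dims, drop = FALSE]))
}

#' @export
print.bamboo_cloud <- function(x, ...) {
  cat(sprintf("# Point cloud: %d points, frame = %s%s\n",
              nrow(x), cloud_frame(x),
              if (is_normalized(x)) ", normalized heights" else ""))
  NextMethod()
}

stopifnot_frame <- function(cloud, frame, what = "cloud") {
  if (!identical(cloud_frame(cloud), frame)) {
    abort(sprintf("%s must be in the '%s' frame, got '%s'",
                  what, frame, cloud_frame(cloud)))
  }
  invisible(cloud)
}

#' Merge two point clouds
#'
#' Concatenates two clouds in the same coordinate frame, preserving per-point
#' attributes. Missing optional columns are filled with NA so ALS and TLS
#' clouds with different column sets can be combined; `source` tags survive
#' and can be counted after the merge.
#'
#' @param a,b `bamboo_cloud` tibbles in the same frame.
#' @return the concatenated `bamboo_cloud`.
#' @export
merge_clouds <- function(a, b) {
  a <- as_point_cloud(a)
  b <- as_point_cloud(b, frame = cloud_frame(b), normalized = is_normalized(b))
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  if (!identical(cloud_frame(a), cloud_frame(b))) {
    abort(sprintf("cannot merge clouds in different frames ('%s' vs '%s')",
                  cloud_frame(a), cloud_frame(b)))
  }
  if (!identical(is_normalized(a), is_normalized(b))) {
    abort("cannot merge a normalized with a non-normalized cloud")
  }
  out <- dplyr::bind_rows(tibble::as_tibble(a), tibble::as_tibble(b))
  new_point_cloud(out, cloud_frame(a), is_normalized(a))
}

#' Thin a cloud on a regular voxel grid
#'
#' Keeps the first point falling in each cubic voxel; deterministic for a
#' fixed point order. Used to make the CSP path graph and ICP tractable on
#' dense terrestrial scans.
#'
#' @param cloud a `bamboo_cloud`.
#' @param voxel_m voxel edge length in metres.
#' @return the thinned cloud, plus an integer attribute `kept` with the row
#'   indices retained from the input.
#' @export
voxel_thin <- function(cloud, voxel_m = 0.05) {
  cloud <- as_point_cloud(cloud)
  if (voxel_m <= 0) abort("voxel_m must be > 0")
  if (nrow(cloud) == 0) return(cloud)
  m <- coords_matrix(cloud)
  ix <- floor(m[, 1] / voxel_m)
  iy <- floor(m[, 2] / voxel_m)
  iz <- floor(m[, 3] / voxel_m)
  key <- paste(ix, iy, iz)
  keep <- which(!duplicated(key))
  out <- restore_cloud(tibble::as_tibble(cloud)[keep, , drop = FALSE], cloud)
  attr(out, "kept") <- keep
  out
}

#' @export
autoplot.bamboo_cloud <- function(object, colour = c("z", "segment", "source"), ...) {
  colour <- match.arg(colour)
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- switch(colour,
    z = p + ggplot2::geom_point(ggplot2::aes(colour = .data$z), size = 0.3) +
      ggplot2::scale_colour_viridis_c(name = if (is_normalized(object)) "height (m)" else "z (m)"),
    segment = p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$segment_id)), size = 0.3, show.legend = FALSE),
    source = p + ggplot2::geom_point(ggplot2::aes(colour = .data$source), size = 0.3)
  )
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}
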
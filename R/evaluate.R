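#' Match detected plants to a reference inventory
#'
#' One-to-one matching between detected plant locations and surveyed
#' reference positions: candidate pairs within the distance threshold are
#' accepted globally nearest first, each detection and each reference
#' matching at most once. A matched detection is a correct detection (Nt);
#' an unmatched detection is a commission error (Nc); an unmatched
#' reference is an omission error (No). The default threshold is the
#' average plant spacing, sqrt(plot area / number of reference plants).
#'
#' @param detections tibble of detected plants; needs `segment_id` plus the
#'   location columns selected by `location` (`apex_x`/`apex_y` or
#'   `base_x`/`base_y`, as produced by [segment_summary()]).
#' @param reference inventory tibble (`plant_id`, `x`, `y`, ...).
#' @param threshold_m matching distance threshold (m); NULL = average
#'   spacing of the reference.
#' @param location which detected location to match on: the highest point
#'   of the segment (`"apex"`, the conventional choice) or the culm base
#'   (`"base"`).
#' @param plot_area_m2 plot area used for the default threshold; NULL =
#'   bounding-box area of the reference positions, or 100 for tiny n.
#' @return a `detection_match`: list with `pairs` (tibble: segment_id,
#'   plant_id, distance_m), counts `nt`, `nc`, `no`, and the threshold.
#' @export
match_detections <- function(detections, reference, threshold_m = NULL,
                             location = c("apex", "base"),
                             plot_area_m2 = NULL) {
  location <- match.arg(location)
  detections <- tibble::as_tibble(detections)
  reference <- validate_inventory(reference)
  xcol <- paste0(if (location == "apex") "apex" else "base", "_x")
  ycol <- paste0(if (location == "apex") "apex" else "base", "_y")
  if (!all(c(xcol, ycol) %in% names(detections))) {
    abort(paste0("detections need columns ", xcol, ", ", ycol))
  }
  n_det <- nrow(detections)
  n_ref <- nrow(reference)
  if (is.null(threshold_m)) {
    if (is.null(plot_area_m2)) {
      spanx <- diff(range(reference$x)); spany <- diff(range(reference$y))
      plot_area_m2 <- if (n_ref >= 4 && spanx > 0 && spany > 0) spanx * spany else 100
    }
    threshold_m <- sqrt(plot_area_m2 / max(n_ref, 1))
  }
  if (threshold_m <= 0) abort("threshold_m must be > 0")

  pairs <- tibble::tibble(segment_id = integer(), plant_id = reference$plant_id[0],
                          distance_m = numeric())
  if (n_det > 0 && n_ref > 0) {
    dx <- outer(detections[[xcol]], reference$x, "-")
    dy <- outer(detections[[ycol]], reference$y, "-")
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist <= threshold_m, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dist[cand], cand[, 1], cand[, 2]) # nearest first, stable
      cand <- cand[ord, , drop = FALSE]
      det_used <- rep(FALSE, n_det)
      ref_used <- rep(FALSE, n_ref)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        di <- cand[i, 1]; ri <- cand[i, 2]
        if (!det_used[di] && !ref_used[ri]) {
          det_used[di] <- TRUE
          ref_used[ri] <- TRUE
          keep[i] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- tibble::tibble(
        segment_id = detections$segment_id[cand[, 1]],
        plant_id = reference$plant_id[cand[, 2]],
        distance_m = dist[cand]
      )
    }
  }
  nt <- nrow(pairs)
  structure(
    list(pairs = pairs, nt = nt, nc = n_det - nt, no = n_ref - nt,
         n_detected = n_det, n_reference = n_ref, threshold_m = threshold_m,
         location = location),
    class = "detection_match"
  )
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf(
    "# Detection match: Nt = %d, Nc = %d, No = %d (threshold %.2f m)\n",
    x$nt, x$nc, x$no, x$threshold_m))
  invisible(x)
}

#' @export
tidy.detection_match <- function(x, ...) x$pairs

#' @export
glance.detection_match <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_detected = x$n_detected, n_reference = x$n_reference,
                   threshold_m = x$threshold_m),
    detection_metrics(x)
  )
}

#' Recall, precision and F-score of plant detection
#'
#' From correct (Nt), commission (Nc) and omission (No) counts:
#' recall r = Nt / (Nt + No), precision p = Nt / (Nt + Nc) and the harmonic
#' mean F = 2rp / (r + p). When nothing is detected and nothing matched
#' (Nt = Nc = 0) precision is undefined and all three are reported as 0.
#'
#' @param x a `detection_match`, or a data frame with columns `nt`, `nc`,
#'   `no` (one row per plot/source; extra columns are kept).
#' @param ... unused.
#' @return tibble with `recall`, `precision`, `f_score` (proportions in
#'   `[0, 1]`) appended to any identifying columns of the input.
#' @export
detection_metrics <- function(x, ...) UseMethod("detection_metrics")

#' @export
detection_metrics.detection_match <- function(x, ...) {
  detection_metrics(tibble::tibble(nt = x$nt, nc = x$nc, no = x$no))
}

#' @export
detection_metrics.data.frame <- function(x, ...) {
  df <- tibble::as_tibble(x)
  names(df) <- tolower(names(df))
  if (!all(c("nt", "nc", "no") %in% names(df))) {
    abort("need columns nt, nc, no")
  }
  if (any(df$nt < 0 | df$nc < 0 | df$no < 0)) abort("counts must be >= 0")
  if (any(df$nt + df$no <= 0)) {
    abort("nt + no must be > 0 (there must be reference plants)")
  }
  r <- df$nt / (df$nt + df$no)
  p <- ifelse(df$nt + df$nc > 0, df$nt / (df$nt + df$nc), 0)
  f <- ifelse(r + p > 0, 2 * r * p / (r + p), 0)
  dplyr::bind_cols(df, tibble::tibble(recall = r, precision = p, f_score = f))
}

#' Accuracy of an extracted trait against field measurements
#'
#' Root-mean-square error, RMSE = sqrt(sum((y - y')^2) / n), and the
#' coefficient of determination of the linear regression of estimates on
#' measurements (the squared Pearson correlation). Only correctly matched
#' plants should be passed in, mirroring how trait accuracy is assessed on
#' correctly segmented plants.
#'
#' @param data data frame holding the two columns (optional; vectors may be
#'   given directly).
#' @param estimate,truth column names (tidy-eval) or numeric vectors.
#' @return one-row tibble: `n`, `rmse`, `r_squared`, `bias` (mean estimate
#'   minus truth).
#' @export
regression_metrics <- function(data = NULL, estimate, truth) {
  if (is.null(data)) {
    e <- estimate; t_ <- truth
  } else {
    e <- rlang::eval_tidy(rlang::enquo(estimate), data)
    t_ <- rlang::eval_tidy(rlang::enquo(truth), data)
  }
  ok <- is.finite(e) & is.finite(t_)
  e <- e[ok]; t_ <- t_[ok]
  if (length(e) != length(t_)) abort("estimate and truth lengths differ")
  if (length(e) < 2) {
    warn("fewer than 2 paired values; metrics are undefined")
    return(tibble::tibble(n = length(e), rmse = NA_real_,
                          r_squared = NA_real_, bias = NA_real_))
  }
  r2 <- if (stats::sd(t_) == 0 || stats::sd(e) == 0) {
    warn("zero variance: R^2 is undefined")
    NA_real_
  } else {
    stats::cor(e, t_)^2
  }
  tibble::tibble(
    n = length(e),
    rmse = sqrt(mean((e - t_)^2)),
    r_squared = r2,
    bias = mean(e - t_)
  )
}

#' @export
autoplot.detection_match <- function(object, detections = NULL,
                                     reference = NULL, ...) {
  df <- object$pairs
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$distance_m)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$threshold_m, linetype = 2) +
    ggplot2::labs(x = "match distance (m)", y = "pairs") +
    ggplot2::theme_minimal()
  p
}
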
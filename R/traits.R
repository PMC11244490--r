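#' Extract the breast-height slice of a segment
#'
#' Member points with height above ground in `[z_lo, z_hi)` — by default the
#' 1.2-1.4 m band bracketing breast height (1.3 m), where the culm taper is
#' nearly constant so a cylinder is the right local model.
#'
#' @param cloud a segmented, normalized `bamboo_cloud`.
#' @param segment_id one segment id.
#' @param z_lo,z_hi slice band (m above ground).
#' @param min_points slices with fewer points are flagged not estimable
#'   (typical for airborne-only culms, which the canopy shadows).
#' @return a `bamboo_cloud` of the slice with attribute `estimable`.
#' @export
slice_culm <- function(cloud, segment_id, z_lo = 1.2, z_hi = 1.4,
                       min_points = 10) {
  if (z_lo >= z_hi) abort("z_lo must be < z_hi")
  cloud <- as_point_cloud(cloud)
  if (!is_normalized(cloud)) abort("slice_culm needs a height-normalized cloud")
  df <- tibble::as_tibble(cloud)
  if (!"segment_id" %in% names(df)) abort("cloud has no segment_id column")
  sel <- !is.na(df$segment_id) & df$segment_id == segment_id &
    df$z >= z_lo & df$z < z_hi
  out <- restore_cloud(df[sel, , drop = FALSE], cloud)
  attr(out, "estimable") <- nrow(out) >= min_points
  out
}

#' Fit a cylinder to a culm slice
#'
#' Nonlinear least squares on the orthogonal distance between each point
#' and the cylinder surface, d = ||(p - c) - ((p - c).a) a|| - 1/k, with a
#' the unit axis direction and k the reciprocal radius. Five parameters are
#' free (two axis-position offsets at the slice mid-height, two axis tilt
#' components, the radius); the anchor along the axis is fixed to remove
#' the gauge freedom. Initialization combines an algebraic circle fit of
#' the horizontal projection with a vertical axis, and a second start from
#' the principal direction of the points; the better converged fit wins.
#' One pass of residual trimming (|r| > 3 x MAD) guards against leaf and
#' branch returns contaminating the slice.
#'
#' @param slice a `bamboo_cloud` (or data frame with x, y, z) of culm
#'   surface points.
#' @param trim logical: apply the robust re-fit pass.
#' @return a `cylinder_fit`: axis direction `a`, anchor `c`, reciprocal
#'   radius `k`, `dbh_m`, residual `rms_m`, residual scale `s`, `n_points`,
#'   `converged`.
#' @export
fit_cylinder <- function(slice, trim = TRUE) {
  df <- tibble::as_tibble(slice)
  m <- unname(as.matrix(df[, c("x", "y", "z")]))
  if (nrow(m) < 10) abort("need at least 10 points to fit a cylinder")
  sv <- svd(scale(m, scale = FALSE))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    abort("degenerate slice geometry: points are essentially collinear")
  }

  fit1 <- fit_cylinder_once(m, init_axis = c(0, 0, 1))
  fit2 <- fit_cylinder_once(m, init_axis = principal_axis(m, sv))
  fit <- if (fit2$sse < fit1$sse) fit2 else fit1

  if (trim) {
    # robust polish: Huber reweighting bounds the influence of leaf returns
    # and of sparse points from the other scanner that carry residual
    # alignment error; hard trimming is unstable when the slice mixes a
    # short clean arc with a contaminated subset
    for (pass in 1:3) {
      res <- fit$residuals
      s_mad <- stats::mad(res)
      if (!is.finite(s_mad) || s_mad < 1e-9) break
      w <- pmin(1, 1.345 * s_mad / pmax(abs(res), 1e-300))
      refit <- fit_cylinder_once(m, init_axis = fit$a, weights = sqrt(w))
      if (!refit$converged) break
      fit <- refit
    }
  }

  if (fit$k <= 0) abort("cylinder fit collapsed to non-positive curvature")
  structure(
    list(a = fit$a, c = fit$c, k = fit$k, dbh_m = 2 / fit$k,
         rms_m = sqrt(mean(fit$residuals^2)),
         s = stats::sd(fit$residuals),
         n_points = length(fit$residuals),
         converged = fit$converged),
    class = "cylinder_fit"
  )
}

principal_axis <- function(m, sv = svd(scale(m, scale = FALSE))) {
  a <- sv$v[, 1]
  if (a[3] < 0) a <- -a
  if (abs(a[3]) < 0.2) c(0, 0, 1) else a # guard against a degenerate tilt
}

# one Levenberg-Marquardt solve from a given starting axis; `weights`
# multiply the residuals (IRLS), the returned residuals are unweighted
fit_cylinder_once <- function(m, init_axis, weights = NULL) {
  centre <- colMeans(m)
  zmid <- centre[3]
  a0 <- init_axis / sqrt(sum(init_axis^2))
  # initial radius/centre from an algebraic (Kasa) circle fit in the plane
  # orthogonal-ish to the axis: use the horizontal projection
  x <- m[, 1] - centre[1]; y <- m[, 2] - centre[2]
  A <- cbind(2 * x, 2 * y, 1)
  ab <- tryCatch(qr.coef(qr(A), x^2 + y^2), error = function(e) c(0, 0, 0.01))
  r0 <- sqrt(max(ab[3] + ab[1]^2 + ab[2]^2, 1e-8))
  p0 <- c(cx = centre[1] + ab[1], cy = centre[2] + ab[2],
          ax = a0[1] / max(a0[3], 0.3), ay = a0[2] / max(a0[3], 0.3),
          r = max(r0, 1e-3))

  resid_fun <- function(p) {
    a <- c(p[3], p[4], 1)
    a <- a / sqrt(sum(a^2))
    cc <- c(p[1], p[2], zmid)
    v <- sweep(m, 2, cc, "-")
    t_ <- v %*% a
    w <- v - t_ %*% t(a)
    sqrt(rowSums(w^2)) - p[5]
  }
  obj_fun <- if (is.null(weights)) resid_fun else function(p) weights * resid_fun(p)
  out <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = obj_fun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL
  )
  if (is.null(out)) {
    res <- resid_fun(p0)
    return(list(a = a0, c = c(p0[1], p0[2], zmid), k = 1 / p0[5],
                residuals = res, sse = sum(res^2), converged = FALSE))
  }
  p <- unname(unlist(out$par))
  a <- c(p[3], p[4], 1); a <- a / sqrt(sum(a^2))
  res <- resid_fun(p)
  list(a = a, c = unname(c(p[1], p[2], zmid)), k = 1 / p[5],
       residuals = res, sse = sum(res^2),
       converged = out$info %in% 1:4)
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "# Cylinder fit: DBH %.4f m (k = %.3f 1/m), rms %.2g m, %d points%s\n",
    x$dbh_m, x$k, x$rms_m, x$n_points,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Diameter at breast height from a cylinder fit
#'
#' @param fit a `cylinder_fit`.
#' @return DBH in metres (twice the fitted radius, 2/k).
#' @export
dbh_from_fit <- function(fit) {
  stopifnot(inherits(fit, "cylinder_fit"))
  if (fit$k <= 0) abort("reciprocal radius k must be > 0")
  2 / fit$k
}

#' @export
tidy.cylinder_fit <- function(x, ...) {
  tibble::tibble(
    term = c("axis_x", "axis_y", "axis_z", "centre_x", "centre_y", "centre_z",
             "k", "dbh_m"),
    estimate = c(x$a, x$c, x$k, x$dbh_m)
  )
}

#' @export
glance.cylinder_fit <- function(x, ...) {
  tibble::tibble(dbh_m = x$dbh_m, rms_m = x$rms_m, s = x$s,
                 n_points = x$n_points, converged = x$converged)
}

#' Estimate DBH for every segment of a cloud
#'
#' Slices each segment at breast height and fits a cylinder; segments whose
#' slice is too thin (airborne-only culms, understory plants) are flagged
#' rather than fitted.
#'
#' @param cloud a segmented, normalized `bamboo_cloud`.
#' @param z_lo,z_hi slice band (m).
#' @param min_points minimum slice size for a fit.
#' @return tibble with `segment_id`, `dbh_m`, `fit_rms_m`, `n_slice_points`,
#'   `estimable`.
#' @export
estimate_dbh <- function(cloud, z_lo = 1.2, z_hi = 1.4, min_points = 10) {
  ids <- segment_summary(cloud)$segment_id
  purrr::map_dfr(ids, function(sid) {
    sl <- slice_culm(cloud, sid, z_lo = z_lo, z_hi = z_hi,
                     min_points = min_points)
    if (!attr(sl, "estimable")) {
      return(tibble::tibble(segment_id = sid, dbh_m = NA_real_,
                            fit_rms_m = NA_real_, n_slice_points = nrow(sl),
                            estimable = FALSE))
    }
    fit <- tryCatch(fit_cylinder(sl), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(segment_id = sid, dbh_m = NA_real_,
                            fit_rms_m = NA_real_, n_slice_points = nrow(sl),
                            estimable = FALSE))
    }
    tibble::tibble(segment_id = sid, dbh_m = fit$dbh_m, fit_rms_m = fit$rms_m,
                   n_slice_points = nrow(sl), estimable = TRUE)
  })
}
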
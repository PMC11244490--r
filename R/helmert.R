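#' Seven-parameter Helmert (similarity) transform
#'
#' The datum transform used to carry a local terrestrial-scanner frame into
#' the projected mapping frame: three translations, three small rotation
#' angles and one scale perturbation. The rotation enters in its small-angle
#' (linearized Bursa-Wolf) matrix form
#' \deqn{X = \Delta + (1 + m) \, M(\theta) \, X_0,\qquad
#'   M = \begin{pmatrix} 1 & \theta_z & -\theta_y \\
#'                      -\theta_z & 1 & \theta_x \\
#'                       \theta_y & -\theta_x & 1 \end{pmatrix}}
#' which is accurate for the sub-degree rotations that occur between survey
#' frames at plot scale.
#'
#' @param dx,dy,dz translations (m).
#' @param rx,ry,rz rotation angles about x, y, z (radians, small).
#' @param scale dimensionless scale perturbation m (0 = unit scale).
#' @return a `helmert_transform` object.
#' @examples
#' t <- helmert_transform(dx = 1, dy = 2, dz = 3)
#' apply_helmert(point_cloud(data.frame(x = 0, y = 0, z = 0), frame = "local"), t)
#' @export
helmert_transform <- function(dx = 0, dy = 0, dz = 0,
                              rx = 0, ry = 0, rz = 0, scale = 0) {
  structure(
    list(dx = dx, dy = dy, dz = dz, rx = rx, ry = ry, rz = rz, scale = scale),
    class = "helmert_transform"
  )
}

#' @export
print.helmert_transform <- function(x, ...) {
  cat("# Helmert transform (7 parameters)\n")
  cat(sprintf("#   translation: (%.4f, %.4f, %.4f) m\n", x$dx, x$dy, x$dz))
  cat(sprintf("#   rotation:    (%.3e, %.3e, %.3e) rad\n", x$rx, x$ry, x$rz))
  cat(sprintf("#   scale:       %+.3e\n", x$scale))
  if (!is.null(attr(x, "rms_m"))) {
    cat(sprintf("#   control-point residual rms: %.4f m (n = %d)\n",
                attr(x, "rms_m"), attr(x, "n_control")))
  }
  invisible(x)
}

helmert_matrix <- function(t) {
  matrix(c(1,      t$rz,  -t$ry,
           -t$rz,  1,      t$rx,
           t$ry,  -t$rx,   1), nrow = 3, byrow = TRUE)
}

# apply (or numerically invert) the transform on an n x 3 coordinate matrix
helmert_coords <- function(m, t, inverse = FALSE) {
  M <- (1 + t$scale) * helmert_matrix(t)
  d <- c(t$dx, t$dy, t$dz)
  if (!inverse) {
    sweep(m %*% t(M), 2, d, "+")
  } else {
    t(solve(M, t(sweep(m, 2, d, "-"))))
  }
}

#' Apply a Helmert transform to a local-frame cloud
#'
#' Evaluates the transform exactly for every point and relabels the frame as
#' projected.
#'
#' @param cloud a `bamboo_cloud` in the local frame.
#' @param transform a [helmert_transform()].
#' @param inverse if TRUE, map a projected-frame cloud back to local.
#' @return the transformed `bamboo_cloud`.
#' @export
apply_helmert <- function(cloud, transform, inverse = FALSE) {
  cloud <- as_point_cloud(cloud)
  stopifnot(inherits(transform, "helmert_transform"))
  stopifnot_frame(cloud, if (inverse) "projected" else "local")
  out <- tibble::as_tibble(cloud)
  if (nrow(out) > 0) {
    m <- helmert_coords(coords_matrix(cloud), transform, inverse = inverse)
    out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  }
  new_point_cloud(out, frame = if (inverse) "local" else "projected",
                  normalized = FALSE)
}

#' Estimate a Helmert transform from control-point pairs
#'
#' Least-squares estimation of the seven parameters from paired local and
#' projected coordinates of surveyed targets (at least three non-collinear
#' full 3-D pairs for the seven unknowns). The linearized model (cross-terms
#' between scale and rotations dropped) gives a direct linear solve; a few
#' Gauss-Newton refinement steps on the exact model then remove the
#' linearization error, which matters when recovery to numerical precision
#' is required.
#'
#' @param control tibble with columns `target_id`, `local_x`, `local_y`,
#'   `local_z`, `proj_x`, `proj_y`, `proj_z` (see [read_control_points()]).
#' @param refine number of Gauss-Newton refinement iterations (0 = plain
#'   linear solve).
#' @param scale `"estimate"` solves for all seven parameters; `"unit"`
#'   fixes the scale perturbation to zero and solves for six. Plot-corner
#'   targets are nearly coplanar, which makes scale barely identifiable:
#'   with GNSS-level noise its estimate can err by several parts per
#'   thousand, a distortion that no rigid refinement can undo, so unit
#'   scale is the sound choice whenever the local frame is metric.
#' @return a `helmert_transform` with attributes `residuals` (n x 3 matrix,
#'   projected minus fitted), `rms_m` and `n_control`.
#' @export
estimate_helmert <- function(control, refine = 8,
                             scale = c("estimate", "unit")) {
  scale <- match.arg(scale)
  control <- tibble::as_tibble(control)
  need <- c("local_x", "local_y", "local_z", "proj_x", "proj_y", "proj_z")
  if (!all(need %in% names(control))) {
    abort(paste("control points need columns", paste(need, collapse = ", ")))
  }
  n <- nrow(control)
  if (n < 3) {
    abort(paste0("at least 3 full 3-D control pairs are required to estimate ",
                 "the 7 transform parameters; got ", n))
  }
  X0 <- as.matrix(control[, c("local_x", "local_y", "local_z")])
  X1 <- as.matrix(control[, c("proj_x", "proj_y", "proj_z")])
  if (!all(is.finite(X0)) || !all(is.finite(X1))) {
    abort("control coordinates must be finite")
  }

  # design matrix of the linearized model, one 3-row block per pair:
  # X - X0 = [ I3 | S(X0) | X0 ] (dx,dy,dz, rx,ry,rz, m)'
  A <- matrix(0, 3 * n, 7)
  b <- numeric(3 * n)
  for (i in seq_len(n)) {
    r <- (3 * i - 2):(3 * i)
    x0 <- X0[i, 1]; y0 <- X0[i, 2]; z0 <- X0[i, 3]
    A[r, 1:3] <- diag(3)
    A[r, 4:6] <- matrix(c(0, -z0, y0,
                          z0, 0, -x0,
                          -y0, x0, 0), nrow = 3, byrow = TRUE)
    A[r, 7] <- X0[i, ]
    b[r] <- X1[i, ] - X0[i, ]
  }
  n_par <- if (scale == "unit") 6L else 7L
  qr_A <- qr(A[, seq_len(n_par), drop = FALSE])
  if (qr_A$rank < n_par) {
    abort(paste0("degenerate control geometry (collinear or coincident ",
                 "targets): design rank ", qr_A$rank, " < ", n_par))
  }
  beta <- c(qr.coef(qr_A, b), numeric(7))[1:7]
  fit <- helmert_transform(beta[1], beta[2], beta[3],
                           beta[4], beta[5], beta[6], beta[7])

  # Gauss-Newton on the exact model X = d + (1+m) M(theta) X0
  for (iter in seq_len(refine)) {
    res <- X1 - helmert_coords(X0, fit)
    J <- matrix(0, 3 * n, 7)
    s <- 1 + fit$scale
    for (i in seq_len(n)) {
      r <- (3 * i - 2):(3 * i)
      x0 <- X0[i, 1]; y0 <- X0[i, 2]; z0 <- X0[i, 3]
      J[r, 1:3] <- diag(3)
      J[r, 4:6] <- s * matrix(c(0, -z0, y0,
                                z0, 0, -x0,
                                -y0, x0, 0), nrow = 3, byrow = TRUE)
      J[r, 7] <- helmert_matrix(fit) %*% X0[i, ]
    }
    step <- c(qr.coef(qr(J[, seq_len(n_par), drop = FALSE]),
                      as.vector(t(res))), numeric(7))[1:7]
    if (any(!is.finite(step))) break
    fit <- helmert_transform(fit$dx + step[1], fit$dy + step[2],
                             fit$dz + step[3], fit$rx + step[4],
                             fit$ry + step[5], fit$rz + step[6],
                             fit$scale + step[7])
    if (max(abs(step)) < 1e-14) break
  }

  res <- X1 - helmert_coords(X0, fit)
  attr(fit, "residuals") <- res
  attr(fit, "rms_m") <- sqrt(mean(res^2))
  attr(fit, "n_control") <- n
  fit
}

#' @export
tidy.helmert_transform <- function(x, ...) {
  tibble::tibble(
    term = c("dx", "dy", "dz", "rx", "ry", "rz", "scale"),
    estimate = c(x$dx, x$dy, x$dz, x$rx, x$ry, x$rz, x$scale),
    unit = c(rep("m", 3), rep("rad", 3), "1")
  )
}

#' @export
glance.helmert_transform <- function(x, ...) {
  tibble::tibble(
    rms_m = attr(x, "rms_m") %||% NA_real_,
    n_control = attr(x, "n_control") %||% NA_integer_
  )
}
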
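#' Fine alignment by iterative closest point (ICP)
#'
#' Rigid point-to-point ICP of a source cloud (typically the coarse-aligned
#' TLS data) onto a target cloud (the ALS data). Each iteration matches
#' every source point to its nearest target neighbour, discards
#' correspondences farther than `reject_radius_m`, and solves the
#' closed-form rigid update (centroid shift + SVD of the cross-covariance).
#' The mean squared correspondence distance is the objective; iterations
#' stop when its root improves by less than `tol_m` or `max_iter` is
#' reached, and an iteration that would increase it is rejected, so the
#' reported objective path is non-increasing. Scale is deliberately not
#' re-estimated: the Helmert coarse alignment already fixed it.
#'
#' @param source,target `bamboo_cloud`s in the projected frame, nonempty.
#' @param max_iter maximum iterations.
#' @param tol_m convergence tolerance on the rms distance (m).
#' @param reject_radius_m correspondence rejection radius (m).
#' @param refine_radius_m once the loop converges at `reject_radius_m`, a
#'   second stage reruns it with this tighter radius so only genuinely
#'   shared structure polishes the pose (NULL disables the stage).
#' @param trim overlap fraction: after the radius cut, only the nearest
#'   `trim` quantile of correspondences feeds the update (trimmed ICP),
#'   which stops structure present in one cloud only from biasing the
#'   pose; 1 disables trimming.
#' @param voxel_m optional voxel size for thinning both clouds before
#'   matching (NULL = use every point); the returned transform applies to
#'   the full-resolution source.
#' @return an `icp_result`: list with `rotation` (3 x 3), `translation`
#'   (length 3), `rms_m`, `rms_path`, `n_iterations`, `converged`,
#'   `n_pairs`.
#' @export
icp_align <- function(source, target, max_iter = 50, tol_m = 1e-6,
                      reject_radius_m = 1.0, refine_radius_m = 0.1,
                      trim = 0.8, voxel_m = 0.05) {
  source <- as_point_cloud(source)
  target <- as_point_cloud(target)
  stopifnot_frame(source, "projected", "source")
  stopifnot_frame(target, "projected", "target")
  if (nrow(source) == 0 || nrow(target) == 0) {
    abort("both clouds must be nonempty for ICP")
  }
  S <- if (!is.null(voxel_m)) coords_matrix(voxel_thin(source, voxel_m)) else coords_matrix(source)
  T_ <- if (!is.null(voxel_m)) coords_matrix(voxel_thin(target, voxel_m)) else coords_matrix(target)

  state <- list(R = diag(3), t = c(0, 0, 0), rms = Inf, path = numeric(0),
                converged = FALSE, n_pairs = 0L)
  state <- icp_stage(S, T_, state, reject_radius_m, max_iter, tol_m, trim,
                     first_stage = TRUE)
  if (!is.null(refine_radius_m) && refine_radius_m < reject_radius_m) {
    # polish at (near) full resolution: the voxel quantization of the first
    # stage is itself a centimetre-scale error floor
    S2 <- coords_matrix(source)
    T2 <- coords_matrix(target)
    state <- icp_stage(S2, T2, state, refine_radius_m, max_iter, tol_m, trim,
                       first_stage = FALSE)
  }

  structure(
    list(rotation = state$R, translation = state$t,
         rms_m = state$rms, rms_path = state$path,
         n_iterations = length(state$path), converged = state$converged,
         n_pairs = state$n_pairs),
    class = "icp_result"
  )
}

# one rejection-radius stage of the ICP loop; `state` carries the pose in.
# Transient objective increases (the trimmed correspondence set reshuffles)
# do not terminate the stage: iteration continues with a small patience
# budget and the best-objective pose is returned, so the reported path --
# the accepted iterations -- stays non-increasing.
icp_stage <- function(S, T_, state, radius, max_iter, tol_m, trim, first_stage,
                      patience = 5L) {
  R_cur <- state$R
  t_cur <- state$t
  best_rms <- Inf
  R_best <- R_cur
  t_best <- t_cur
  stalled <- 0L
  for (iter in seq_len(max_iter)) {
    moved <- sweep(S %*% t(R_cur), 2, t_cur, "+")
    nn <- cpp_knn(T_, moved, 1L)
    d <- nn$dist[, 1]
    ok <- is.finite(d) & d <= radius
    if (trim < 1 && sum(ok) > 20) {
      ok <- ok & d <= stats::quantile(d[ok], trim)
    }
    if (!any(ok)) {
      if (iter == 1 && first_stage) {
        abort(paste0("no correspondences within the rejection radius (",
                     radius, " m): coarse alignment too poor for ICP"))
      }
      break
    }
    rms <- sqrt(mean(d[ok]^2))
    if (rms < best_rms - 1e-15) { # accepted iteration
      improved <- best_rms - rms
      best_rms <- rms
      R_best <- R_cur
      t_best <- t_cur
      state$path <- c(state$path, rms)
      state$n_pairs <- sum(ok)
      stalled <- 0L
      if (improved < tol_m && iter > 1) {
        state$converged <- TRUE
        break
      }
    } else {
      stalled <- stalled + 1L
      if (stalled > patience) break
    }

    P <- moved[ok, , drop = FALSE]
    Q <- T_[nn$idx[ok, 1], , drop = FALSE]
    cp <- colMeans(P)
    cq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cp, "-"), sweep(Q, 2, cq, "-"))
    sv <- svd(H)
    D <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R_step <- sv$v %*% D %*% t(sv$u)
    t_step <- cq - as.vector(R_step %*% cp)
    R_cur <- R_step %*% R_cur
    t_cur <- as.vector(R_step %*% t_cur) + t_step
  }
  state$R <- R_best
  state$t <- t_best
  if (is.finite(best_rms)) state$rms <- best_rms
  state
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf(
    "# ICP result: rms %.4g m after %d iterations (%s), %d correspondences\n",
    x$rms_m, x$n_iterations,
    if (x$converged) "converged" else "max iterations / stalled", x$n_pairs))
  invisible(x)
}

#' Apply a rigid transform to a cloud
#'
#' @param cloud a `bamboo_cloud` in the projected frame.
#' @param transform an `icp_result`, or a list with `rotation` and
#'   `translation`.
#' @return the transformed cloud.
#' @export
apply_rigid <- function(cloud, transform) {
  cloud <- as_point_cloud(cloud)
  out <- tibble::as_tibble(cloud)
  if (nrow(out) > 0) {
    m <- sweep(coords_matrix(cloud) %*% t(transform$rotation), 2,
               transform$translation, "+")
    out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  }
  restore_cloud(out, cloud)
}

#' @export
tidy.icp_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$rms_path), rms_m = x$rms_path)
}

#' @export
glance.icp_result <- function(x, ...) {
  tibble::tibble(rms_m = x$rms_m, n_iterations = x$n_iterations,
                 converged = x$converged, n_pairs = x$n_pairs)
}

#' @export
autoplot.icp_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$iteration, y = .data$rms_m)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "iteration", y = "rms correspondence distance (m)") +
    ggplot2::theme_minimal()
}
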
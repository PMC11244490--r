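# normalized cloud of a small stand, with truth labels travelling along
norm_cloud <- function(st, scanner) {
  cl <- classify_ground(if (scanner$mode == "als") render_als(st, scanner)
                        else render_tls(st, scanner)$cloud |>
                          apply_helmert(helmert_transform()))
  suppressWarnings(normalize_heights(cl, build_dem(cl)))
}

seg_purity <- function(seg) {
  df <- tibble::as_tibble(seg)
  df <- df[!is.na(df$segment_id) & !is.na(df$plant_id), ]
  purity <- tapply(df$plant_id, df$segment_id,
                   function(p) max(table(p)) / length(p))
  unname(purity)
}

test_that("PCS separates well-spaced crowns and seeds from the global top", {
  st <- small_stand(n = 6, seed = 41, spacing = 3.0)
  norm <- norm_cloud(st, fast_als())
  seg <- segment_pcs(norm, d = 2.0)
  df <- tibble::as_tibble(seg)

  expect_equal(length(unique(na.omit(df$segment_id))), 6)
  expect_gte(min(seg_purity(seg)), 0.99)
  # the globally highest point is in segment 1
  expect_equal(df$segment_id[which.max(df$z)], 1L)
  # partition property: each in-scope point in exactly one segment
  expect_equal(sum(!is.na(df$segment_id)) + sum(is.na(df$segment_id)), nrow(df))

  summ <- segment_summary(seg)
  m <- match_detections(summ, stand_inventory(st), plot_area_m2 = 100)
  expect_equal(c(m$nt, m$nc, m$no), c(6L, 0L, 0L))
})

test_that("a single plant yields one PCS segment containing the maximum", {
  st <- small_stand(n = 1, seed = 42)
  norm <- norm_cloud(st, fast_als())
  seg <- segment_pcs(norm, d = 2.0)
  df <- tibble::as_tibble(seg)
  expect_equal(unique(na.omit(df$segment_id)), 1L)
  expect_equal(df$segment_id[which.max(df$z)], 1L)
  expect_error(segment_pcs(norm, d = -1), "d must be > 0")
})

test_that("culm detection finds every culm with centimetre accuracy", {
  st <- small_stand(n = 6, seed = 43)
  norm <- norm_cloud(st, fast_tls())
  culms <- detect_culms(norm, min_points = fast_min_points)
  expect_equal(nrow(culms), 6)
  nn <- bamboostand:::cpp_knn(as.matrix(st$plants[, c("x", "y")]),
                              as.matrix(culms[, c("x", "y")]), 1L)
  expect_lt(max(nn$dist), 0.05)
})

test_that("sparse uniform scatter yields the no-cluster error path", {
  set.seed(44)
  scatter <- point_cloud(data.frame(x = runif(400, 0, 10),
                                    y = runif(400, 0, 10),
                                    z = runif(400, 0.5, 2)))
  attr(scatter, "normalized") <- TRUE
  expect_error(detect_culms(scatter, min_points = 100), "no culm clusters")
  expect_equal(nrow(detect_culms(scatter, min_points = 100,
                                 on_empty = "tolerate")), 0)
  # and the airborne culm layer is too sparse for the terrestrial thresholds
  st <- small_stand(n = 6, seed = 43)
  norm_a <- norm_cloud(st, fast_als())
  culms_a <- detect_culms(norm_a, min_points = fast_min_points,
                          on_empty = "tolerate")
  expect_lt(nrow(culms_a), 6)
})

test_that("CSP assigns points to their own plant through the path graph", {
  st <- small_stand(n = 6, seed = 45)
  norm <- norm_cloud(st, fast_tls())
  seg <- segment_csp(norm, min_points = fast_min_points)
  df <- tibble::as_tibble(seg)
  expect_equal(length(unique(na.omit(df$segment_id))), 6)
  expect_gte(min(seg_purity(seg)), 0.98)
  # partition: in-scope points are assigned (up to dissolved fragments),
  # everything else is unassigned
  in_scope <- df$classification != 2L & df$z >= 0.1
  expect_gt(mean(!is.na(df$segment_id[in_scope])), 0.99)
  expect_true(all(is.na(df$segment_id[!in_scope])))
})

test_that("one culm collects the whole cloud into one segment", {
  st <- small_stand(n = 1, seed = 46)
  norm <- norm_cloud(st, fast_tls())
  seg <- segment_csp(norm, min_points = fast_min_points)
  df <- tibble::as_tibble(seg)
  expect_equal(unique(na.omit(df$segment_id)), 1L)
})

test_that("path-based assignment beats horizontal-nearest on interlocked crowns", {
  # constructed fixture: plant B's drooping top hangs over plant A's crown,
  # so the overhanging foliage is horizontally nearest to culm A but stays
  # physically connected to culm B through the bent culm
  set.seed(52)
  mk_culm <- function(cx, n, hmax, bend_dx = 0) {
    h <- runif(n, 0.2, hmax)
    bend <- ifelse(h > 8, ((h - 8) / (hmax - 8))^2, 0) * bend_dx
    phi <- runif(n, 0, 2 * pi)
    tibble::tibble(x = cx[1] + bend + 0.04 * cos(phi),
                   y = cx[2] + 0.04 * sin(phi), z = h,
                   plant_id = NA_integer_)
  }
  a_culm <- mk_culm(c(4, 5), 2000, 12)
  a_crown <- tibble::tibble(x = 4 + rnorm(1200, 0, 0.4),
                            y = 5 + rnorm(1200, 0, 0.4),
                            z = runif(1200, 9, 11.5), plant_id = NA_integer_)
  b_culm <- mk_culm(c(5.2, 5), 2000, 12, bend_dx = -0.8)
  b_crown <- tibble::tibble(x = 4.4 + rnorm(700, 0, 0.25),
                            y = 5 + rnorm(700, 0, 0.25),
                            z = runif(700, 11, 12.3), plant_id = NA_integer_)
  truth <- rep(c(1L, 1L, 2L, 2L), c(2000, 1200, 2000, 700))
  cloud <- point_cloud(dplyr::bind_rows(a_culm, a_crown, b_culm, b_crown))
  cloud$plant_id <- truth
  attr(cloud, "normalized") <- TRUE

  seg <- segment_csp(cloud, min_points = 150)
  df <- tibble::as_tibble(seg)
  culms <- attr(seg, "culms")
  expect_equal(nrow(culms), 2)

  bases <- matrix(c(4, 5, 5.2, 5), ncol = 2, byrow = TRUE)
  nn <- bamboostand:::cpp_knn(bases, as.matrix(culms[, c("x", "y")]), 1L)
  seg2plant <- integer(max(culms$segment_id, na.rm = TRUE))
  seg2plant[culms$segment_id] <- nn$idx[, 1]

  hit <- !is.na(df$segment_id)
  acc_path <- mean(seg2plant[df$segment_id[hit]] == df$plant_id[hit])
  # naive oracle: nearest culm centroid in the horizontal plane
  nnc <- bamboostand:::cpp_knn(as.matrix(culms[, c("x", "y")]),
                               cbind(df$x[hit], df$y[hit]), 1L)
  acc_naive <- mean(seg2plant[nnc$idx[, 1]] == df$plant_id[hit])
  expect_gt(acc_path, acc_naive)
  expect_gt(acc_path, 0.85)
})

test_that("the double pass is a fixed point on clean stands and can split", {
  st <- small_stand(n = 5, seed = 48)
  norm <- norm_cloud(st, fast_tls())
  expect_message(seg <- segment_csp_double(norm, min_points = fast_min_points),
                 "converged")
  expect_true(attr(seg, "converged"))
  p <- attr(seg, "passes")
  expect_equal(unname(p["pass1"]), unname(p["pass2"]))

  # constructed under-segmentation: culm B's band count sits between half and
  # full threshold, so pass 1 absorbs it and pass 2 recovers it
  set.seed(49)
  mk_plant <- function(centre, n_band, n_crown, h_top) {
    band <- cylinder_slice(n_band, radius = 0.05, centre = centre,
                           z_range = c(0.5, 2), noise_sd = 0.002)
    stem <- cylinder_slice(round(n_band * 2), radius = 0.04, centre = centre,
                           z_range = c(2, h_top - 1), noise_sd = 0.002)
    crown <- tibble::tibble(x = centre[1] + rnorm(n_crown, 0, 0.4),
                            y = centre[2] + rnorm(n_crown, 0, 0.4),
                            z = runif(n_crown, h_top - 1, h_top))
    dplyr::bind_rows(band, stem, crown)
  }
  cloud <- point_cloud(dplyr::bind_rows(mk_plant(c(3, 5), 400, 300, 9),
                                        mk_plant(c(5, 5), 180, 250, 8)))
  attr(cloud, "normalized") <- TRUE
  seg2 <- segment_csp_double(cloud, min_points = 300)
  p2 <- attr(seg2, "passes")
  expect_gte(unname(p2["pass2"]), unname(p2["pass1"]))
  expect_equal(unname(p2["pass2"]), 2)
})

test_that("heights come from the highest member point", {
  df <- tibble::tibble(x = c(0, 0, 5), y = 0, z = c(3, 12.4, 7),
                       segment_id = c(1L, 1L, 2L))
  cloud <- point_cloud(df)
  attr(cloud, "normalized") <- TRUE
  expect_equal(extract_height(cloud, 1), 12.4)
  expect_equal(extract_height(cloud, 2), 7)
  expect_error(extract_height(cloud, 3), "empty or absent")
  summ <- segment_summary(cloud)
  expect_equal(summ$height_m, c(12.4, 7))

  # dense rendering recovers a truth height within tolerance
  st <- small_stand(n = 3, seed = 50)
  norm <- norm_cloud(st, fast_als())
  seg <- segment_pcs(norm, d = 2.0)
  summ <- segment_summary(seg)
  m <- match_detections(summ, stand_inventory(st), plot_area_m2 = 100)
  est <- summ$height_m[match(m$pairs$segment_id, summ$segment_id)]
  truth <- stand_inventory(st)$height_m[match(m$pairs$plant_id,
                                              stand_inventory(st)$plant_id)]
  expect_lt(max(abs(est - truth)), 0.25)
})
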
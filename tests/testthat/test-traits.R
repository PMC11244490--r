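test_that("the breast-height slice honours the band and the size flag", {
  df <- tibble::tibble(x = 0, y = 0, z = c(seq(1.0, 1.6, by = 0.05)),
                       segment_id = 1L)
  cloud <- point_cloud(df)
  attr(cloud, "normalized") <- TRUE
  sl <- slice_culm(cloud, 1)
  expect_true(all(sl$z >= 1.2 & sl$z < 1.4))
  expect_false(attr(sl, "estimable")) # only 4 points in band
  expect_true(attr(slice_culm(cloud, 1, min_points = 2), "estimable"))
  expect_error(slice_culm(cloud, 1, z_lo = 1.4, z_hi = 1.2), "z_lo")
})

test_that("exact on-surface samples recover the radius to machine precision", {
  set.seed(61)
  for (r0 in c(0.03, 0.045, 0.08)) {
    sl <- cylinder_slice(200, radius = r0)
    fit <- fit_cylinder(sl)
    expect_true(fit$converged)
    expect_lt(abs(fit$dbh_m - 2 * r0), 1e-6)
    expect_lt(fit$rms_m, 1e-9)
    expect_equal(dbh_from_fit(fit), fit$dbh_m)
  }
})

test_that("a tilted cylinder is recovered in axis and radius", {
  set.seed(62)
  for (tilt in c(5, 15, 30)) {
    a <- c(sin(tilt * pi / 180), 0, cos(tilt * pi / 180))
    sl <- cylinder_slice(400, radius = 0.05, axis = a)
    fit <- fit_cylinder(sl)
    axis_err <- acos(min(1, abs(sum(fit$a * a)))) * 180 / pi
    expect_lt(axis_err, 0.5)
    expect_lt(abs(fit$dbh_m - 0.10) / 0.10, 0.02)
  }
})

test_that("DBH survives rigid motion of the slice (equivariance)", {
  set.seed(63)
  sl <- cylinder_slice(300, radius = 0.06)
  fit0 <- fit_cylinder(sl)
  th <- 20 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  m <- as.matrix(sl) %*% t(Rz)
  moved <- tibble::tibble(x = m[, 1] + 4, y = m[, 2] - 2, z = m[, 3] + 1)
  fit1 <- fit_cylinder(moved)
  expect_lt(abs(fit1$dbh_m - fit0$dbh_m), 1e-9)
})

test_that("noisy slices recover DBH at the millimetre scale", {
  set.seed(64)
  errs <- replicate(10, {
    sl <- cylinder_slice(200, radius = 0.045, noise_sd = 0.003)
    fit_cylinder(sl)$dbh_m - 0.09
  })
  expect_lt(sqrt(mean(errs^2)), 0.004)
})

test_that("degenerate and invalid inputs are rejected", {
  line <- tibble::tibble(x = seq(0, 1, length.out = 50), y = 0, z = 0)
  expect_error(fit_cylinder(line), "collinear")
  expect_error(fit_cylinder(cylinder_slice(5)), "at least 10")
  bad <- structure(list(a = c(0, 0, 1), k = -2), class = "cylinder_fit")
  expect_error(dbh_from_fit(bad), "k must be > 0")
})

test_that("estimate_dbh flags sparse airborne slices and fits dense ones", {
  st <- small_stand(n = 4, seed = 65)
  # terrestrial: dense culms, estimable
  tls <- render_tls(st, fast_tls())$cloud |> apply_helmert(helmert_transform())
  cls <- classify_ground(tls)
  norm <- normalize_heights(cls, build_dem(cls))
  seg <- segment_csp(norm, min_points = fast_min_points)
  dbh <- estimate_dbh(seg)
  expect_true(all(dbh$estimable))
  truth <- st$plants$dbh_m
  expect_lt(max(abs(sort(dbh$dbh_m) - sort(truth))), 0.01)

  # airborne: the canopy shadows the culm layer, slices fall below minimum
  als <- render_als(st, fast_als())
  cls_a <- classify_ground(als)
  norm_a <- normalize_heights(cls_a, build_dem(cls_a))
  seg_a <- segment_pcs(norm_a, d = 2.0)
  dbh_a <- estimate_dbh(seg_a)
  expect_gt(mean(!dbh_a$estimable), 0.5)
})

test_that("tidy and glance expose the fit parameters", {
  set.seed(66)
  fit <- fit_cylinder(cylinder_slice(100, radius = 0.05))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "dbh_m"], 0.1, tolerance = 1e-6)
  expect_named(glance(fit), c("dbh_m", "rms_m", "s", "n_points", "converged"))
})
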
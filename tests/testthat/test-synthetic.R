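test_that("stand generation respects spacing, bounds and determinism", {
  st <- small_stand(n = 8, seed = 3)
  p <- st$plants
  expect_equal(nrow(p), 8)
  d <- as.matrix(dist(cbind(p$x, p$y)))
  diag(d) <- Inf
  expect_true(all(d >= st$config$min_spacing_m))
  expect_true(all(p$x >= 0 & p$x <= 10 & p$y >= 0 & p$y <= 10))
  expect_true(all(p$dbh_m > 0 & p$height_m > 0))

  expect_identical(small_stand(n = 8, seed = 3), st)
  expect_false(identical(small_stand(n = 8, seed = 4), st))

  single <- generate_stand(stand_config(n_plants = 1, seed = 1))
  expect_equal(nrow(single$plants), 1)
  expect_equal(single$corners$x, c(0, 10, 10, 0))
  expect_equal(single$corners$y, c(0, 0, 10, 10))

  expect_error(
    generate_stand(stand_config(n_plants = 60, min_spacing_m = 3, seed = 1)),
    "could not place")
})

test_that("DBH and height are positively correlated by the allometry", {
  st <- generate_stand(stand_config(n_plants = 40, seed = 5))
  expect_gt(cor(st$plants$dbh_m, st$plants$height_m), 0.3)
})

test_that("rendered clouds are labelled and mode profiles differ", {
  st <- small_stand(n = 6, seed = 7)
  als <- render_als(st, fast_als())
  tls <- render_tls(st, fast_tls())$cloud # identity transform

  expect_equal(cloud_frame(als), "projected")
  expect_equal(cloud_frame(tls), "local")
  for (cl in list(als, tls)) {
    df <- tibble::as_tibble(cl)
    expect_true(all(df$truth_class %in% c("ground", "culm", "crown")))
    expect_true(all(is.na(df$plant_id[df$truth_class == "ground"])))
    expect_true(all(df$plant_id[df$truth_class != "ground"] %in% st$plants$id))
  }

  # vertical sampling bias: airborne sees crowns, terrestrial sees culms
  mean_h <- function(cl) {
    df <- tibble::as_tibble(cl)
    df <- df[!is.na(df$plant_id), ]
    mean(df$z - ground_height(st, df$x, df$y))
  }
  expect_gt(mean_h(als), mean_h(tls) + 2)

  # per plant the profile bias holds too
  per_plant <- function(cl) {
    df <- tibble::as_tibble(cl)
    df <- df[!is.na(df$plant_id), ]
    tapply(df$z - ground_height(st, df$x, df$y), df$plant_id, mean)
  }
  expect_true(all(per_plant(als) > per_plant(tls)[names(per_plant(als))]))
})

test_that("noise-free culm points lie on the taper surface", {
  st <- small_stand(n = 4, seed = 9)
  als <- render_als(st, fast_als(noise_sd_m = 0))
  df <- tibble::as_tibble(als)
  culm <- df[df$truth_class == "culm", ]
  for (pid in unique(culm$plant_id)) {
    pts <- culm[culm$plant_id == pid, ]
    base_z <- ground_height(st, st$plants$x[pid], st$plants$y[pid])
    ax <- culm_axis(st, pid, pts$z - base_z)
    r <- sqrt((pts$x - ax$x)^2 + (pts$y - ax$y)^2)
    expect_lt(max(abs(r - ax$radius)), 1e-9)
  }
})

test_that("an empty stand renders only ground points", {
  st <- generate_stand(stand_config(n_plants = 0, seed = 1))
  als <- render_als(st, fast_als())
  expect_true(all(tibble::as_tibble(als)$truth_class == "ground"))
})

test_that("the local TLS frame is the inverse-Helmert image of projected", {
  st <- small_stand(n = 3, seed = 13)
  tr <- helmert_transform(dx = 50, dy = 80, dz = 12,
                          rx = 0.004, ry = -0.003, rz = 0.008, scale = 2e-5)
  tls <- render_tls(st, fast_tls(noise_sd_m = 0), true_transform = tr)

  # identity transform puts TLS and ALS in the same frame
  tls_id <- render_tls(st, fast_tls(noise_sd_m = 0))
  expect_lt(max(abs(range(tls_id$cloud$z) -
                      range(apply_helmert(tls$cloud, tr)$z))), 1e-9)

  # mapping the local cloud forward puts culm points back on truth surfaces
  proj <- apply_helmert(tls$cloud, tr)
  df <- tibble::as_tibble(proj)
  culm <- df[df$truth_class == "culm" & df$plant_id == 1, ]
  base_z <- ground_height(st, st$plants$x[1], st$plants$y[1])
  ax <- culm_axis(st, 1, culm$z - base_z)
  r <- sqrt((culm$x - ax$x)^2 + (culm$y - ax$y)^2)
  expect_lt(max(abs(r - ax$radius)), 1e-6)

  # exact local corner coordinates, noisy projected coordinates
  ctl0 <- render_tls(st, fast_tls(), true_transform = tr,
                     control_noise_sd_m = 0)$control
  expect_equal(ctl0$proj_x, st$corners$x)
  ctl <- render_tls(st, fast_tls(), true_transform = tr,
                    control_noise_sd_m = 0.05)$control
  disp <- sqrt((ctl$proj_x - st$corners$x)^2 + (ctl$proj_y - st$corners$y)^2 +
                 (ctl$proj_z - st$corners$z)^2)
  expect_true(all(disp > 0))
  expect_true(all(disp < 5 * 0.05 * sqrt(3)))
  expect_equal(ctl$local_x, ctl0$local_x)
})
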
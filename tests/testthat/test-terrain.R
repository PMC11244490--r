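plane_cloud <- function(n = 4000, gx = 0.1, gy = 0, z0 = 50, noise = 0) {
  x <- runif(n, 0, 10); y <- runif(n, 0, 10)
  point_cloud(data.frame(x = x, y = y,
                         z = z0 + gx * x + gy * y + rnorm(n, 0, noise)))
}

test_that("a flat plane with one culm separates into ground and vegetation", {
  set.seed(31)
  ground <- plane_cloud(3000, gx = 0.05)
  culm <- cylinder_slice(400, radius = 0.05, centre = c(5, 5),
                         z_range = c(50.6, 53))
  cloud <- merge_clouds(ground, point_cloud(culm))
  cls <- classify_ground(cloud)
  lab <- cls$classification
  expect_true(all(lab[seq_len(3000)] == 2L))
  expect_true(all(lab[3001:3400] == 1L))
})

test_that("a pure ground cloud classifies as all ground", {
  set.seed(32)
  cls <- classify_ground(plane_cloud(2000, noise = 0.01))
  expect_true(all(cls$classification == 2L))
})

test_that("ground classification matches generator labels on a full stand", {
  st <- small_stand(n = 6, seed = 33)
  als <- render_als(st, fast_als())
  cls <- classify_ground(als)
  df <- tibble::as_tibble(cls)
  is_g <- df$truth_class == "ground"
  recall <- mean(df$classification[is_g] == 2L)
  leak <- mean(df$classification[!is_g] == 2L)
  expect_gte(recall, 0.95)
  expect_lte(leak, 0.02)
})

test_that("the DEM reproduces an analytic plane at cell centres", {
  set.seed(34)
  cloud <- plane_cloud(5000, gx = 0.1, gy = 0)
  cls <- classify_ground(cloud)
  dem <- build_dem(cls, cell_size_m = 0.5)
  grid <- tidy(dem)
  inside <- grid$x > 0.5 & grid$x < 9.5 & grid$y > 0.5 & grid$y < 9.5
  err <- grid$elevation[inside] - (50 + 0.1 * grid$x[inside])
  expect_lt(max(abs(err)), 0.1 * 0.5) # cell-scale discretization bound

  # idempotence: re-gridding the DEM's own cell-centre samples reproduces it
  centre_cloud <- point_cloud(data.frame(x = grid$x, y = grid$y,
                                         z = grid$elevation))
  dem2 <- build_dem(centre_cloud, cell_size_m = 0.5)
  expect_equal(dem2$z, dem$z)
})

test_that("degenerate DEM inputs behave", {
  one <- point_cloud(data.frame(x = 1, y = 1, z = 5))
  dem <- build_dem(one, cell_size_m = 0.5)
  expect_equal(c(dem$nrow, dem$ncol), c(1, 1))
  expect_equal(as.vector(dem$z), 5)

  flat <- point_cloud(data.frame(x = runif(100, 0, 4), y = runif(100, 0, 4),
                                 z = 7))
  demf <- build_dem(flat)
  expect_true(all(demf$z == 7))
  expect_error(build_dem(point_cloud(NULL)), "no ground points")
})

test_that("height normalization subtracts the DEM and is invertible", {
  dem <- build_dem(point_cloud(data.frame(x = runif(200, 0, 5),
                                          y = runif(200, 0, 5), z = 3)))
  pc <- point_cloud(data.frame(x = runif(50, 0, 5), y = runif(50, 0, 5),
                               z = runif(50, 3, 15)))
  norm <- normalize_heights(pc, dem)
  expect_true(is_normalized(norm))
  expect_equal(norm$z, pc$z - 3)
  back <- denormalize_heights(norm, dem)
  expect_equal(back$z, pc$z)
  expect_false(is_normalized(back))
})

test_that("stand normalization recovers truth heights within tolerance", {
  st <- small_stand(n = 5, seed = 35)
  als <- render_als(st, fast_als(noise_sd_m = 0.005))
  cls <- classify_ground(als)
  norm <- normalize_heights(cls, build_dem(cls))
  df <- tibble::as_tibble(norm)
  # ground points sit near zero
  expect_lt(max(abs(df$z[df$truth_class == "ground"])), 0.3)
  # the top of each labelled plant approximates its truth height
  tops <- tapply(df$z[!is.na(df$plant_id)], df$plant_id[!is.na(df$plant_id)], max)
  truth <- st$plants$height_m[as.integer(names(tops))]
  expect_lt(max(abs(tops - truth)), 0.25)
})
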
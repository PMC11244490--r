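test_that("point_cloud validates coordinates and carries frame metadata", {
  pc <- point_cloud(data.frame(x = 1:3, y = 0, z = c(1, 5, 2)))
  expect_s3_class(pc, "bamboo_cloud")
  expect_equal(cloud_frame(pc), "projected")
  expect_false(is_normalized(pc))
  expect_equal(nrow(point_cloud(NULL)), 0)

  expect_error(point_cloud(data.frame(x = 1, y = 2)), "missing")
  expect_error(point_cloud(data.frame(x = NaN, y = 0, z = 0)), "non-finite")
  expect_error(point_cloud(data.frame(x = Inf, y = 0, z = 0)), "non-finite")
})

test_that("merge_clouds concatenates, preserves tags, and checks frames", {
  a <- point_cloud(data.frame(x = 1:5, y = 0, z = 1, source = "als"))
  b <- point_cloud(data.frame(x = 1:3, y = 1, z = 2, source = "tls"))
  m <- merge_clouds(a, b)
  expect_equal(nrow(m), 8)
  expect_equal(as.vector(table(m$source)), c(5, 3))

  expect_equal(nrow(merge_clouds(a, point_cloud(NULL))), 5)
  expect_equal(nrow(merge_clouds(point_cloud(NULL), b)), 3)

  local_b <- point_cloud(data.frame(x = 1, y = 1, z = 1), frame = "local")
  expect_error(merge_clouds(a, local_b), "different frames")
})

test_that("voxel thinning keeps one point per voxel deterministically", {
  set.seed(1)
  pc <- point_cloud(data.frame(x = runif(500), y = runif(500), z = runif(500)))
  th1 <- voxel_thin(pc, 0.2)
  th2 <- voxel_thin(pc, 0.2)
  expect_identical(tibble::as_tibble(th1), tibble::as_tibble(th2))
  expect_lt(nrow(th1), nrow(pc))
  key <- with(th1, paste(floor(x / 0.2), floor(y / 0.2), floor(z / 0.2)))
  expect_false(anyDuplicated(key) > 0)
})

test_that("XYZ text round-trips at fixed precision", {
  pc <- point_cloud(data.frame(x = c(1.23456, -2), y = c(0, 10.5),
                               z = c(100.0001, 3)))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_point_cloud(pc, path, digits = 4)
  back <- read_point_cloud(path)
  expect_equal(coords <- as.matrix(tibble::as_tibble(back)[, 1:3]),
               round(as.matrix(tibble::as_tibble(pc)[, 1:3]), 4))
  # read of write of read is exact at the same precision
  write_point_cloud(back, path, digits = 4)
  again <- read_point_cloud(path)
  expect_equal(tibble::as_tibble(again), tibble::as_tibble(back))
})

test_that("empty and malformed cloud files are handled", {
  path <- withr::local_tempfile(fileext = ".xyz")
  file.create(path)
  expect_warning(pc <- read_point_cloud(path), "empty")
  expect_equal(nrow(pc), 0)

  writeLines(c("1 2 3", "4 not_a_number 6"), path)
  expect_error(read_point_cloud(path), "malformed")
  writeLines(c("1 2 3", "4 NaN 6"), path)
  expect_error(read_point_cloud(path), "non-finite")
})

test_that("LAS round-trips coordinates, classification, source and labels", {
  set.seed(2)
  n <- 200
  pc <- point_cloud(tibble::tibble(
    x = runif(n, 0, 10), y = runif(n, 0, 10), z = runif(n, 40, 60),
    classification = sample(c(1L, 2L), n, TRUE),
    source = sample(c("als", "tls"), n, TRUE),
    segment_id = sample(c(NA, 1:5), n, TRUE)
  ))
  path <- withr::local_tempfile(fileext = ".las")
  write_point_cloud(pc, path, scale = 0.001)
  back <- read_point_cloud(path)
  expect_equal(back$x, pc$x, tolerance = 1e-3)
  expect_equal(back$y, pc$y, tolerance = 1e-3)
  expect_equal(back$z, pc$z, tolerance = 1e-3)
  expect_lte(max(abs(back$x - pc$x)), 0.001 / 2 + 1e-9) # quantization bound
  expect_equal(back$classification, pc$classification)
  expect_equal(back$source, pc$source)
  expect_equal(back$segment_id, pc$segment_id)

  # empty cloud writes a valid file
  write_point_cloud(point_cloud(NULL), path, format = "las")
  expect_warning(empty <- read_point_cloud(path), "empty")
  expect_equal(nrow(empty), 0)
})

test_that("control-point and inventory tables are validated", {
  ctl <- tibble::tibble(
    target_id = paste0("T", 1:4),
    local_x = c(0, 10, 10, 0), local_y = c(0, 0, 10, 10), local_z = 0,
    proj_x = c(0, 10, 10, 0), proj_y = c(0, 0, 10, 10), proj_z = 50
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_control_points(ctl, path)
  expect_equal(nrow(read_control_points(path)), 4)

  expect_error(bamboostand:::validate_control_points(ctl[1:2, ]), "at least 3")
  dup <- ctl; dup$target_id[2] <- "T1"
  expect_error(bamboostand:::validate_control_points(dup), "duplicate")
  bad <- ctl; bad$proj_z[1] <- NA
  expect_error(bamboostand:::validate_control_points(bad), "finite")

  inv <- tibble::tibble(plant_id = 1:37, x = runif(37, 0, 10),
                        y = runif(37, 0, 10), dbh_m = 0.09, height_m = 13)
  write_inventory(inv, path)
  expect_equal(nrow(read_inventory(path)), 37)
  inv$dbh_m[1] <- -0.1
  expect_error(bamboostand:::validate_inventory(inv), "dbh_m")
})
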
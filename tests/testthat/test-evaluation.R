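ref_grid <- function(n) {
  k <- ceiling(sqrt(n))
  g <- expand.grid(x = seq(1, 9, length.out = k), y = seq(1, 9, length.out = k))
  tibble::tibble(plant_id = seq_len(n), x = g$x[seq_len(n)], y = g$y[seq_len(n)])
}

det_at <- function(ref, ids = ref$plant_id, jitter = 0) {
  tibble::tibble(segment_id = seq_along(ids),
                 apex_x = ref$x[match(ids, ref$plant_id)] + jitter,
                 apex_y = ref$y[match(ids, ref$plant_id)])
}

test_that("exact detections match one-to-one with no errors", {
  ref <- ref_grid(12)
  m <- match_detections(det_at(ref), ref, threshold_m = 1)
  expect_equal(c(m$nt, m$nc, m$no), c(12L, 0L, 0L))
  expect_equal(sort(tidy(m)$plant_id), ref$plant_id)
})

test_that("commissions and omissions are counted like a field survey", {
  # 37 reference plants; 40 detections of which 36 sit near distinct plants
  ref <- ref_grid(37)
  near <- det_at(ref, ids = 1:36, jitter = 0.2)
  far <- tibble::tibble(segment_id = 37:40,
                        apex_x = c(0.1, 0.1, 9.9, 9.9) + c(0, 0, 0, 0),
                        apex_y = c(0.05, 9.95, 0.05, 9.95))
  # keep the spurious detections away from any reference
  m <- match_detections(dplyr::bind_rows(near, far), ref, threshold_m = 0.5)
  expect_equal(c(m$nt, m$nc, m$no), c(36L, 4L, 1L))

  none <- match_detections(det_at(ref)[0, ], ref, threshold_m = 1)
  expect_equal(c(none$nt, none$nc, none$no), c(0L, 0L, 37L))
})

test_that("matching is one-to-one, nearest-first, and label-invariant", {
  ref <- tibble::tibble(plant_id = 1:2, x = c(0, 1), y = c(0, 0))
  det <- tibble::tibble(segment_id = 1:2, apex_x = c(0.4, 0.45), apex_y = 0)
  m <- match_detections(det, ref, threshold_m = 1)
  expect_equal(m$nt, 2L)
  # the globally nearest pair wins first: det2 (0.45) -> ref1? no: det1 at 0.4
  pair1 <- m$pairs[m$pairs$plant_id == 1, ]
  expect_equal(pair1$segment_id, 1L)

  # relabeling detections changes ids, not the matching structure
  det_shuffled <- det[2:1, ]
  det_shuffled$segment_id <- c(7L, 9L)
  m2 <- match_detections(det_shuffled, ref, threshold_m = 1)
  expect_equal(m2$nt, m$nt)
  expect_equal(sort(m2$pairs$distance_m), sort(m$pairs$distance_m))
})

test_that("recall, precision and F follow their definitions", {
  got <- detection_metrics(tibble::tibble(nt = 36, nc = 4, no = 1))
  expect_equal(round(100 * got$recall, 2), 97.30)
  expect_equal(round(100 * got$precision, 2), 90.00)
  expect_equal(round(got$f_score, 2), 0.94)

  got2 <- detection_metrics(tibble::tibble(nt = 29, nc = 9, no = 23))
  expect_equal(round(100 * got2$recall, 2), 55.77)
  expect_equal(round(100 * got2$precision, 2), 76.32)
  expect_equal(round(got2$f_score, 2), 0.64)

  # r = p implies F = r (harmonic mean of equals)
  eq <- detection_metrics(tibble::tibble(nt = 30, nc = 10, no = 10))
  expect_equal(eq$f_score, eq$recall)

  # degenerate zero-detection case
  zero <- detection_metrics(tibble::tibble(nt = 0, nc = 0, no = 5))
  expect_equal(c(zero$recall, zero$precision, zero$f_score), c(0, 0, 0))

  expect_error(detection_metrics(tibble::tibble(nt = -1, nc = 0, no = 1)),
               ">= 0")
  expect_error(detection_metrics(tibble::tibble(nt = 0, nc = 3, no = 0)),
               "reference")
})

test_that("F lies between recall and precision (harmonic-mean bounds)", {
  set.seed(71)
  for (i in 1:200) {
    nt <- sample(0:50, 1); nc <- sample(0:20, 1); no <- sample(0:30, 1)
    if (nt + no == 0) no <- 1
    g <- detection_metrics(tibble::tibble(nt = nt, nc = nc, no = no))
    expect_gte(g$f_score, min(g$recall, g$precision) - 1e-12)
    expect_lte(g$f_score, max(g$recall, g$precision) + 1e-12)
  }
})

test_that("trait regression metrics follow their closed forms", {
  exact <- regression_metrics(estimate = c(1, 2, 3), truth = c(1, 2, 3))
  expect_equal(c(exact$rmse, exact$r_squared), c(0, 1))

  shifted <- regression_metrics(estimate = c(2, 3, 4), truth = c(1, 2, 3))
  expect_equal(c(shifted$rmse, shifted$r_squared, shifted$bias), c(1, 1, 1))

  df <- tibble::tibble(est = c(1, 2, 4), ref = c(1, 2, 3))
  expect_equal(regression_metrics(df, est, ref)$rmse, sqrt(1 / 3))

  expect_warning(flat <- regression_metrics(estimate = c(1, 2), truth = c(3, 3)),
                 "zero variance")
  expect_true(is.na(flat$r_squared))
  expect_warning(tiny <- regression_metrics(estimate = 1, truth = 1),
                 "fewer than 2")
  expect_true(is.na(tiny$rmse))
})
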
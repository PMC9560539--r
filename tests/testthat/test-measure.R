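test_that("refinement removes speckles, keeps the body, adds no components", {
  m <- matrix(0L, 60, 80)
  m[16:45, 21:60] <- 1L
  speckles <- rbind(c(5, 5), c(55, 70), c(8, 75))
  m[speckles] <- 1L
  out <- refine_mask(m, 5)
  expect_true(all(out[speckles] == 0L))
  # interior preserved; boundary may lose at most the kernel radius
  expect_true(all(out[19:42, 24:57] == 1L))
  expect_true(all(out[m == 0L] == 0L))      # never grows here (no holes)
  expect_equal(max(EBImage::bwlabel(out)), 1)
  expect_error(refine_mask(matrix(0L, 5, 5)), "no foreground")
})

test_that("refinement fills interior holes via closing", {
  m <- matrix(0L, 40, 40)
  m[10:30, 10:30] <- 1L
  m[20, 20] <- 0L
  out <- refine_mask(m, 5)
  expect_equal(out[20, 20], 1L)
})

test_that("axis-aligned sign calibration is exact division", {
  m <- matrix(0L, 150, 260)
  m[26:125, 31:230] <- 1L                   # 100 rows x 200 cols
  sc <- extract_calibration(m, sign_cm = c(50, 25))
  expect_equal(sc$px_per_cm_x, 4, tolerance = 1e-6)
  expect_equal(sc$px_per_cm_y, 4, tolerance = 1e-6)
})

test_that("rotated signs calibrate within 2%", {
  theta <- 10 * pi / 180
  H <- 220; W <- 300
  cx <- 150; cy <- 110
  cols <- matrix(rep(1:W, each = H), H, W, byrow = FALSE)
  rows <- matrix(rep(1:H, W), H, W)
  u <- (cols - cx) * cos(theta) + (rows - cy) * sin(theta)
  v <- -(cols - cx) * sin(theta) + (rows - cy) * cos(theta)
  m <- (abs(u) <= 100 & abs(v) <= 50) * 1L   # 200 x 100 px sign, rotated
  sc <- suppressWarnings(extract_calibration(m, sign_cm = c(50, 25)))
  expect_equal(sc$px_per_cm_x, 4, tolerance = 0.02)
  expect_equal(sc$px_per_cm_y, 4, tolerance = 0.02)
})

test_that("degenerate sign masks raise errors", {
  expect_error(extract_calibration(matrix(0L, 10, 10), c(10, 5)), "empty")
  thin <- matrix(0L, 10, 30); thin[5, 2:29] <- 1L
  expect_error(extract_calibration(thin, c(10, 5)), "degenerate")
  expect_error(extract_calibration(matrix(1L, 4, 4), c(0, 5)), "positive")
})

test_that("calibration warns on anisotropy above 5%", {
  expect_warning(calibration_scale(4, 4.3), "anisotropy")
  expect_silent(calibration_scale(4, 4.1))
  expect_error(calibration_scale(0, 4), "> 0")
})

test_that("side measures recover a clean generated silhouette", {
  sc <- generate_scene(scene_spec(seed = 21, pose = "side",
                                  body_height_cm = 60, body_length_cm = 75,
                                  chest_depth_cm = 30, px_per_cm = 4,
                                  noise_sd = 0, blur_sigma = 0))
  m <- sc$truth$silhouette_mask
  got <- measure_side(m, calibration_scale(4, 4))
  expect_equal(got$height_cm, 60, tolerance = 0.01)
  expect_equal(got$length_cm, 75, tolerance = 0.02)
  expect_equal(got$chest_depth_cm, 30, tolerance = 0.02)
  expect_equal(got$head_side, "left")
  expect_error(measure_side(matrix(0L, 5, 5), calibration_scale(4, 4)),
               "empty mask")
})

test_that("side measures are mirror-invariant via head detection", {
  sc <- generate_scene(scene_spec(seed = 22, pose = "side", px_per_cm = 2,
                                  noise_sd = 0, blur_sigma = 0))
  m <- sc$truth$silhouette_mask
  flipped <- m[, ncol(m):1]
  a <- measure_side(m, calibration_scale(2, 2))
  b <- measure_side(flipped, calibration_scale(2, 2))
  expect_equal(b$head_side, "right")
  expect_equal(a$height_cm, b$height_cm)
  expect_equal(a$length_cm, b$length_cm)
  expect_equal(a$chest_depth_cm, b$chest_depth_cm)
})

test_that("rear measures recover the chest width", {
  sc <- generate_scene(scene_spec(seed = 23, pose = "rear",
                                  chest_width_cm = 30, px_per_cm = 4,
                                  noise_sd = 0, blur_sigma = 0))
  got <- measure_rear(sc$truth$silhouette_mask, calibration_scale(4, 4))
  expect_equal(got$chest_width_cm, 30, tolerance = 0.02)
  expect_error(measure_rear(matrix(0L, 5, 5), calibration_scale(4, 4)),
               "empty mask")
})

test_that("centimetre values scale linearly with the calibration factor", {
  sc <- generate_scene(scene_spec(seed = 24, pose = "side", px_per_cm = 2,
                                  noise_sd = 0, blur_sigma = 0))
  m <- sc$truth$silhouette_mask
  at1 <- measure_side(m, calibration_scale(2, 2))
  at2 <- measure_side(m, calibration_scale(4, 4))
  expect_equal(at2$height_cm, at1$height_cm / 2)
  expect_equal(at2$length_cm, at1$length_cm / 2)
})

test_that("girth matches the circle limit and errors on bad input", {
  expect_equal(estimate_girth(20, 20), pi * 20, tolerance = 1e-12)
  expect_error(estimate_girth(0, 10), "> 0")
  expect_error(estimate_girth(10, -1), "> 0")
})

test_that("girth approximation tracks numerical arc length within 0.5%", {
  ellipse_perimeter <- function(a, b) {
    4 * stats::integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2),
                         0, pi / 2, rel.tol = 1e-10)$value
  }
  # printed example: depth 30, width 20
  expect_equal(estimate_girth(30, 20), ellipse_perimeter(15, 10),
               tolerance = 0.005 * ellipse_perimeter(15, 10))
  expect_equal(round(estimate_girth(30, 20), 1), 79.3)
  for (ratio in c(1, 1.5, 2, 3)) {
    want <- ellipse_perimeter(ratio * 10, 10)
    got <- estimate_girth(2 * ratio * 10, 2 * 10)
    expect_lt(abs(got - want) / want, 0.005)
  }
  # bounds: between the inscribed and circumscribed circles
  g <- estimate_girth(30, 20)
  expect_gte(g, pi * 20)
  expect_lte(g, pi * 30)
})

test_that("combining measurements derives girth and flags missing poses", {
  sc_s <- generate_scene(scene_spec(seed = 25, pose = "side", px_per_cm = 2,
                                    noise_sd = 0, blur_sigma = 0))
  sc_r <- generate_scene(scene_spec(seed = 25, pose = "rear", px_per_cm = 2,
                                    noise_sd = 0, blur_sigma = 0))
  side <- measure_side(sc_s$truth$silhouette_mask, calibration_scale(2, 2))
  rear <- measure_rear(sc_r$truth$silhouette_mask, calibration_scale(2, 2))
  full <- combine_measurements(side, rear)
  expect_equal(full$girth_cm,
               estimate_girth(side$chest_depth_cm, rear$chest_width_cm))
  expect_setequal(full$pose_sources, c("side", "rear"))
  expect_warning(partial <- combine_measurements(side, NULL), "girth omitted")
  expect_true(is.na(partial$girth_cm))
})
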
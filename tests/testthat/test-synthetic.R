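test_that("scene rendering is deterministic given the seed", {
  a <- generate_scene(scene_spec(seed = 5, pose = "side"))
  b <- generate_scene(scene_spec(seed = 5, pose = "side"))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$silhouette_mask, b$truth$silhouette_mask)
})

test_that("ground-truth extents follow the physical dimensions", {
  sc <- generate_scene(scene_spec(seed = 1, pose = "side",
                                  body_height_cm = 60, px_per_cm = 4,
                                  noise_sd = 0, blur_sigma = 0))
  sil <- sc$truth$silhouette_mask
  rows <- which(rowSums(sil) > 0)
  expect_equal(rows[length(rows)] - rows[1] + 1, 60 * 4)
})

test_that("noiseless unblurred scenes render the backdrop exactly", {
  spec <- scene_spec(seed = 2, pose = "rear", noise_sd = 0, brightness = 1,
                     blur_sigma = 0)
  sc <- generate_scene(spec)
  back <- sc$truth$silhouette_mask == 0L & sc$truth$sign_mask == 0L
  for (k in 1:3) {
    ch <- sc$image$pixels[, , k]
    expect_true(all(ch[back] == spec$backdrop_color[k]))
  }
  # silhouette and sign truth masks are disjoint
  expect_true(all(sc$truth$silhouette_mask + sc$truth$sign_mask <= 1L))
})

test_that("colour step recovers the backdrop complement exactly on a noiseless scene", {
  for (pose in c("side", "rear")) {
    sc <- generate_scene(scene_spec(seed = 3, pose = pose, noise_sd = 0,
                                    brightness = 1, blur_sigma = 0))
    ret <- chroma_step(sc$image)$retention
    want <- pmin(sc$truth$silhouette_mask + sc$truth$sign_mask, 1L)
    expect_identical(ret, unname(want))
  }
})

test_that("colour step tolerates noise_sd 8 at the default threshold", {
  sc <- generate_scene(scene_spec(seed = 4, pose = "side", noise_sd = 8,
                                  blur_sigma = 0))
  ret <- chroma_step(sc$image)$retention
  sil <- sc$truth$silhouette_mask > 0
  back <- sc$truth$silhouette_mask == 0L & sc$truth$sign_mask == 0L
  expect_gte(mean(ret[sil] == 1L), 0.999)
  expect_gte(mean(ret[back] == 0L), 0.99)
})

test_that("JPEG round trips are lossy, monotonically in quality, then stable as PNG", {
  sc <- generate_scene(scene_spec(seed = 6, pose = "rear", noise_sd = 0,
                                  blur_sigma = 0))
  q95 <- degrade_jpeg(sc$image, 95)
  expect_gt(sum(q95$pixels != sc$image$pixels), 0)
  expect_equal(q95$source_format, "jpg")

  q10 <- degrade_jpeg(sc$image, 10)
  mae <- function(img) mean(abs(img$pixels - sc$image$pixels))
  expect_gt(mae(q10), mae(q95))

  path <- withr::local_tempfile(fileext = ".png")
  write_png(q95, path)
  expect_identical(load_image(path)$pixels, q95$pixels)
})

test_that("lossy inputs never reduce annotation effort", {
  # in-kind check of the compression effect: the robot-refined two-step
  # pipeline on JPEG-degraded scenes needs at least as many strokes, and
  # reaches no better IoU, than on the lossless originals
  orig_strokes <- deg_strokes <- orig_iou <- deg_iou <- numeric(12)
  for (s in 1:12) {
    pose <- if (s %% 2) "side" else "rear"
    sc <- generate_scene(random_scene_spec(5000 + s, pose = pose,
                                           shadow = TRUE))
    box <- scene_bounding_box(sc)
    truth <- sc$truth$silhouette_mask
    o <- segment_with_robot(chroma_step(sc$image)$image, truth, box)
    d <- segment_with_robot(chroma_step(degrade_jpeg(sc$image, 70))$image,
                            truth, box)
    orig_strokes[s] <- o$strokes; deg_strokes[s] <- d$strokes
    orig_iou[s] <- o$iou; deg_iou[s] <- d$iou
  }
  expect_true(all(deg_strokes >= orig_strokes))
  expect_lte(mean(deg_iou), mean(orig_iou))
})

test_that("scene specification enforces protocol colour margins", {
  expect_error(scene_spec(backdrop_color = c(100, 100, 150)), "B - R >= 80")
  expect_error(scene_spec(coat_color = c(60, 100, 150)), "B - R <= 0")
  expect_error(scene_spec(body_height_cm = 20, chest_depth_cm = 30),
               "exceed chest depth")
})

test_that("random scene specifications stay inside protocol margins", {
  for (s in 1:20) {
    spec <- random_scene_spec(s, pose = if (s %% 2) "side" else "rear")
    expect_lte(spec$coat_color[3] - spec$coat_color[1], -40)
    expect_gte(spec$backdrop_color[3] - spec$backdrop_color[1], 80)
    expect_true(all(unlist(spec[c("body_height_cm", "body_length_cm",
                                  "chest_width_cm", "chest_depth_cm")]) > 0))
  }
})
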
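test_that("stroke counting: one rasterized pixel is one stroke", {
  box <- bounding_box(2, 2, 5, 5)
  line10 <- stroke_event("sure_foreground", cbind(x = c(3, 3), y = c(2, 11)))
  expect_equal(count_strokes(annotation_set(bounding_box(2, 2, 10, 12),
                                            list(line10))), 10)
  expect_equal(count_strokes(annotation_set(box)), 0)
  # duplicates across separate events count per event
  two <- annotation_set(bounding_box(2, 2, 10, 12), list(line10, line10))
  expect_equal(count_strokes(two), 20)
  # duplicates within one event are deduplicated
  there_and_back <- stroke_event("sure_background",
                                 cbind(x = c(2, 6, 2), y = c(3, 3, 3)))
  expect_equal(count_strokes(annotation_set(box, list(there_and_back))), 5)
})

test_that("diagonal polylines rasterize with a deterministic line algorithm", {
  ev <- stroke_event("sure_foreground", cbind(x = c(1, 5), y = c(1, 5)))
  px <- preciseedge:::rasterize_stroke(ev)
  expect_equal(nrow(px), 5)
  expect_true(all(px[, 1] == px[, 2]))
})

test_that("annotation persistence round-trips through JSON", {
  ann <- annotation_set(
    bounding_box(3, 4, 20, 15),
    list(stroke_event("sure_foreground", cbind(x = c(5, 9), y = c(6, 6))),
         stroke_event("sure_background", cbind(x = 12, y = 10))))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$box, ann$box)
  expect_equal(length(back$events), 2)
  expect_equal(back$events[[1]]$label, "sure_foreground")
  expect_equal(unname(back$events[[1]]$path), unname(ann$events[[1]]$path))
  expect_equal(count_strokes(back), count_strokes(ann))
})

test_that("compiled min-cut matches igraph max-flow on random grids", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (rep in 1:5) {
    nb <- sample(4:9, 1); mb <- sample(4:9, 1)
    n <- nb * mb
    wr <- sample(0:30, nb * (mb - 1), replace = TRUE)
    wd <- sample(0:30, (nb - 1) * mb, replace = TRUE)
    src <- sample(0:50, n, replace = TRUE)
    snk <- sample(0:50, n, replace = TRUE)
    got <- preciseedge:::.grid_mincut(nb, mb, wr, wd, src, snk)

    idx <- matrix(seq_len(n), nb, mb)
    pr <- cbind(as.vector(idx[, -mb]), as.vector(idx[, -1]))
    pd <- cbind(as.vector(idx[-nb, ]), as.vector(idx[-1, ]))
    S <- n + 1L; Tn <- n + 2L
    edges <- rbind(pr, pr[, 2:1], pd, pd[, 2:1],
                   cbind(S, seq_len(n)), cbind(seq_len(n), Tn))
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    fl <- igraph::max_flow(g, S, Tn, capacity = c(wr, wr, wd, wd, src, snk))
    # the solver drops the common part of each node's terminal capacities,
    # which lowers the flow by exactly sum(pmin(src, snk))
    expect_equal(got$flow + sum(pmin(src, snk)), fl$value)
    # the returned labelling must itself achieve the minimal cut value
    lab <- got$foreground
    cut <- sum(src[!lab]) + sum(snk[lab]) +
      sum(wr[lab[pr[, 1]] != lab[pr[, 2]]]) +
      sum(wd[lab[pd[, 1]] != lab[pd[, 2]]])
    expect_equal(cut, fl$value)
  }
})

test_that("graph cut recovers a clean rectangle exactly from the box alone", {
  sc <- rectangle_scene()
  box <- bounding_box(x = 21, y = 16, w = 45, h = 35)   # 5 px margin
  mask <- run_grabcut(sc$image, annotation_set(box))
  expect_identical(mask, sc$truth)
})

test_that("contract errors: full-image box and out-of-image strokes", {
  sc <- rectangle_scene()
  expect_error(run_grabcut(sc$image,
                           annotation_set(bounding_box(1, 1, 80, 60))),
               "whole image")
  bad <- annotation_set(
    bounding_box(21, 16, 45, 35),
    list(stroke_event("sure_background", cbind(x = 99, y = 1))))
  expect_error(run_grabcut(sc$image, bad), "outside the image")
  outside_fg <- annotation_set(
    bounding_box(21, 16, 45, 35),
    list(stroke_event("sure_foreground", cbind(x = 2, y = 2))))
  expect_error(run_grabcut(sc$image, outside_fg), "outside the bounding box")
})

test_that("hard stroke constraints always hold in the output", {
  sc <- rectangle_scene()
  box <- bounding_box(21, 16, 45, 35)
  # background stroke across coat-coloured pixels forces them out
  bg <- stroke_event("sure_background", cbind(x = c(30, 40), y = c(30, 30)))
  m1 <- run_grabcut(sc$image, annotation_set(box, list(bg)))
  expect_true(all(m1[30, 30:40] == 0L))
  # foreground stroke on black pixels inside the box forces them in
  fg <- stroke_event("sure_foreground", cbind(x = c(22, 24), y = c(17, 17)))
  m2 <- run_grabcut(sc$image, annotation_set(box, list(fg)))
  expect_true(all(m2[17, 22:24] == 1L))
  # support: foreground never escapes the box
  inside <- matrix(0L, 60, 80)
  inside[16:50, 21:65] <- 1L
  expect_true(all(m1[inside == 0L] == 0L))
  expect_true(all(m2[inside == 0L] == 0L))
})

test_that("mask_iou scores exact masks and honours the tolerance band", {
  a <- matrix(0L, 20, 20); a[5:15, 5:15] <- 1L
  expect_equal(mask_iou(a, a), 1)
  b <- a; b[5, ] <- 0L                      # one-row erosion at the edge
  expect_lt(mask_iou(b, a), 1)
  expect_equal(mask_iou(b, a, boundary_tolerance = 1), 1)
  expect_error(mask_iou(a, matrix(0L, 5, 5)), "shape")
})

test_that("robot annotator emits nothing when converged", {
  t <- matrix(0L, 30, 30); t[8:22, 8:22] <- 1L
  box <- bounding_box(5, 5, 22, 22)
  expect_equal(robot_annotate(t, t, box), list())
})

test_that("robot annotator marks missing regions as sure foreground", {
  t <- matrix(0L, 40, 40); t[6:34, 6:34] <- 1L
  cur <- t
  cur[12:21, 12:21] <- 0L                   # 10 x 10 hole
  box <- bounding_box(3, 3, 36, 36)
  ev <- robot_annotate(cur, t, box)
  fg <- Filter(function(e) e$label == "sure_foreground", ev)
  expect_gt(length(fg), 0)
  pts <- do.call(rbind, lapply(fg, function(e) e$path))
  expect_true(all(pts[, "x"] >= 12 & pts[, "x"] <= 21 &
                    pts[, "y"] >= 12 & pts[, "y"] <= 21))
})

test_that("robot annotator marks false-positive blobs as sure background", {
  t <- matrix(0L, 40, 40); t[6:20, 6:20] <- 1L
  cur <- t
  cur[28:37, 28:37] <- 1L                   # 10 x 10 spurious blob
  box <- bounding_box(3, 3, 36, 36)
  ev <- robot_annotate(cur, t, box)
  bg <- Filter(function(e) e$label == "sure_background", ev)
  expect_gt(length(bg), 0)
  pts <- do.call(rbind, lapply(bg, function(e) e$path))
  expect_true(all(pts[, "x"] >= 28 & pts[, "x"] <= 37 &
                    pts[, "y"] >= 28 & pts[, "y"] <= 37))
})

test_that("stroke events are capped at the configured length", {
  t <- matrix(0L, 60, 60); t[10:50, 10:50] <- 1L
  cur <- matrix(0L, 60, 60)                 # everything missing
  box <- bounding_box(5, 5, 52, 52)
  ev <- robot_annotate(cur, t, box, max_stroke_len = 30)
  lens <- vapply(ev, function(e)
    nrow(preciseedge:::rasterize_stroke(e)), integer(1))
  expect_true(all(lens <= 30))
})

test_that("robot refinement converges on a synthetic scene", {
  sc <- generate_scene(scene_spec(seed = 9, pose = "rear", shadow = TRUE))
  res <- segment_with_robot(chroma_step(sc$image)$image,
                            sc$truth$silhouette_mask,
                            scene_bounding_box(sc))
  expect_gte(res$iou, 0.98)
  expect_lte(res$rounds, 10)
})
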
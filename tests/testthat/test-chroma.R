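one_px <- function(rgb) rgb_image(array(as.numeric(rgb), dim = c(1, 1, 3)))

test_that("channel splitting widens without changing values", {
  ch <- split_and_widen(one_px(c(10, 20, 200)))
  expect_identical(c(ch$R[1, 1], ch$G[1, 1], ch$B[1, 1]), c(10L, 20L, 200L))
  # signed arithmetic: no unsigned wraparound
  expect_identical(ch$R[1, 1] - ch$B[1, 1], -190L)
  zero <- split_and_widen(one_px(c(0, 0, 0)))
  expect_true(all(zero$R == 0L & zero$G == 0L & zero$B == 0L))
})

test_that("difference matrices follow BR = B - R and GR = G - R", {
  d <- with(split_and_widen(one_px(c(10, 20, 200))),
            difference_matrices(R, G, B))
  expect_equal(c(d$BR[1, 1], d$GR[1, 1]), c(190, 10))
  d2 <- with(split_and_widen(one_px(c(100, 100, 100))),
             difference_matrices(R, G, B))
  expect_equal(c(d2$BR[1, 1], d2$GR[1, 1]), c(0, 0))
  d3 <- with(split_and_widen(one_px(c(200, 120, 60))),
             difference_matrices(R, G, B))
  expect_equal(c(d3$BR[1, 1], d3$GR[1, 1]), c(-140, -80))
  expect_error(difference_matrices(matrix(0, 2, 2), matrix(0, 2, 3),
                                   matrix(0, 2, 2)), "shape")
})

test_that("near-equality marks achromatic pixels at the tolerance", {
  neq <- function(rgb, tol = 5, pair = "GR") {
    d <- with(split_and_widen(one_px(rgb)), difference_matrices(R, G, B))
    near_equality_mask(d, tol, pair)[1, 1]
  }
  expect_identical(neq(c(100, 100, 100)), 1L)
  expect_identical(neq(c(100, 104, 97)), 1L)   # BR = -3, GR = 4
  expect_identical(neq(c(10, 20, 200)), 0L)
  # BG convention differs where |B-G| and |G-R| disagree
  expect_identical(neq(c(100, 106, 103), pair = "GR"), 0L)  # GR = 6
  expect_identical(neq(c(100, 106, 103), pair = "BG"), 1L)  # BG = -3
})

test_that("blue removal is inclusive at the threshold", {
  brm <- function(br, thr) {
    d <- list(BR = matrix(br, 1, 1))
    blue_removal_mask(d, thr)[1, 1]
  }
  expect_identical(brm(190, 40), 0L)
  expect_identical(brm(-140, 40), 1L)   # brown retained
  expect_identical(brm(39, 40), 1L)
  expect_identical(brm(40, 40), 0L)
  expect_error(blue_removal_mask(list(BR = matrix(0, 1, 1)), 121))
})

test_that("retention matrix is the clamped OR of its inputs", {
  e <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  b <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  r <- retention_matrix(e, b)
  expect_identical(as.vector(r), c(0L, 1L, 1L, 1L))   # never 2
  expect_error(retention_matrix(matrix(0L, 1, 2), matrix(0L, 2, 1)), "shape")
})

test_that("apply_retention zeroes removed pixels and keeps the rest intact", {
  img <- random_test_image(8, 9, seed = 11)
  ones <- matrix(1L, 8, 9)
  expect_identical(apply_retention(img, ones)$pixels, img$pixels)
  zeros <- matrix(0L, 8, 9)
  expect_true(all(apply_retention(img, zeros)$pixels == 0L))
  mixed <- matrix(rbinom(72, 1, 0.5), 8, 9)
  out <- apply_retention(img, mixed)
  for (k in 1:3) {
    expect_identical(out$pixels[, , k][mixed == 0L],
                     rep(0L, sum(mixed == 0L)))
    expect_identical(out$pixels[, , k][mixed == 1L],
                     img$pixels[, , k][mixed == 1L])
  }
})

test_that("pure blue is fully removed and greyscale passes unchanged", {
  blue <- rgb_image(array(rep(c(0, 0, 255), each = 25), dim = c(5, 5, 3)))
  res <- chroma_step(blue)
  expect_true(all(res$image$pixels == 0L))
  expect_true(all(res$retention == 0L))

  set.seed(12)
  g <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  grey <- rgb_image(array(rep(g, 3), dim = c(5, 5, 3)))
  res2 <- chroma_step(grey, chroma_params(threshold = 0))
  expect_identical(res2$image$pixels, grey$pixels)
})

test_that("vectorized colour step matches the per-pixel oracle", {
  for (seed in 1:5) {
    img <- random_test_image(16, 16, seed = 100 + seed)
    for (thr in c(0L, 5L, 40L, 120L)) {
      got <- chroma_step(img, chroma_params(threshold = thr))
      want <- chroma_pixel_oracle(img, thr)
      expect_identical(got$retention, want$retention)
      expect_identical(got$image$pixels, want$pixels)
    }
  }
})

test_that("colour step is idempotent at fixed parameters", {
  for (thr in c(0L, 40L, 120L)) {
    img <- random_test_image(20, 20, seed = 200 + thr)
    p <- chroma_params(threshold = thr)
    once <- chroma_step(img, p)
    twice <- chroma_step(once$image, p)
    expect_identical(twice$image$pixels, once$image$pixels)
  }
})

test_that("retained set is non-decreasing in the threshold", {
  img <- random_test_image(24, 24, seed = 300)
  prev <- NULL
  for (thr in seq(0L, 120L, by = 10L)) {
    ret <- chroma_step(img, chroma_params(threshold = thr))$retention
    if (!is.null(prev)) expect_true(all(ret >= prev))
    prev <- ret
  }
})
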
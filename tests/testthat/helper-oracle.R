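# Literal per-pixel reference implementation of the colour step: loops over
# every pixel and applies the near-equality, threshold, and retention rules
# exactly as written, independent of the vectorized implementation.
chroma_pixel_oracle <- function(image, threshold = 40L, tolerance = 5L) {
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  out <- px
  keep <- matrix(0L, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      r <- px[i, j, 1]; g <- px[i, j, 2]; b <- px[i, j, 3]
      br <- b - r
      gr <- g - r
      eq <- abs(br) <= tolerance && abs(gr) <= tolerance
      slide <- br < threshold
      k <- if (slide || eq) 1L else 0L
      keep[i, j] <- k
      if (k == 0L) out[i, j, ] <- 0L
    }
  }
  list(pixels = out, retention = keep)
}

# Exact null distribution of the rank-sum statistic by full enumeration,
# independent of stats::wilcox.test.
exact_ranksum_p_less <- function(b, a) {
  pooled <- c(b, a)
  n <- length(b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  mean(w_all <= w_obs)
}

random_test_image <- function(h, w, seed) {
  set.seed(seed)
  rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

# Tiny clean post-chroma-style scene: a coat-coloured rectangle on black,
# with exact ground truth.
rectangle_scene <- function(h = 60, w = 80, r0 = 21, r1 = 45, c0 = 26,
                            c1 = 60, colour = c(150, 100, 60)) {
  px <- array(0L, dim = c(h, w, 3))
  truth <- matrix(0L, h, w)
  truth[r0:r1, c0:c1] <- 1L
  for (k in 1:3) {
    ch <- matrix(0L, h, w)
    ch[r0:r1, c0:c1] <- colour[k]
    px[, , k] <- ch
  }
  list(image = rgb_image(px), truth = truth)
}
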
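#' Parameters of the chromakey colour step
#'
#' The colour step removes the blue backdrop wherever the per-pixel
#' blue-minus-red difference is at least `threshold`, except at pixels whose
#' channels are all nearly equal (grey/white features such as the
#' calibration sign), which are always retained. `threshold` corresponds to
#' the interactive track-bar position; 40 is the standard initial setting
#' that works for most backdropped images, and the track bar runs from 0
#' to 120.
#'
#' @param threshold integer blue-minus-red removal threshold (track-bar
#'   value), default 40.
#' @param threshold_max,threshold_min track-bar range, defaults 120 and 0.
#' @param equivalence_tolerance near-equality tolerance in intensity units,
#'   default 5: a pixel whose channel differences are all within this value
#'   is treated as achromatic and retained.
#' @param equivalence_pair which second channel difference is tested for
#'   near-equality alongside `|B - R|`: `"GR"` (default; `|G - R|`, the
#'   difference matrix the algorithm constructs) or `"BG"` (`|B - G|`).
#' @return A list of class `chroma_params`.
#' @export
chroma_params <- function(threshold = 40L, threshold_max = 120L,
                          threshold_min = 0L, equivalence_tolerance = 5L,
                          equivalence_pair = c("GR", "BG")) {
  equivalence_pair <- match.arg(equivalence_pair)
  threshold <- as.integer(threshold)
  if (threshold < threshold_min || threshold > threshold_max)
    stop("threshold must lie in [", threshold_min, ", ", threshold_max, "]")
  if (equivalence_tolerance < 0) stop("equivalence_tolerance must be >= 0")
  structure(list(threshold = threshold,
                 threshold_max = as.integer(threshold_max),
                 threshold_min = as.integer(threshold_min),
                 equivalence_tolerance = as.integer(equivalence_tolerance),
                 equivalence_pair = equivalence_pair),
            class = "chroma_params")
}

#' Split an image into widened signed channel matrices
#'
#' Extracts the R, G, B channels as plain signed integer matrices so that
#' later channel subtractions cannot wrap around (8-bit unsigned arithmetic
#' would turn 10 - 200 into 66; on signed values it is -190). Values are
#' unchanged numerically.
#'
#' @param image an [rgb_image()].
#' @return A list with integer matrices `R`, `G`, `B` of the image's shape.
#' @export
split_and_widen <- function(image) {
  stopifnot_rgb_image(image)
  d <- dim(image$pixels)[1:2]
  list(R = matrix(image$pixels[, , 1], d[1], d[2]),
       G = matrix(image$pixels[, , 2], d[1], d[2]),
       B = matrix(image$pixels[, , 3], d[1], d[2]))
}

#' Channel difference matrices
#'
#' @param R,G,B signed integer channel matrices of equal shape (from
#'   [split_and_widen()]).
#' @return A list with `BR = B - R` and `GR = G - R`, each in `[-255, 255]`.
#' @export
difference_matrices <- function(R, G, B) {
  if (!identical(dim(R), dim(G)) || !identical(dim(R), dim(B)))
    stop("channel matrices must share a shape")
  list(BR = B - R, GR = G - R)
}

#' Near-equality (achromatic pixel) mask
#'
#' Marks pixels whose channels are all close in value -- greys and whites --
#' which the colour step must retain regardless of the blue threshold.
#'
#' @param diffs list with `BR` and `GR` from [difference_matrices()].
#' @param tolerance non-negative integer tolerance (default 5).
#' @param pair `"GR"` to test `|B-R| <= tol & |G-R| <= tol` (default),
#'   `"BG"` to test `|B-R| <= tol & |B-G| <= tol`.
#' @return A `{0,1}` integer matrix (`equivpxls`), 1 where near-equal.
#' @export
near_equality_mask <- function(diffs, tolerance = 5L, pair = c("GR", "BG")) {
  pair <- match.arg(pair)
  if (tolerance < 0) stop("tolerance must be >= 0")
  second <- if (pair == "GR") diffs$GR else diffs$BR - diffs$GR  # B-G = BR-GR
  m <- (abs(diffs$BR) <= tolerance) & (abs(second) <= tolerance)
  mode(m) <- "integer"
  m
}

#' Blue-removal mask from the track-bar threshold
#'
#' Zero where the blue-minus-red difference is large (in
#' `[threshold, 255]`, i.e. blue backdrop), one elsewhere. The boundary is
#' inclusive on the removal side: a pixel with `B - R` exactly equal to the
#' threshold is removed.
#'
#' @param diffs list with `BR` from [difference_matrices()].
#' @param threshold integer in `[0, 120]` (track-bar value).
#' @return A `{0,1}` integer matrix (`bminusrslide`).
#' @export
blue_removal_mask <- function(diffs, threshold = 40L) {
  if (threshold < 0 || threshold > 120)
    stop("threshold must lie in [0, 120]")
  m <- diffs$BR < threshold
  mode(m) <- "integer"
  m
}

#' Combined retention matrix
#'
#' A pixel is retained (1) if the blue-removal mask retains it or the
#' near-equality mask marks it achromatic; it is removed (0) only when both
#' vote to remove. The sum of the two Boolean matrices is clamped to
#' `{0,1}` (a logical OR), since a retained pixel's intensities are later
#' multiplied by this matrix and must not be doubled.
#'
#' @param equivpxls,bminusrslide `{0,1}` matrices of equal shape.
#' @return A `{0,1}` integer matrix (`bGTr`).
#' @export
retention_matrix <- function(equivpxls, bminusrslide) {
  if (!identical(dim(equivpxls), dim(bminusrslide)))
    stop("mask shapes differ")
  m <- pmin(bminusrslide + equivpxls, 1L)
  dim(m) <- dim(equivpxls)
  mode(m) <- "integer"
  m
}

#' Apply a retention matrix to an image
#'
#' Multiplies every channel elementwise by the retention matrix and merges
#' the channels back into an image: removed pixels become (0,0,0) black,
#' retained pixels are bit-identical to the input.
#'
#' @param image an [rgb_image()].
#' @param bGTr a `{0,1}` matrix matching the image shape.
#' @return An [rgb_image()] with the backdrop suppressed.
#' @export
apply_retention <- function(image, bGTr) {
  stopifnot_rgb_image(image)
  if (!identical(dim(bGTr), dim(image$pixels)[1:2]))
    stop("mask shape does not match image")
  px <- image$pixels
  for (k in 1:3) px[, , k] <- px[, , k] * bGTr
  rgb_image(px, source_format = image$source_format,
            scale_applied = image$scale_applied)
}

#' Chromakey colour step (step 1)
#'
#' Composition of the five colour-step operations: channel split and signed
#' widening, difference matrices, near-equality mask, blue-removal mask,
#' retention matrix, and mask application. Returns both the
#' backdrop-suppressed image and the retention matrix.
#'
#' The step is idempotent at fixed parameters: removed pixels become
#' (0,0,0), which is achromatic and hence retained on a second pass, while
#' retained pixels are unchanged.
#'
#' @param image an [rgb_image()].
#' @param params a [chroma_params()] object.
#' @return A list with `image` (backdrop-suppressed [rgb_image()]) and
#'   `retention` (the `{0,1}` matrix, 1 = retained).
#' @export
chroma_step <- function(image, params = chroma_params()) {
  stopifnot_rgb_image(image)
  if (!inherits(params, "chroma_params")) stop("expected 'chroma_params'")
  ch <- split_and_widen(image)
  diffs <- difference_matrices(ch$R, ch$G, ch$B)
  equiv <- near_equality_mask(diffs, params$equivalence_tolerance,
                              pair = params$equivalence_pair)
  slide <- blue_removal_mask(diffs, params$threshold)
  bGTr <- retention_matrix(equiv, slide)
  list(image = apply_retention(image, bGTr), retention = bGTr)
}
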
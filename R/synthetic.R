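#' Specification of a synthetic backdropped scene
#'
#' Describes one test scene emulating the standardised field protocol: a
#' matte animal-like silhouette in coat colours over a blue backdrop that
#' fills the frame (tarp behind and beneath the subject), plus a rectangular
#' calibration sign of known physical size in the top-left corner. Rendering
#' is deterministic given `seed`.
#'
#' Physical dimensions are in centimetres; `px_per_cm` sets the working
#' resolution. The default 2 px/cm gives desk-scale scenes on which the
#' full segmentation loop runs quickly; all dimensions scale linearly.
#'
#' @param seed integer RNG seed for the noise field.
#' @param pose `"side"` or `"rear"`.
#' @param body_height_cm wither height: top of the back to the ground.
#' @param body_length_cm chest wall to pin bone (side pose torso length).
#' @param chest_width_cm maximum torso width seen from the rear.
#' @param chest_depth_cm vertical torso thickness at the withers (side pose).
#' @param px_per_cm rendering scale, pixels per centimetre.
#' @param sign_cm physical (width, height) of the calibration sign.
#' @param backdrop_color RGB triple of the tarp; must satisfy `B - R >= 80`.
#' @param coat_color RGB triple of the coat; must satisfy `B - R <= 0`.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param brightness global multiplicative brightness factor.
#' @param blur_sigma optical blur applied to the rendered scene (pixels);
#'   emulates camera focus/downsampling. Ground-truth masks are captured
#'   before blurring.
#' @param leg_gap_cm gap between the two rear-pose legs (rear legs are the
#'   hardest region for edge detection, so the gap is explicit).
#' @param shadow if `TRUE`, render a soft darkened band on the tarp under
#'   the belly (the region that typically confuses box-initialised graph
#'   cuts); off by default.
#' @param shadow_strength multiplicative darkening of the shadow region.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(seed = 1L, pose = c("side", "rear"),
                       body_height_cm = 60, body_length_cm = 75,
                       chest_width_cm = 24, chest_depth_cm = 30,
                       px_per_cm = 2, sign_cm = c(25, 20),
                       backdrop_color = c(40, 60, 200),
                       coat_color = c(150, 100, 60),
                       noise_sd = 5, brightness = 1, blur_sigma = 1,
                       leg_gap_cm = 6, shadow = FALSE,
                       shadow_strength = 0.45) {
  pose <- match.arg(pose)
  if (any(c(body_height_cm, body_length_cm, chest_width_cm, chest_depth_cm,
            px_per_cm, sign_cm) <= 0))
    stop("all physical dimensions must be > 0")
  if (backdrop_color[3] - backdrop_color[1] < 80)
    stop("backdrop must be strongly blue: B - R >= 80")
  if (coat_color[3] - coat_color[1] > 0)
    stop("coat must not be blue-dominant: B - R <= 0")
  if (body_height_cm <= chest_depth_cm)
    stop("body height must exceed chest depth (legs must exist)")
  structure(list(seed = as.integer(seed), pose = pose,
                 body_height_cm = body_height_cm,
                 body_length_cm = body_length_cm,
                 chest_width_cm = chest_width_cm,
                 chest_depth_cm = chest_depth_cm,
                 px_per_cm = px_per_cm, sign_cm = sign_cm,
                 backdrop_color = backdrop_color, coat_color = coat_color,
                 noise_sd = noise_sd, brightness = brightness,
                 blur_sigma = blur_sigma, leg_gap_cm = leg_gap_cm,
                 shadow = shadow, shadow_strength = shadow_strength),
            class = "scene_spec")
}

#' Draw a random but realistic scene specification
#'
#' Samples animal dimensions, coat/backdrop colour jitter, and brightness
#' from ranges typical of adult goats photographed under the field
#' protocol. Deterministic given `seed` (which also seeds the scene's
#' noise field).
#'
#' @param seed integer seed.
#' @param pose `"side"` or `"rear"`.
#' @param shadow passed through to [scene_spec()].
#' @param noise_sd,px_per_cm passed through to [scene_spec()].
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(seed, pose = c("side", "rear"),
                              shadow = FALSE, noise_sd = 5, px_per_cm = 2) {
  pose <- match.arg(pose)
  with_local_seed(seed, {
    h <- runif(1, 50, 70)
    len <- runif(1, 65, 90)
    cw <- runif(1, 20, 30)
    cd <- h * runif(1, 0.45, 0.55)
    bright <- runif(1, 0.8, 1.15)
    # coats stay at least one threshold-width on the red side of the
    # chroma margin (B - R <= -40), as the backdrop protocol assumes
    coat_r <- round(runif(1, 110, 190))
    coat_g <- round(runif(1, 70, 130))
    coat_b <- coat_r + round(runif(1, -110, -40))
    coat <- pmin(pmax(c(coat_r, coat_g, coat_b), 5), 250)
    backdrop <- c(40, 60, 200) + round(runif(3, -15, 15))
    backdrop <- pmin(pmax(backdrop, 0), 255)
    scene_spec(seed = seed, pose = pose, body_height_cm = h,
               body_length_cm = len, chest_width_cm = cw,
               chest_depth_cm = cd, px_per_cm = px_per_cm,
               backdrop_color = backdrop, coat_color = coat,
               noise_sd = noise_sd, brightness = bright, shadow = shadow)
  })
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a synthetic scene with exact ground truth
#'
#' Renders the silhouette (side pose: flat-backed torso, rectangular head
#' block, two legs; rear pose: upright elliptical torso over two legs with
#' a gap) in the coat colour over a blue backdrop, plus a white calibration
#' sign with a dark border, then applies optical blur, the brightness
#' factor, and clipped Gaussian noise. Ground-truth masks are captured
#' before blur and noise, so they are exact.
#'
#' @param spec a [scene_spec()].
#' @return A list with
#'   `image` (an [rgb_image()]),
#'   `truth` (list: `silhouette_mask`, `sign_mask` as `{0,1}` matrices,
#'   `dimensions_cm`, `scale` a [calibration_scale()], `sign_box`,
#'   `animal_bbox` = (row0, row1, col0, col1)), and `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("expected a 'scene_spec'")
  ppc <- spec$px_per_cm
  sw <- spec$sign_cm[1]; sh <- spec$sign_cm[2]
  sign_x0 <- 4; sign_y0 <- 4
  y_a0 <- sign_y0 + sh + 6                   # animal top (cm from frame top)

  if (spec$pose == "side") {
    head_len <- 14; head_h <- 12
    side_margin <- 12; bottom_margin <- 8
    x0 <- side_margin + head_len             # chest wall x (cm)
    len <- spec$body_length_cm
    frame_w <- max(x0 + len + side_margin, sign_x0 + sw + 8)
    frame_h <- y_a0 + spec$body_height_cm + bottom_margin
  } else {
    side_margin <- 16; bottom_margin <- 8
    frame_w <- max(spec$chest_width_cm + 2 * side_margin, sign_x0 + sw + 8)
    frame_h <- y_a0 + spec$body_height_cm + bottom_margin
  }

  H <- as.integer(round(frame_h * ppc))
  W <- as.integer(round(frame_w * ppc))
  yy <- matrix((seq_len(H) - 0.5) / ppc, H, W)
  xx <- matrix((seq_len(W) - 0.5) / ppc, H, W, byrow = TRUE)

  ground_y <- y_a0 + spec$body_height_cm
  leg_w <- 8
  sil <- matrix(FALSE, H, W)
  shadow_reg <- matrix(FALSE, H, W)

  if (spec$pose == "side") {
    depth <- spec$chest_depth_cm
    cx <- x0 + len / 2; cy <- y_a0 + depth / 2
    a <- len / 2; b <- depth / 2
    torso <- (abs((xx - cx) / a))^4 + (abs((yy - cy) / b))^4 <= 1
    head <- xx >= x0 - head_len & xx < x0 &
      yy >= y_a0 & yy < y_a0 + head_h
    leg_top <- y_a0 + depth * 0.8
    leg1 <- xx >= x0 + 6 & xx < x0 + 6 + leg_w &
      yy >= leg_top & yy < ground_y
    leg2 <- xx >= x0 + len - 6 - leg_w & xx < x0 + len - 6 &
      yy >= leg_top & yy < ground_y
    sil <- torso | head | leg1 | leg2
    if (spec$shadow) {
      scy <- (y_a0 + depth + ground_y) / 2
      sa <- len * 0.30; sb <- (spec$body_height_cm - depth) * 0.38
      shadow_reg <- ((xx - cx) / sa)^2 + ((yy - scy) / sb)^2 <= 1
    }
  } else {
    cw <- spec$chest_width_cm
    cx <- frame_w / 2
    # barrel reaches ~65% of the way to the ground; hind legs are narrower
    # than the fore legs and their outer span stays inside the torso width
    tb <- spec$body_height_cm * 0.65         # torso vertical diameter
    cy <- y_a0 + tb / 2
    torso <- ((xx - cx) / (cw / 2))^2 + ((yy - cy) / (tb / 2))^2 <= 1
    gap <- spec$leg_gap_cm
    rear_leg_w <- 6
    leg_top <- y_a0 + spec$body_height_cm * 0.55
    legL <- xx >= cx - gap / 2 - rear_leg_w & xx < cx - gap / 2 &
      yy >= leg_top & yy < ground_y
    legR <- xx >= cx + gap / 2 & xx < cx + gap / 2 + rear_leg_w &
      yy >= leg_top & yy < ground_y
    sil <- torso | legL | legR
    if (spec$shadow) {
      scy <- (y_a0 + tb + ground_y) / 2
      sa <- cw * 0.55; sb <- (ground_y - (y_a0 + tb)) * 0.38
      shadow_reg <- ((xx - cx) / sa)^2 + ((yy - scy) / sb)^2 <= 1
    }
  }
  shadow_reg <- shadow_reg & !sil

  sign_reg <- xx >= sign_x0 & xx < sign_x0 + sw &
    yy >= sign_y0 & yy < sign_y0 + sh
  border <- sign_reg &
    !(xx >= sign_x0 + 1 & xx < sign_x0 + sw - 1 &
        yy >= sign_y0 + 1 & yy < sign_y0 + sh - 1)
  if (any(sign_reg & sil)) stop("sign and silhouette overlap; enlarge frame")
  if (!any(sil)) stop("silhouette larger than frame or empty")

  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3) {
    ch <- matrix(spec$backdrop_color[k], H, W)
    ch[shadow_reg] <- spec$backdrop_color[k] * spec$shadow_strength
    ch[sil] <- spec$coat_color[k]
    ch[sign_reg] <- 235
    ch[border] <- 40
    img[, , k] <- ch
  }

  if (spec$blur_sigma > 0) {
    for (k in 1:3)
      img[, , k] <- EBImage::gblur(img[, , k], sigma = spec$blur_sigma)
  }
  img <- img * spec$brightness
  if (spec$noise_sd > 0) {
    img <- with_local_seed(spec$seed,
                           img + stats::rnorm(length(img), 0, spec$noise_sd))
  }
  img <- pmin(pmax(round(img), 0), 255)

  sil_i <- sil; mode(sil_i) <- "integer"
  sign_i <- sign_reg; mode(sign_i) <- "integer"
  rows <- range(which(rowSums(sil_i) > 0))
  cols <- range(which(colSums(sil_i) > 0))
  truth <- list(
    silhouette_mask = sil_i,
    sign_mask = sign_i,
    dimensions_cm = list(body_height = spec$body_height_cm,
                         body_length = spec$body_length_cm,
                         chest_width = spec$chest_width_cm,
                         chest_depth = spec$chest_depth_cm),
    scale = calibration_scale(ppc, ppc,
                              sign_px = spec$sign_cm * ppc,
                              sign_cm = spec$sign_cm),
    sign_box = c(x = sign_x0 * ppc, y = sign_y0 * ppc,
                 w = sw * ppc, h = sh * ppc),
    animal_bbox = c(row0 = rows[1], row1 = rows[2],
                    col0 = cols[1], col1 = cols[2])
  )
  list(image = rgb_image(img), truth = truth, spec = spec)
}

#' Bounding box around a scene's ground-truth silhouette
#'
#' Expands the silhouette's bounding box by `margin` pixels (clipped one
#' pixel inside the frame so sure background always exists outside it),
#' emulating the box a user would draw around the animal.
#'
#' @param scene output of [generate_scene()].
#' @param margin margin in pixels, default 5.
#' @return A [bounding_box()].
#' @export
scene_bounding_box <- function(scene, margin = 5) {
  bb <- scene$truth$animal_bbox
  H <- nrow(scene$truth$silhouette_mask)
  W <- ncol(scene$truth$silhouette_mask)
  r0 <- max(2, bb["row0"] - margin); r1 <- min(H - 1, bb["row1"] + margin)
  c0 <- max(2, bb["col0"] - margin); c1 <- min(W - 1, bb["col1"] + margin)
  bounding_box(x = c0, y = r0, w = c1 - c0 + 1, h = r1 - r0 + 1)
}

#' Round-trip an image through lossy JPEG encoding
#'
#' Reproduces compression artifacts for lossy-versus-lossless experiments:
#' the returned image is the result of encoding at the given quality and
#' decoding again, and is tagged as JPG-sourced.
#'
#' @param image an [rgb_image()].
#' @param quality JPEG quality in 1..100.
#' @return An [rgb_image()] with DCT compression artifacts.
#' @export
degrade_jpeg <- function(image, quality = 75) {
  stopifnot_rgb_image(image)
  if (quality < 1 || quality > 100) stop("quality must be in 1..100")
  tf <- tempfile(fileext = ".jpg")
  on.exit(unlink(tf))
  # libjpeg emits an informational "quantization tables too coarse" warning
  # at very low quality; coarse tables are exactly what is being emulated
  suppressWarnings(
    jpeg::writeJPEG(image$pixels / 255, target = tf, quality = quality / 100))
  a <- jpeg::readJPEG(tf)
  rgb_image(decode_array_to_pixels(a), source_format = "jpg",
            scale_applied = image$scale_applied)
}
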
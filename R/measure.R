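#' Pixel-to-centimetre calibration factors
#'
#' Derived from the rectangular calibration sign of known physical size
#' included in every photograph. The protocol assumes the sign is held
#' fronto-parallel to the camera, so the horizontal and vertical factors
#' should agree; an anisotropy above 5% of their mean triggers a warning.
#'
#' @param px_per_cm_x,px_per_cm_y pixels per centimetre along image columns
#'   and rows, both > 0.
#' @param sign_px measured (width, height) of the sign in pixels.
#' @param sign_cm physical (width, height) of the sign in centimetres.
#' @return A list of class `calibration_scale`.
#' @export
calibration_scale <- function(px_per_cm_x, px_per_cm_y,
                              sign_px = c(NA, NA), sign_cm = c(NA, NA)) {
  if (px_per_cm_x <= 0 || px_per_cm_y <= 0)
    stop("scale factors must be > 0")
  aniso <- abs(px_per_cm_x - px_per_cm_y) /
    mean(c(px_per_cm_x, px_per_cm_y))
  if (aniso > 0.05)
    warning(sprintf(
      "calibration anisotropy %.1f%% exceeds 5%%: sign may not be fronto-parallel",
      100 * aniso))
  structure(list(px_per_cm_x = px_per_cm_x, px_per_cm_y = px_per_cm_y,
                 sign_px = sign_px, sign_cm = sign_cm),
            class = "calibration_scale")
}

#' Morphological mask refinement
#'
#' Fully automated post-segmentation cleanup: morphological opening then
#' closing with an elliptical (disc) structuring element, then retention of
#' the largest connected foreground component only. Opening removes
#' sub-kernel speckles; closing fills comparable holes; the
#' largest-component rule drops any detached debris.
#'
#' @param mask `{0,1}` matrix.
#' @param kernel_size diameter of the disc kernel in pixels (default 5;
#'   even values are rounded up to the next odd size).
#' @return A refined `{0,1}` integer matrix.
#' @export
refine_mask <- function(mask, kernel_size = 5) {
  if (!any(mask > 0)) stop("no foreground in mask")
  ks <- as.integer(kernel_size)
  if (ks %% 2L == 0L) ks <- ks + 1L
  m <- (mask > 0) * 1
  if (ks >= 3L) {
    brush <- EBImage::makeBrush(ks, "disc")
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
  }
  if (!any(m > 0)) stop("no foreground left after morphology")
  lab <- EBImage::bwlabel(m)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- (lab == keep) * 1L
  mode(out) <- "integer"
  out
}

# Minimum-area enclosing rectangle of a point set (rotating calipers over
# the convex hull). Returns extents along the two rectangle axes and the
# angle of the first axis to the image x-axis.
min_area_rect <- function(pts) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1 else i + 1, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    ex <- max(pu) - min(pu); ey <- max(pv) - min(pv)
    if (is.null(best) || ex * ey < best$area)
      best <- list(area = ex * ey, ext = c(ex, ey),
                   angle = atan2(u[2], u[1]))
  }
  best
}

#' Extract calibration factors from a sign mask
#'
#' Fits the minimum-area rectangle to the sign's largest connected
#' component (over the pixel footprint, i.e. pixel corners, so an n-pixel
#' wide sign measures n px) and divides the pixel sides by the known
#' physical sides. The rectangle side closest to the image horizontal is
#' taken as the width.
#'
#' @param sign_mask `{0,1}` matrix containing the segmented sign.
#' @param sign_cm physical (width, height) of the sign in centimetres.
#' @return A [calibration_scale()].
#' @export
extract_calibration <- function(sign_mask, sign_cm) {
  if (length(sign_cm) != 2 || any(sign_cm <= 0))
    stop("sign_cm must be two positive lengths (width, height)")
  if (!any(sign_mask > 0)) stop("empty sign mask")
  lab <- EBImage::bwlabel((sign_mask > 0) * 1)
  tab <- tabulate(lab[lab > 0])
  comp <- which(lab == which.max(tab), arr.ind = TRUE)
  # pixel footprint corners: (col +/- 0.5, row +/- 0.5)
  x <- comp[, 2]; y <- comp[, 1]
  pts <- cbind(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
               c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
  rect <- min_area_rect(pts)
  ext <- rect$ext
  if (min(ext) < 2) stop("degenerate calibration sign (thinner than 2 px)")
  ang <- rect$angle %% pi
  horizontal_first <- ang <= pi / 4 || ang >= 3 * pi / 4
  w_px <- if (horizontal_first) ext[1] else ext[2]
  h_px <- if (horizontal_first) ext[2] else ext[1]
  calibration_scale(w_px / sign_cm[1], h_px / sign_cm[2],
                    sign_px = c(w_px, h_px), sign_cm = sign_cm)
}

mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0) stop("empty mask")
  c(r0 = rows[1], r1 = rows[length(rows)],
    c0 = cols[1], c1 = cols[length(cols)])
}

# Length of the top-connected vertical foreground run in one column.
top_run_length <- function(col_vals) {
  fg <- which(col_vals > 0)
  if (length(fg) == 0) return(0L)
  runs <- cumsum(c(1L, diff(fg) != 1L))
  sum(runs == 1L)
}

#' Body measurements from a refined side-pose mask
#'
#' Landmark conventions (all band fractions configurable):
#' * body height: vertical extent of the silhouette within the wither
#'   band, the column band `wither_band` (default 20-40%) of the mask
#'   width measured from the chest (head) end -- topmost wither pixel down
#'   to the hoof/ground;
#' * body length: horizontal extent between the foremost chest-wall pixel
#'   and the rearmost pin-bone pixel within the torso row band
#'   `torso_band` (default 30-70% of mask height);
#' * chest depth: vertical torso thickness just behind the forelegs (the
#'   heart-girth site), taken as the median top-connected run length over
#'   the rearmost quarter of the wither band's columns.
#'
#' The head end is detected as the lighter (smaller foreground area) of
#' the left and right thirds of the mask's bounding box, overridable via
#' `head_side`.
#'
#' @param mask refined `{0,1}` side-pose mask.
#' @param scale a [calibration_scale()].
#' @param wither_band,torso_band band fractions, see above.
#' @param head_side `"auto"`, `"left"`, or `"right"`.
#' @return A list of class `body_measurements` with `height_px/cm`,
#'   `length_px/cm`, `chest_depth_px/cm`, and `pose = "side"`.
#' @export
measure_side <- function(mask, scale, wither_band = c(0.2, 0.4),
                         torso_band = c(0.3, 0.7),
                         head_side = c("auto", "left", "right")) {
  head_side <- match.arg(head_side)
  if (!any(mask > 0)) stop("empty mask")
  bb <- mask_bbox(mask)
  if (bb["r0"] == 1 || bb["c0"] == 1 || bb["r1"] == nrow(mask) ||
      bb["c1"] == ncol(mask))
    warning("mask touches the image border: subject may be truncated")
  mw <- bb["c1"] - bb["c0"] + 1
  mh <- bb["r1"] - bb["r0"] + 1
  sub <- mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]

  if (head_side == "auto") {
    third <- max(1L, floor(mw / 3))
    left_mass <- sum(sub[, seq_len(third)])
    right_mass <- sum(sub[, (ncol(sub) - third + 1):ncol(sub)])
    head_side <- if (left_mass <= right_mass) "left" else "right"
  }
  frac <- (seq_len(mw) - 0.5) / mw
  if (head_side == "right") frac <- rev(frac)
  band_cols <- which(frac >= wither_band[1] & frac < wither_band[2])
  if (length(band_cols) == 0) stop("wither band contains no columns")

  band <- sub[, band_cols, drop = FALSE]
  rows_any <- which(rowSums(band) > 0)
  if (length(rows_any) == 0) stop("no foreground in the wither band")
  height_px <- rows_any[length(rows_any)] - rows_any[1] + 1

  rfrac <- (seq_len(mh) - 0.5) / mh
  trows <- which(rfrac >= torso_band[1] & rfrac < torso_band[2])
  torso <- sub[trows, , drop = FALSE]
  cols_any <- which(colSums(torso) > 0)
  if (length(cols_any) == 0) stop("no foreground in the torso band")
  length_px <- cols_any[length(cols_any)] - cols_any[1] + 1

  # heart-girth site: the rearmost quarter of the wither band (the band is
  # anchored at the chest end, so its rear edge sits just behind the
  # forelegs, where the torso carries its full depth)
  k <- max(1L, ceiling(length(band_cols) / 4))
  girth_cols <- if (head_side == "left") utils::tail(band_cols, k)
                else utils::head(band_cols, k)
  runs <- apply(sub[, girth_cols, drop = FALSE], 2, top_run_length)
  runs <- runs[runs > 0]
  if (length(runs) == 0) stop("no foreground at the heart-girth site")
  chest_depth_px <- as.numeric(stats::median(runs))

  structure(list(
    pose = "side", head_side = head_side,
    height_px = as.numeric(height_px),
    length_px = as.numeric(length_px),
    chest_depth_px = chest_depth_px,
    height_cm = height_px / scale$px_per_cm_y,
    length_cm = length_px / scale$px_per_cm_x,
    chest_depth_cm = chest_depth_px / scale$px_per_cm_y
  ), class = "body_measurements")
}

#' Chest width from a refined rear-pose mask
#'
#' The chest width is the maximum horizontal contiguous foreground run
#' within the torso row band (default 30-70% of the mask height), which
#' spans the widest part of the torso while excluding the legs.
#'
#' @param mask refined `{0,1}` rear-pose mask.
#' @param scale a [calibration_scale()].
#' @param torso_band row band fractions of the mask height.
#' @return A list of class `body_measurements` with `chest_width_px/cm`
#'   and `pose = "rear"`.
#' @export
measure_rear <- function(mask, scale, torso_band = c(0.3, 0.7)) {
  if (!any(mask > 0)) stop("empty mask")
  bb <- mask_bbox(mask)
  mh <- bb["r1"] - bb["r0"] + 1
  sub <- mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  rfrac <- (seq_len(mh) - 0.5) / mh
  trows <- which(rfrac >= torso_band[1] & rfrac < torso_band[2])
  longest_run <- function(v) {
    fg <- which(v > 0)
    if (length(fg) == 0) return(0L)
    runs <- rle(diff(fg) == 1L)
    1L + max(0L, max(c(0L, runs$lengths[runs$values])))
  }
  width_px <- max(apply(sub[trows, , drop = FALSE], 1, longest_run))
  if (width_px == 0) stop("no foreground in the torso band")
  structure(list(
    pose = "rear",
    chest_width_px = as.numeric(width_px),
    chest_width_cm = width_px / scale$px_per_cm_x
  ), class = "body_measurements")
}

#' Chest girth from side depth and rear width
#'
#' Models the torso cross-section just behind the forelegs as an ellipse
#' with vertical axis the side-pose chest depth and horizontal axis the
#' rear-pose chest width, and returns its perimeter via the Ramanujan
#' approximation `P = pi * (3(a+b) - sqrt((3a+b)(a+3b)))` with semi-axes
#' `a = depth/2`, `b = width/2` (accurate to well under 0.5% for axis
#' ratios up to 3). This is a modelling choice: the cross-section of a
#' real animal is only approximately elliptical.
#'
#' @param chest_depth_cm,chest_width_cm ellipse axes in centimetres,
#'   both > 0.
#' @return Girth in centimetres.
#' @export
estimate_girth <- function(chest_depth_cm, chest_width_cm) {
  if (chest_depth_cm <= 0 || chest_width_cm <= 0)
    stop("chest depth and width must be > 0")
  a <- chest_depth_cm / 2
  b <- chest_width_cm / 2
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Combine side and rear measurements into one record
#'
#' @param side output of [measure_side()].
#' @param rear output of [measure_rear()], or `NULL` if the rear pose is
#'   missing (girth is then omitted with a warning).
#' @return A list of class `body_measurements` covering height, length,
#'   chest depth/width, and girth, with pose provenance.
#' @export
combine_measurements <- function(side, rear = NULL) {
  out <- list(height_px = side$height_px, height_cm = side$height_cm,
              length_px = side$length_px, length_cm = side$length_cm,
              chest_depth_px = side$chest_depth_px,
              chest_depth_cm = side$chest_depth_cm,
              chest_width_px = NA_real_, chest_width_cm = NA_real_,
              girth_cm = NA_real_,
              pose_sources = "side")
  if (is.null(rear)) {
    warning("rear pose missing: girth omitted")
  } else {
    out$chest_width_px <- rear$chest_width_px
    out$chest_width_cm <- rear$chest_width_cm
    out$girth_cm <- estimate_girth(side$chest_depth_cm, rear$chest_width_cm)
    out$pose_sources <- c("side", "rear")
  }
  structure(out, class = "body_measurements")
}
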
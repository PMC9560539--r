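#' Intersection-over-union of two binary masks
#'
#' With `boundary_tolerance > 0`, pixels within that radius of the
#' reference mask's boundary are excluded from both the intersection and
#' the union (a "don't care" band): synthetic ground truth is exact to the
#' pixel, but noise and optical blur make the true edge ambiguous within
#' about one pixel, so edge pixels are not scored.
#'
#' @param mask `{0,1}` matrix under evaluation.
#' @param reference `{0,1}` ground-truth matrix of the same shape.
#' @param boundary_tolerance radius (pixels) of the excluded band around
#'   the reference boundary; 0 scores every pixel.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(mask, reference, boundary_tolerance = 0) {
  if (!identical(dim(mask), dim(reference))) stop("mask shapes differ")
  a <- mask > 0; b <- reference > 0
  keep <- TRUE
  if (boundary_tolerance > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(boundary_tolerance) + 1L,
                                "disc")
    band <- (EBImage::dilate(reference, brush) > 0) &
      !(EBImage::erode(reference, brush) > 0)
    keep <- !band
  }
  inter <- sum(a & b & keep)
  uni <- sum((a | b) & keep)
  if (uni == 0) return(1)
  inter / uni
}

erode_by <- function(mask, r) {
  if (r <= 0) return(mask > 0)
  EBImage::erode(mask, EBImage::makeBrush(2L * as.integer(r) + 1L,
                                          "disc")) > 0
}

# Ordered boundary traces of each connected component of a logical mask,
# chopped into polyline paths of at most max_len pixels.
component_contour_paths <- function(region, max_len) {
  if (!any(region)) return(list())
  lab <- EBImage::bwlabel(region * 1L)
  ctr <- EBImage::ocontour(lab)
  paths <- list()
  for (cc in ctr) {
    if (is.null(cc) || nrow(cc) == 0) next
    # ocontour coordinates are 0-based (dim1, dim2) = (row, col)
    xy <- cbind(x = cc[, 2] + 1L, y = cc[, 1] + 1L)
    starts <- seq(1, nrow(xy), by = max_len)
    for (s in starts) {
      seg <- xy[s:min(s + max_len - 1, nrow(xy)), , drop = FALSE]
      paths[[length(paths) + 1L]] <- seg
    }
  }
  paths
}

#' Scripted annotator emulating a human refiner
#'
#' Compares the current segmentation with ground truth and, like the human
#' workflow, draws sure-foreground strokes just inside the true region of
#' interest along edges currently misclassified as background, and
#' sure-background strokes just outside it along false-positive regions.
#' Strokes follow component boundaries, are inset/offset `inset` pixels
#' from the true edge (so a stroke never asserts a label the ground truth
#' contradicts), and are capped at `max_stroke_len` pixels per event. If
#' no safely-placeable stroke exists at the configured inset, the inset is
#' relaxed towards 0 before giving up.
#'
#' Returns an empty list once the tolerant IoU reaches `stop_iou` (or when
#' only unscoreable boundary-band pixels disagree).
#'
#' @param current_mask `{0,1}` segmentation under refinement.
#' @param truth_mask `{0,1}` ground truth of the same shape.
#' @param box the [bounding_box()] of the run (foreground strokes are kept
#'   inside it).
#' @param stop_iou stop criterion on [mask_iou()] with a 1-px tolerance
#'   band (default 0.98).
#' @param max_stroke_len maximum rasterized pixels per stroke event
#'   (default 30).
#' @param inset stroke inset/offset from the true edge in pixels
#'   (default 2).
#' @param boundary_tolerance tolerance band radius used in the stop
#'   criterion (default 1).
#' @return A list of [stroke_event()]s, empty when converged.
#' @export
robot_annotate <- function(current_mask, truth_mask, box, stop_iou = 0.98,
                           max_stroke_len = 30, inset = 2,
                           boundary_tolerance = 1) {
  if (!identical(dim(current_mask), dim(truth_mask)))
    stop("mask shapes differ")
  if (mask_iou(current_mask, truth_mask, boundary_tolerance) >= stop_iou)
    return(list())
  cur <- current_mask > 0; tru <- truth_mask > 0
  H <- nrow(tru); W <- ncol(tru)

  clip_to_box <- function(paths) {
    lapply(paths, function(p) {
      keep <- p[, "x"] >= box$x & p[, "x"] <= box$x + box$w - 1L &
        p[, "y"] >= box$y & p[, "y"] <= box$y + box$h - 1L
      p[keep, , drop = FALSE]
    })
  }
  events <- list()
  # false negatives: truth pixels labelled background, kept >= inset inside
  # the true edge
  for (r in seq(inset, 0)) {
    fn <- tru & !cur & erode_by(tru, r)
    paths <- clip_to_box(component_contour_paths(fn, max_stroke_len))
    paths <- paths[vapply(paths, nrow, integer(1)) > 0]
    if (length(paths)) {
      events <- c(events, lapply(paths, function(p)
        stroke_event("sure_foreground", p)))
      break
    }
  }
  # false positives: background pixels labelled foreground, kept >= inset
  # outside the true edge
  for (r in seq(inset, 0)) {
    fp <- cur & !tru & erode_by(!tru, r)
    paths <- component_contour_paths(fp, max_stroke_len)
    paths <- paths[vapply(paths, nrow, integer(1)) > 0]
    if (length(paths)) {
      events <- c(events, lapply(paths, function(p)
        stroke_event("sure_background", p)))
      break
    }
  }
  events
}

#' Segment one image to convergence with the scripted annotator
#'
#' Runs the box-initialised graph cut, then alternates scripted refinement
#' strokes and re-segmentation until the tolerant IoU against ground truth
#' reaches `stop_iou`, the annotator has nothing safe left to draw, or
#' `max_rounds` refinement rounds have run. This is the instrumented
#' replay of the interactive workflow used to compare annotation effort
#' between the two-step pipeline and the box-only baseline.
#'
#' @param image an [rgb_image()] (already colour-suppressed for the
#'   two-step pipeline).
#' @param truth_mask ground-truth `{0,1}` silhouette mask.
#' @param box a [bounding_box()] around the region of interest.
#' @param iterations graph-cut iterations per refinement round.
#' @param max_rounds maximum refinement rounds (default 10).
#' @param stop_iou,max_stroke_len,inset,boundary_tolerance passed to
#'   [robot_annotate()].
#' @param gamma,k_components passed to [run_grabcut()].
#' @return A list: `mask`, `annotations` (the accumulated
#'   [annotation_set()]), `strokes` (total stroke count), `rounds`
#'   (refinement rounds used, 0 = box only), `iou` (final tolerant IoU),
#'   `iou_history`.
#' @export
segment_with_robot <- function(image, truth_mask, box, iterations = 5,
                               max_rounds = 10, stop_iou = 0.98,
                               max_stroke_len = 30, inset = 2,
                               boundary_tolerance = 1, gamma = 50,
                               k_components = 5) {
  ann <- annotation_set(box)
  mask <- run_grabcut(image, ann, iterations = iterations, gamma = gamma,
                      k_components = k_components)
  iou <- mask_iou(mask, truth_mask, boundary_tolerance)
  history <- iou
  rounds <- 0L
  while (rounds < max_rounds) {
    ev <- robot_annotate(mask, truth_mask, box, stop_iou = stop_iou,
                         max_stroke_len = max_stroke_len, inset = inset,
                         boundary_tolerance = boundary_tolerance)
    if (length(ev) == 0) break
    ann <- annotation_set(box, c(ann$events, ev))
    mask <- run_grabcut(image, ann, iterations = iterations, gamma = gamma,
                        k_components = k_components, init_mask = mask)
    iou <- mask_iou(mask, truth_mask, boundary_tolerance)
    history <- c(history, iou)
    rounds <- rounds + 1L
  }
  list(mask = mask, annotations = ann, strokes = count_strokes(ann),
       rounds = rounds, iou = iou, iou_history = history)
}
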
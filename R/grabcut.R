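#' Bounding box (1-based, inclusive)
#'
#' Covers columns `x .. x+w-1` and rows `y .. y+h-1` in the package's
#' row/column convention (row 1 is the top of the image).
#'
#' @param x column of the left edge (1-based).
#' @param y row of the top edge (1-based).
#' @param w,h width and height in pixels, both >= 1.
#' @return A list of class `bounding_box`.
#' @export
bounding_box <- function(x, y, w, h) {
  x <- as.integer(x); y <- as.integer(y)
  w <- as.integer(w); h <- as.integer(h)
  if (w < 1 || h < 1) stop("box must have w >= 1 and h >= 1")
  if (x < 1 || y < 1) stop("box must lie inside the image")
  structure(list(x = x, y = y, w = w, h = h), class = "bounding_box")
}

#' A sure-foreground or sure-background refinement stroke
#'
#' One drawing action: a polyline of pixel coordinates labelled either
#' sure foreground or sure background. Only these two hard labels exist;
#' there are no "probable" annotations.
#'
#' @param label `"sure_foreground"` or `"sure_background"`.
#' @param path an `n x 2` matrix of polyline vertices with columns
#'   `(x, y)` = (column, row), 1-based. A single row is a point stroke.
#' @return A list of class `stroke_event`.
#' @export
stroke_event <- function(label = c("sure_foreground", "sure_background"),
                         path) {
  label <- match.arg(label)
  path <- matrix(as.integer(path), ncol = 2,
                 dimnames = list(NULL, c("x", "y")))
  if (nrow(path) < 1) stop("stroke path must be non-empty")
  structure(list(label = label, path = path), class = "stroke_event")
}

#' Bounding box plus ordered refinement strokes
#'
#' @param box a [bounding_box()].
#' @param events list of [stroke_event()]s, possibly empty (a
#'   bounding-box-only run). Order matters: where strokes overlap, the
#'   later event's label wins.
#' @return A list of class `annotation_set`.
#' @export
annotation_set <- function(box, events = list()) {
  if (!inherits(box, "bounding_box")) stop("expected a 'bounding_box'")
  if (!all(vapply(events, inherits, logical(1), "stroke_event")))
    stop("events must be stroke_event objects")
  structure(list(box = box, events = events), class = "annotation_set")
}

# Bresenham line between two pixels, endpoints included. Returns an n x 2
# (x, y) integer matrix.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  n <- max(dx, dy) + 1L
  out <- matrix(0L, n, 2)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  out
}

# Rasterize one stroke event at thickness 1; duplicate pixels within the
# event are deduplicated.
rasterize_stroke <- function(event) {
  p <- event$path
  if (nrow(p) == 1) return(p)
  segs <- lapply(seq_len(nrow(p) - 1), function(i)
    bresenham(p[i, 1], p[i, 2], p[i + 1, 1], p[i + 1, 2]))
  pts <- do.call(rbind, segs)
  unique(pts)
}

#' Count annotation effort in strokes
#'
#' One rasterized pixel = one stroke, the unit of user input. Pixels are
#' deduplicated within a single drawing action, but the same pixel marked in
#' separate events counts each time (each drawing action adds its own
#' coordinates). Bounding-box pixels are not counted.
#'
#' @param annotations an [annotation_set()].
#' @return Integer total stroke count.
#' @export
count_strokes <- function(annotations) {
  if (!inherits(annotations, "annotation_set"))
    stop("expected an 'annotation_set'")
  if (length(annotations$events) == 0) return(0L)
  sum(vapply(annotations$events,
             function(e) nrow(rasterize_stroke(e)), integer(1)))
}

#' Serialise annotations to JSON
#'
#' @param annotations an [annotation_set()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  obj <- list(
    box = unclass(annotations$box),
    events = lapply(annotations$events, function(e)
      list(label = e$label, path = unname(e$path)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotations from JSON
#'
#' @param path file written by [write_annotations()].
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  box <- bounding_box(obj$box$x, obj$box$y, obj$box$w, obj$box$h)
  events <- list()
  if (length(obj$events)) {
    events <- lapply(seq_len(nrow_events(obj$events)), function(i) {
      e <- if (is.data.frame(obj$events)) obj$events[i, ] else obj$events[[i]]
      stroke_event(e$label[[1]], matrix(unlist(e$path), ncol = 2))
    })
  }
  annotation_set(box, events)
}

nrow_events <- function(ev) if (is.data.frame(ev)) nrow(ev) else length(ev)

# --- GrabCut core -----------------------------------------------------------

# Fit a k-component Gaussian mixture to colours X (n x 3) via k-means
# hard assignment. A variance floor keeps components from degenerating on
# exactly-uniform regions (e.g. the all-black suppressed backdrop).
fit_colour_gmm <- function(X, k = 5, var_floor = 1) {
  X <- as.matrix(X)
  ux <- unique(X)
  k <- max(1L, min(k, nrow(ux)))
  if (k == 1L) {
    cl <- rep(1L, nrow(X))
  } else {
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(X, centers = ux[sample.int(nrow(ux), k), , drop = FALSE],
                      iter.max = 30, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) { cl <- rep(1L, nrow(X)); k <- 1L } else cl <- km$cluster
  }
  comps <- lapply(seq_len(k), function(i) {
    Xi <- X[cl == i, , drop = FALSE]
    if (nrow(Xi) == 0) return(NULL)
    mu <- colMeans(Xi)
    S <- if (nrow(Xi) > 1) stats::cov(Xi) else matrix(0, 3, 3)
    S <- S + diag(var_floor, 3)
    R <- chol(S)
    list(pi = nrow(Xi) / nrow(X), mu = mu, chol = R,
         logdet = 2 * sum(log(diag(R))))
  })
  comps[!vapply(comps, is.null, logical(1))]
}

# Negative log-likelihood of colours under the mixture, using the best
# (hard-assigned) component per pixel, capped for use as a graph capacity.
gmm_neg_loglik <- function(gmm, X, cap = 5000) {
  X <- as.matrix(X)
  best <- rep(Inf, nrow(X))
  for (g in gmm) {
    Z <- forwardsolve(t(g$chol), t(X) - g$mu)
    d <- -log(g$pi) + 0.5 * g$logdet + 0.5 * colSums(Z^2) +
      1.5 * log(2 * pi)
    best <- pmin(best, d)
  }
  pmin(best, cap)
}

#' Graph-cut foreground extraction with hard stroke constraints
#'
#' Box-initialised iterative graph-cut segmentation in the reduced
#' annotation model: the user supplies only a bounding box and (optionally)
#' sure-foreground / sure-background strokes -- no "probable" labels.
#' Everything outside the box is sure background. Colour likelihoods are
#' modelled by per-class Gaussian mixtures refit each iteration from the
#' current labelling; the binary labelling is solved exactly per iteration
#' by a minimum s-t cut (compiled Dinic solver on the pixel grid) over the
#' box region with contrast-weighted 4-neighbour smoothness terms.
#'
#' Hard constraints always hold in the output: pixels under a
#' sure-background stroke are 0, pixels under a sure-foreground stroke
#' are 1, and all pixels outside the box are 0.
#'
#' @param image an [rgb_image()] (for the two-step pipeline, the output of
#'   [chroma_step()]; for the box-only baseline, the original image).
#' @param annotations an [annotation_set()]. The box must not cover the
#'   whole image (some sure background must exist outside it) and
#'   sure-foreground strokes must lie inside the box.
#' @param iterations maximum mixture-refit/min-cut rounds (default 5);
#'   stops early when the labelling is stable.
#' @param gamma smoothness weight of the contrast-sensitive neighbour
#'   terms (default 50).
#' @param k_components Gaussian mixture components per class (default 5).
#' @param bg_sample_max pixels subsampled per class for the mixture fits
#'   (deterministic; default 15000).
#' @param init_mask optional `{0,1}` mask used as the initial labelling
#'   inside the box (e.g. the previous refinement round's output); by
#'   default the whole box starts as foreground.
#' @return A `{0,1}` integer segmentation mask (1 = foreground).
#' @export
run_grabcut <- function(image, annotations, iterations = 5, gamma = 50,
                        k_components = 5, bg_sample_max = 15000,
                        init_mask = NULL) {
  stopifnot_rgb_image(image)
  if (!inherits(annotations, "annotation_set"))
    stop("expected an 'annotation_set'")
  if (iterations < 1) stop("iterations must be >= 1")
  H <- image$height; W <- image$width
  box <- annotations$box
  r0 <- box$y; r1 <- box$y + box$h - 1L
  c0 <- box$x; c1 <- box$x + box$w - 1L
  if (r1 > H || c1 > W) stop("box must lie inside the image")
  if (r0 == 1L && c0 == 1L && r1 == H && c1 == W)
    stop("box covers the whole image: no sure background exists")

  # fixed labels from strokes (0 none, 1 fg, 2 bg); later events override
  fixed <- matrix(0L, H, W)
  for (e in annotations$events) {
    px <- rasterize_stroke(e)
    if (any(px[, 1] < 1 | px[, 1] > W | px[, 2] < 1 | px[, 2] > H))
      stop("stroke outside the image")
    lab <- if (e$label == "sure_foreground") 1L else 2L
    if (lab == 1L &&
        any(px[, 1] < c0 | px[, 1] > c1 | px[, 2] < r0 | px[, 2] > r1))
      stop("sure-foreground stroke outside the bounding box")
    fixed[cbind(px[, 2], px[, 1])] <- lab
  }

  nb <- r1 - r0 + 1L; mb <- c1 - c0 + 1L
  n_box <- nb * mb
  idx <- matrix(seq_len(n_box), nb, mb)
  chans <- lapply(1:3, function(k) image$pixels[, , k])
  Xbox <- cbind(as.vector(chans[[1]][r0:r1, c0:c1]),
                as.vector(chans[[2]][r0:r1, c0:c1]),
                as.vector(chans[[3]][r0:r1, c0:c1]))

  # contrast-weighted 4-neighbour links inside the box
  pr <- cbind(as.vector(idx[, -mb]), as.vector(idx[, -1]))   # right
  pd <- cbind(as.vector(idx[-nb, ]), as.vector(idx[-1, ]))   # down
  d2r <- rowSums((Xbox[pr[, 1], , drop = FALSE] -
                    Xbox[pr[, 2], , drop = FALSE])^2)
  d2d <- rowSums((Xbox[pd[, 1], , drop = FALSE] -
                    Xbox[pd[, 2], , drop = FALSE])^2)
  md2 <- mean(c(d2r, d2d))
  beta <- if (md2 > 0) 1 / (2 * md2) else 0
  wr <- gamma * exp(-beta * d2r)
  wd <- gamma * exp(-beta * d2d)

  # n-links from box-border pixels to the (sure-background) outside are
  # folded into their sink capacity
  extra_bg <- numeric(n_box)
  fold <- function(cells_in, cells_out) {
    d2 <- rowSums((Xbox[cells_in, , drop = FALSE] - cells_out)^2)
    extra_bg[cells_in] <<- extra_bg[cells_in] + gamma * exp(-beta * d2)
  }
  out_col <- function(rows, col)
    cbind(chans[[1]][rows, col], chans[[2]][rows, col], chans[[3]][rows, col])
  if (r0 > 1L) fold(idx[1, ], out_col(r0 - 1L, c0:c1))
  if (r1 < H) fold(idx[nb, ], out_col(r1 + 1L, c0:c1))
  if (c0 > 1L) fold(idx[, 1], out_col(r0:r1, c0 - 1L))
  if (c1 < W) fold(idx[, mb], out_col(r0:r1, c1 + 1L))

  # Capacities are quantized to a 1/8-intensity integer grid for the
  # integer-capacity min-cut solver; the quantization error is negligible
  # against gamma-scale weights.
  quant <- 8
  wr_q <- round(wr * quant)
  wd_q <- round(wd * quant)
  BIG <- 1e6 * quant

  fixed_box <- as.vector(fixed[r0:r1, c0:c1])
  in_box <- matrix(FALSE, H, W); in_box[r0:r1, c0:c1] <- TRUE
  if (is.null(init_mask)) {
    alpha <- in_box & fixed != 2L        # init: box = fg minus bg strokes
  } else {
    if (!identical(dim(init_mask), c(H, W)))
      stop("init_mask shape does not match image")
    alpha <- init_mask > 0 & in_box & fixed != 2L
    if (!any(alpha)) alpha <- in_box & fixed != 2L
  }
  alpha[fixed == 1L] <- TRUE

  all_cols <- cbind(as.vector(chans[[1]]), as.vector(chans[[2]]),
                    as.vector(chans[[3]]))

  with_local_seed(20260920L, {
    for (it in seq_len(iterations)) {
      fg_idx <- which(alpha)
      if (length(fg_idx) > bg_sample_max)
        fg_idx <- fg_idx[sort(sample.int(length(fg_idx), bg_sample_max))]
      bg_idx <- which(!alpha)
      if (length(bg_idx) > bg_sample_max)
        bg_idx <- bg_idx[sort(sample.int(length(bg_idx), bg_sample_max))]
      # always include in-box sure-background pixels in the fit
      bg_fixed <- which(!alpha & fixed == 2L)
      bg_idx <- union(bg_idx, bg_fixed)
      gmm_fg <- fit_colour_gmm(all_cols[fg_idx, , drop = FALSE], k_components)
      gmm_bg <- fit_colour_gmm(all_cols[bg_idx, , drop = FALSE], k_components)
      D_fg <- gmm_neg_loglik(gmm_fg, Xbox)
      D_bg <- gmm_neg_loglik(gmm_bg, Xbox)

      src_cap <- round(D_bg * quant)       # paid when the pixel is cut to bg
      sink_cap <- round((D_fg + extra_bg) * quant)  # paid when cut to fg
      src_cap[fixed_box == 1L] <- BIG
      sink_cap[fixed_box == 1L] <- 0
      src_cap[fixed_box == 2L] <- 0
      sink_cap[fixed_box == 2L] <- BIG

      cut <- .grid_mincut(nb, mb, wr_q, wd_q, src_cap, sink_cap)
      alpha_box <- cut$foreground
      alpha_box[fixed_box == 1L] <- TRUE
      alpha_box[fixed_box == 2L] <- FALSE
      new_alpha <- matrix(FALSE, H, W)
      new_alpha[r0:r1, c0:c1] <- alpha_box
      changed <- sum(new_alpha != alpha)
      alpha <- new_alpha
      # stable labelling: further mixture refits cannot move much
      if (changed <= max(2, 1e-3 * n_box)) break
    }
  })

  mask <- alpha; mode(mask) <- "integer"
  mask
}
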
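#' RGB raster image container
#'
#' Wraps an `H x W x 3` array of 8-bit intensities in the row/column
#' convention used throughout this package: the first index `i` runs down
#' rows from the top of the image (vertical), the second index `j` runs
#' across columns from the left (horizontal), and the third index is the
#' channel in (R, G, B) order.
#'
#' @param pixels numeric or integer `H x W x 3` array with values in
#'   `[0, 255]`.
#' @param source_format `"png"` or `"jpg"`; which container the pixels were
#'   decoded from (informational; all downstream stages consume only the
#'   in-memory array).
#' @param scale_applied scale factor already applied to the pixel grid by
#'   [resize_to_fit()], kept so that coordinates measured on the working
#'   image can be mapped back to the original capture.
#'
#' @return An object of class `rgb_image`: a list with elements `pixels`
#'   (integer array), `height`, `width`, `source_format`, `scale_applied`.
#' @export
rgb_image <- function(pixels, source_format = c("png", "jpg"),
                      scale_applied = 1) {
  source_format <- match.arg(source_format)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L)
    stop("image must be at least 1 x 1")
  px <- as.integer(round(pixels))
  if (anyNA(px) || any(px < 0L) || any(px > 255L))
    stop("intensities must lie in [0, 255]")
  dim(px) <- d
  structure(
    list(pixels = px, height = d[1], width = d[2],
         source_format = source_format, scale_applied = scale_applied),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image> %d x %d px, source %s, scale %.4g\n",
              x$height, x$width, x$source_format, x$scale_applied))
  invisible(x)
}

#' Test for the rgb_image class
#' @param x object to test
#' @return `TRUE` if `x` is an [rgb_image()].
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

stopifnot_rgb_image <- function(x) {
  if (!is_rgb_image(x)) stop("expected an 'rgb_image' object")
  invisible(x)
}

# png/jpeg readers return H x W x 3 doubles in [0,1]; PNG values are exact
# multiples of 1/255, so round(x * 255) reproduces the stored bytes.
decode_array_to_pixels <- function(a) {
  if (length(dim(a)) == 2L)            # greyscale -> replicate channels
    a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L)                  # drop alpha
    a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Load a PNG or JPG image
#'
#' Decodes the file and tags the result with its source format. No
#' resizing is performed (see [resize_to_fit()]). Greyscale files are
#' replicated to three channels; an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.jpg`, or `.jpeg` file.
#' @return An [rgb_image()].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- tryCatch(png::readPNG(path),
                  error = function(e) stop("PNG decode error: ",
                                           conditionMessage(e)))
    fmt <- "png"
  } else if (ext %in% c("jpg", "jpeg")) {
    a <- tryCatch(jpeg::readJPEG(path),
                  error = function(e) stop("JPG decode error: ",
                                           conditionMessage(e)))
    fmt <- "jpg"
  } else {
    stop("unsupported image format: .", ext, " (PNG and JPG are supported)")
  }
  rgb_image(decode_array_to_pixels(a), source_format = fmt)
}

#' Write an image as PNG
#'
#' @param image an [rgb_image()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  stopifnot_rgb_image(image)
  ok <- tryCatch({
    png::writePNG(image$pixels / 255, target = path)
    TRUE
  }, error = function(e) {
    stop("PNG write error: ", conditionMessage(e))
  })
  invisible(path)
}

#' Transcode an image to a genuine PNG file
#'
#' Performs a full re-encode of the in-memory pixels as PNG (renaming a JPG
#' file's extension would leave the lossy encoding in place; this function
#' writes a real PNG so every later read is bit-identical). Reloading the
#' written file yields pixels identical to `image$pixels`.
#'
#' @param image an [rgb_image()].
#' @param out_path destination `.png` path.
#' @return `out_path`, invisibly.
#' @export
transcode_to_png <- function(image, out_path) {
  write_png(image, out_path)
}

#' Resize an image to fit within a maximum dimension
#'
#' Downscales so that the larger dimension equals `max_dim`, preserving the
#' aspect ratio to within one pixel of rounding. Images already within
#' bounds are returned unchanged. Downscaling uses exact area averaging
#' (each output pixel is the mean of the input area it covers), which keeps
#' intensities stable for the colour-difference step. The applied scale
#' factor is recorded in `scale_applied` for coordinate back-mapping.
#'
#' @param image an [rgb_image()].
#' @param max_dim maximum allowed height or width in pixels (default 1280,
#'   a screen-fitting working resolution).
#' @return An [rgb_image()], possibly the input unchanged.
#' @export
resize_to_fit <- function(image, max_dim = 1280) {
  stopifnot_rgb_image(image)
  if (max_dim < 1) stop("max_dim must be >= 1")
  big <- max(image$height, image$width)
  if (big <= max_dim) return(image)
  s <- max_dim / big
  new_h <- max(1L, as.integer(round(image$height * s)))
  new_w <- max(1L, as.integer(round(image$width * s)))
  if (image$height >= image$width) new_h <- as.integer(max_dim)
  if (image$width >= image$height) new_w <- as.integer(max_dim)
  Wr <- overlap_weights(image$height, new_h)
  Wc <- overlap_weights(image$width, new_w)
  out <- array(0, dim = c(new_h, new_w, 3L))
  for (k in 1:3)
    out[, , k] <- Wr %*% image$pixels[, , k] %*% t(Wc)
  rgb_image(pmin(pmax(round(out), 0), 255), source_format = image$source_format,
            scale_applied = image$scale_applied * s)
}

# Row-weight matrix for exact area-averaged resampling: entry [a, i] is the
# fraction of output interval a covered by input pixel i.
overlap_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (a in seq_len(n_out)) {
    lo <- (a - 1) * s
    hi <- a * s
    i0 <- floor(lo) + 1
    i1 <- min(ceiling(hi), n_in)
    idx <- i0:i1
    ov <- pmin(idx, hi) - pmax(idx - 1, lo)
    W[a, idx] <- ov / s
  }
  W
}
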
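#' Run configuration for the batch pipeline
#'
#' Bundles the stage parameters of the two compared pipelines. In
#' `"grabcut_only"` mode the colour step is skipped entirely and the
#' original image feeds the graph-cut stage, so `chroma` settings have no
#' effect on that mode's output.
#'
#' @param mode `"preciseedge"` (colour step, then graph cut) or
#'   `"grabcut_only"`.
#' @param out_dir output directory for masks, annotations, and tables.
#' @param chroma a [chroma_params()].
#' @param grabcut list: `iterations`, `gamma`, `k_components`.
#' @param robot list: `max_rounds`, `stop_iou`, `max_stroke_len`, `inset`,
#'   `boundary_tolerance` for the scripted annotator.
#' @param measure list: `sign_cm`, `kernel_size`, `wither_band`,
#'   `torso_band`.
#' @param max_dim resize bound for [resize_to_fit()].
#' @param seed integer seed for all randomised steps.
#' @param interactive reserved for an interactive front end; the batch
#'   pipeline requires `FALSE`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("preciseedge", "grabcut_only"),
                       out_dir = tempfile("pe_run_"),
                       chroma = chroma_params(),
                       grabcut = list(iterations = 5, gamma = 50,
                                      k_components = 5),
                       robot = list(max_rounds = 10, stop_iou = 0.98,
                                    max_stroke_len = 30, inset = 2,
                                    boundary_tolerance = 1),
                       measure = list(sign_cm = c(25, 20), kernel_size = 5,
                                      wither_band = c(0.2, 0.4),
                                      torso_band = c(0.3, 0.7)),
                       max_dim = 1280, seed = 1L, interactive = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, out_dir = out_dir, chroma = chroma,
                 grabcut = grabcut, robot = robot, measure = measure,
                 max_dim = max_dim, seed = as.integer(seed),
                 interactive = interactive),
            class = "run_config")
}

#' Materialise a synthetic fixture set
#'
#' Writes side and rear scene PNGs, ground-truth mask PNGs, and a manifest
#' CSV (ids, poses, physical dimensions, scale, sign box, file paths) that
#' the segment/measure/evaluate commands consume.
#'
#' @param config a [run_config()] (supplies `out_dir` and `seed`).
#' @param n_animals number of animals; each gets a side and a rear scene.
#' @param shadow render the under-body shadow band (default `TRUE`, the
#'   realistic field condition).
#' @param noise_sd,px_per_cm scene rendering parameters.
#' @return The manifest as a data frame (also written to
#'   `out_dir/manifest.csv`), invisibly.
#' @export
simulate_command <- function(config, n_animals = 5, shadow = TRUE,
                             noise_sd = 5, px_per_cm = 2) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- with_local_seed(config$seed, sample.int(1e9L, n_animals))
  rows <- list()
  for (i in seq_len(n_animals)) {
    base <- random_scene_spec(seeds[i], pose = "side", shadow = shadow,
                              noise_sd = noise_sd, px_per_cm = px_per_cm)
    for (pose in c("side", "rear")) {
      spec <- base
      spec$pose <- pose
      if (pose == "rear") spec$seed <- base$seed + 1L
      scene <- generate_scene(spec)
      id <- sprintf("animal%03d_%s", i, pose)
      img_path <- file.path(config$out_dir, paste0(id, ".png"))
      mask_path <- file.path(config$out_dir, paste0(id, "_truth.png"))
      write_png(scene$image, img_path)
      png::writePNG(scene$truth$silhouette_mask * 1.0, mask_path)
      sb <- scene$truth$sign_box
      rows[[length(rows) + 1L]] <- data.frame(
        animal = i, pose = pose, image = img_path, truth_mask = mask_path,
        body_height_cm = spec$body_height_cm,
        body_length_cm = spec$body_length_cm,
        chest_width_cm = spec$chest_width_cm,
        chest_depth_cm = spec$chest_depth_cm,
        px_per_cm = px_per_cm,
        sign_x = sb["x"], sign_y = sb["y"], sign_w = sb["w"],
        sign_h = sb["h"],
        sign_cm_w = spec$sign_cm[1], sign_cm_h = spec$sign_cm[2])
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- (a > 0.5) * 1L
  mode(m) <- "integer"
  m
}

#' Segment a batch of images (scripted replay mode)
#'
#' For every manifest row: load, resize, transcode to PNG, apply the
#' colour step (in `"preciseedge"` mode only), run the box-initialised
#' graph cut, and refine with the scripted annotator against the manifest's
#' ground-truth mask. Persists the bounding-box-only mask, the final mask,
#' the annotation record (JSON), and a per-image CSV of stroke counts and
#' IoU. Per-image failures are logged and skipped; the command fails only
#' if every image fails.
#'
#' @param config a [run_config()].
#' @param manifest data frame from [simulate_command()] (or its CSV path).
#' @return Data frame with one row per image: `id`, `pose`, `mode`,
#'   `strokes`, `rounds`, `iou`, `mask_path`, `annotation_path`.
#' @export
segment_command <- function(config, manifest) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stop("empty manifest: nothing to segment")
  seg_dir <- file.path(config$out_dir, paste0("segment_", config$mode))
  dir.create(seg_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(); failures <- 0L
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- sprintf("animal%03d_%s", row$animal, row$pose)
    res <- tryCatch({
      img <- load_image(row$image)
      img <- resize_to_fit(img, config$max_dim)
      png_path <- file.path(seg_dir, paste0(id, "_input.png"))
      transcode_to_png(img, png_path)
      truth <- read_mask_png(row$truth_mask)
      work <- if (config$mode == "preciseedge")
        chroma_step(img, config$chroma)$image else img
      bb <- mask_bbox(truth)
      H <- nrow(truth); W <- ncol(truth)
      box <- bounding_box(
        x = max(2, bb["c0"] - 5), y = max(2, bb["r0"] - 5),
        w = min(W - 1, bb["c1"] + 5) - max(2, bb["c0"] - 5) + 1,
        h = min(H - 1, bb["r1"] + 5) - max(2, bb["r0"] - 5) + 1)
      box_only <- run_grabcut(work, annotation_set(box),
                              iterations = config$grabcut$iterations,
                              gamma = config$grabcut$gamma,
                              k_components = config$grabcut$k_components)
      png::writePNG(box_only * 1.0, file.path(seg_dir, paste0(id, "_boxonly.png")))
      seg <- segment_with_robot(
        work, truth, box,
        iterations = config$grabcut$iterations,
        max_rounds = config$robot$max_rounds,
        stop_iou = config$robot$stop_iou,
        max_stroke_len = config$robot$max_stroke_len,
        inset = config$robot$inset,
        boundary_tolerance = config$robot$boundary_tolerance,
        gamma = config$grabcut$gamma,
        k_components = config$grabcut$k_components)
      mask_path <- file.path(seg_dir, paste0(id, "_mask.png"))
      ann_path <- file.path(seg_dir, paste0(id, "_annotations.json"))
      png::writePNG(seg$mask * 1.0, mask_path)
      write_annotations(seg$annotations, ann_path)
      data.frame(id = id, animal = row$animal, pose = row$pose,
                 mode = config$mode, strokes = seg$strokes,
                 rounds = seg$rounds, iou = seg$iou,
                 mask_path = mask_path, annotation_path = ann_path)
    }, error = function(e) {
      message("segmentation failed for ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else
      out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0) stop("all images failed to segment")
  res <- do.call(rbind, out)
  utils::write.csv(res, file.path(seg_dir, "segmentation.csv"),
                   row.names = FALSE)
  res
}

#' Measure a batch of segmented animals
#'
#' Pairs each animal's side and rear masks, refines them morphologically,
#' calibrates from the sign, and writes one CSV row per animal with pixel
#' and centimetre measures. A missing rear mask yields a row without girth
#' and a warning; a corrupt mask file skips the row with a logged error.
#'
#' @param config a [run_config()].
#' @param manifest data frame (or CSV path) from [simulate_command()].
#' @param segmentation data frame (or CSV path) from [segment_command()].
#' @return Data frame of measurements (also written to
#'   `out_dir/measurements_<mode>.csv`).
#' @export
measure_command <- function(config, manifest, segmentation) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (is.character(segmentation))
    segmentation <- utils::read.csv(segmentation, stringsAsFactors = FALSE)
  rows <- list()
  for (a in unique(segmentation$animal)) {
    res <- tryCatch({
      seg_a <- segmentation[segmentation$animal == a, ]
      man_a <- manifest[manifest$animal == a, ][1, ]
      side_row <- seg_a[seg_a$pose == "side", ]
      if (nrow(side_row) == 0) stop("no side mask for animal ", a)
      side_mask <- refine_mask(read_mask_png(side_row$mask_path[1]),
                               config$measure$kernel_size)
      img <- load_image(manifest[manifest$animal == a &
                                   manifest$pose == "side", "image"][1])
      ret <- chroma_step(img, config$chroma)$retention
      sign_box <- c(x = man_a$sign_x, y = man_a$sign_y,
                    w = man_a$sign_w, h = man_a$sign_h)
      scale <- extract_calibration(
        extract_sign_mask(ret, sign_box),
        c(man_a$sign_cm_w, man_a$sign_cm_h))
      side_m <- measure_side(side_mask, scale,
                             wither_band = config$measure$wither_band,
                             torso_band = config$measure$torso_band)
      rear_row <- seg_a[seg_a$pose == "rear", ]
      rear_m <- NULL
      if (nrow(rear_row) > 0) {
        rear_mask <- refine_mask(read_mask_png(rear_row$mask_path[1]),
                                 config$measure$kernel_size)
        rear_m <- measure_rear(rear_mask, scale,
                               torso_band = config$measure$torso_band)
      }
      m <- combine_measurements(side_m, rear_m)
      strokes <- sum(seg_a$strokes)
      data.frame(animal = a, mode = config$mode,
                 height_px = m$height_px, height_cm = m$height_cm,
                 length_px = m$length_px, length_cm = m$length_cm,
                 chest_depth_cm = m$chest_depth_cm,
                 chest_width_cm = m$chest_width_cm,
                 girth_cm = m$girth_cm,
                 px_per_cm_x = scale$px_per_cm_x,
                 px_per_cm_y = scale$px_per_cm_y,
                 strokes = strokes)
    }, error = function(e) {
      message("measurement failed for animal ", a, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) stop("all animals failed to measure")
  out <- do.call(rbind, rows)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out, file.path(config$out_dir,
                                  paste0("measurements_", config$mode,
                                         ".csv")),
                   row.names = FALSE)
  out
}

#' Compare two pipeline runs
#'
#' Takes the segmentation/measurement tables of a box-only run and a
#' two-step run over the same images, verifies the image sets match, and
#' emits the comparison report (stroke statistics, Wilcoxon test, per-trait
#' correlations against the manifest's ground-truth dimensions).
#'
#' @param config a [run_config()] (supplies `out_dir`).
#' @param manifest data frame (or CSV path) from [simulate_command()].
#' @param measures_a,measures_b measurement tables (or CSV paths) from
#'   [measure_command()] for the baseline and compared runs.
#' @param paired use the paired Wilcoxon test (default `TRUE`: same
#'   scenes under both modes).
#' @return A [comparison_report()], invisibly; files are written under
#'   `out_dir/report`.
#' @export
evaluate_command <- function(config, manifest, measures_a, measures_b,
                             paired = TRUE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (is.character(measures_a))
    measures_a <- utils::read.csv(measures_a, stringsAsFactors = FALSE)
  if (is.character(measures_b))
    measures_b <- utils::read.csv(measures_b, stringsAsFactors = FALSE)
  if (!setequal(measures_a$animal, measures_b$animal))
    stop("runs cover different animals: ",
         paste(union(setdiff(measures_a$animal, measures_b$animal),
                     setdiff(measures_b$animal, measures_a$animal)),
               collapse = ", "))
  measures_a <- measures_a[order(measures_a$animal), ]
  measures_b <- measures_b[order(measures_b$animal), ]
  man <- manifest[manifest$pose == "side", ]
  man <- man[match(measures_b$animal, man$animal), ]
  digital <- list(height = measures_b$height_cm,
                  length = measures_b$length_cm,
                  width = measures_b$chest_width_cm)
  reference <- list(height = man$body_height_cm,
                    length = man$body_length_cm,
                    width = man$chest_width_cm)
  rep <- comparison_report(measures_a$strokes, measures_b$strokes,
                           digital = digital, reference = reference,
                           labels = c(measures_a$mode[1],
                                      measures_b$mode[1]),
                           paired = paired)
  write_comparison_report(rep, file.path(config$out_dir, "report"))
  invisible(rep)
}
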
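#' Stroke-count distribution comparison
#'
#' Reproduces the annotation-effort comparison: per-sample normality
#' testing (Kolmogorov-Smirnov with sample-estimated mean and standard
#' deviation, i.e. the Lilliefors correction, via
#' [nortest::lillie.test()]), and a Wilcoxon test that method B needs
#' fewer strokes than method A. For independent samples this is the
#' two-sample rank-sum (Mann-Whitney) test; with `paired = TRUE` it is the
#' signed-rank test on the per-image differences. Exact p-values are used
#' where the sample permits (small n, no ties), the usual midrank normal
#' approximation otherwise.
#'
#' @param counts_a stroke counts of the baseline method (e.g. box-only
#'   graph cut), length >= 3.
#' @param counts_b stroke counts of the compared method (e.g. the two-step
#'   pipeline), length >= 3.
#' @param alternative alternative hypothesis for the Wilcoxon test;
#'   default `"less"` tests `counts_b < counts_a`.
#' @param paired treat the samples as paired (same images under both
#'   methods).
#' @return A list with `mean_a`, `sd_a`, `mean_b`, `sd_b`, `ks_p_a`,
#'   `ks_p_b`, `wilcoxon_p`, and `wilcoxon_test` (a description string).
#'   `ks_p_*` is `NA` with a `degenerate` flag when a sample is constant
#'   (normality is then undefined); `wilcoxon_p` is `NA` when a paired
#'   comparison has no nonzero differences.
#' @export
stroke_distribution_tests <- function(counts_a, counts_b,
                                      alternative = c("less", "two.sided",
                                                      "greater"),
                                      paired = FALSE) {
  alternative <- match.arg(alternative)
  if (length(counts_a) < 3 || length(counts_b) < 3)
    stop("each sample needs at least 3 stroke counts")
  if (paired && length(counts_a) != length(counts_b))
    stop("paired samples must have equal length")

  ks_norm_p <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    if (length(x) < 4) return(NA_real_)   # Lilliefors needs n >= 4
    nortest::lillie.test(x)$p.value
  }
  wp <- tryCatch(
    suppressWarnings(stats::wilcox.test(counts_b, counts_a,
                                        alternative = alternative,
                                        paired = paired)$p.value),
    error = function(e) NA_real_)
  list(
    mean_a = mean(counts_a), sd_a = stats::sd(counts_a),
    mean_b = mean(counts_b), sd_b = stats::sd(counts_b),
    ks_p_a = ks_norm_p(counts_a), ks_p_b = ks_norm_p(counts_b),
    degenerate = stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0,
    wilcoxon_p = wp,
    wilcoxon_test = paste0(if (paired) "signed-rank (paired)"
                           else "rank-sum (unpaired)",
                           ", alternative b ", alternative, " a")
  )
}

#' Per-trait Pearson correlations of digital versus reference measures
#'
#' @param digital named list (or data frame) of numeric vectors of
#'   digitally extracted measures, one element per trait.
#' @param reference same structure with the reference (manual or
#'   ground-truth) measures; traits and lengths must match.
#' @return Named numeric vector of Pearson correlation coefficients.
#' @export
measurement_correlations <- function(digital, reference) {
  traits <- names(digital)
  if (is.null(traits) || !setequal(traits, names(reference)))
    stop("digital and reference must cover the same named traits")
  vapply(traits, function(tr) {
    x <- digital[[tr]]; y <- reference[[tr]]
    if (length(x) != length(y))
      stop("trait '", tr, "': vector lengths differ")
    if (length(x) < 3) stop("trait '", tr, "': need at least 3 pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("trait '", tr, "': constant vector, correlation undefined")
    stats::cor(x, y)
  }, numeric(1))
}

#' Assemble a comparison report
#'
#' Bundles stroke-distribution statistics and per-trait correlations into
#' one report object that can be written as JSON, text, and stroke-count
#' histograms (bin width 50 strokes).
#'
#' @param strokes_a,strokes_b stroke counts for the two methods.
#' @param digital,reference optional per-trait measures for
#'   [measurement_correlations()].
#' @param labels length-2 character vector naming the methods.
#' @param paired passed to [stroke_distribution_tests()].
#' @return A list of class `comparison_report`.
#' @export
comparison_report <- function(strokes_a, strokes_b, digital = NULL,
                              reference = NULL,
                              labels = c("grabcut_only", "preciseedge"),
                              paired = FALSE) {
  st <- stroke_distribution_tests(strokes_a, strokes_b, paired = paired)
  r <- if (!is.null(digital)) measurement_correlations(digital, reference)
  structure(list(
    labels = labels,
    strokes_a = strokes_a, strokes_b = strokes_b,
    mean_strokes_a = st$mean_a, std_strokes_a = st$sd_a,
    mean_strokes_b = st$mean_b, std_strokes_b = st$sd_b,
    ks_p_a = st$ks_p_a, ks_p_b = st$ks_p_b,
    wilcoxon_p = st$wilcoxon_p, wilcoxon_test = st$wilcoxon_test,
    stroke_reduction_pct =
      100 * (1 - st$mean_b / max(st$mean_a, .Machine$double.eps)),
    pearson_r = r
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Stroke counts: %s mean %.2f (sd %.2f) | %s mean %.2f (sd %.2f)\n",
              x$labels[1], x$mean_strokes_a, x$std_strokes_a,
              x$labels[2], x$mean_strokes_b, x$std_strokes_b))
  cat(sprintf("Stroke reduction: %.1f%%; Wilcoxon p = %.4g (%s)\n",
              x$stroke_reduction_pct, x$wilcoxon_p, x$wilcoxon_test))
  if (!is.null(x$pearson_r)) {
    cat("Pearson r by trait:\n")
    for (tr in names(x$pearson_r))
      cat(sprintf("  %-12s %.4f\n", tr, x$pearson_r[[tr]]))
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits `report.json`, `report.txt`, and (when a PNG graphics device is
#' available) stroke-count histograms with 50-stroke bins.
#'
#' @param report a [comparison_report()].
#' @param dir output directory, created if needed.
#' @param histograms also write histogram PNGs (default `TRUE`).
#' @return `dir`, invisibly.
#' @export
write_comparison_report <- function(report, dir, histograms = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fields <- report[c("labels", "mean_strokes_a", "std_strokes_a",
                     "mean_strokes_b", "std_strokes_b", "ks_p_a", "ks_p_b",
                     "wilcoxon_p", "wilcoxon_test", "stroke_reduction_pct")]
  fields$pearson_r <- as.list(report$pearson_r)
  jsonlite::write_json(fields, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  if (histograms) {
    ok <- tryCatch({
      for (side in c("a", "b")) {
        counts <- report[[paste0("strokes_", side)]]
        lab <- report$labels[if (side == "a") 1 else 2]
        grDevices::png(file.path(dir, paste0("strokes_", lab, ".png")),
                       width = 640, height = 480)
        graphics::hist(counts,
                       breaks = seq(0, max(counts, 50) + 50, by = 50),
                       main = paste("Stroke counts:", lab),
                       xlab = "strokes per image", col = "grey70")
        grDevices::dev.off()
      }
      TRUE
    }, error = function(e) {
      warning("histograms skipped: ", conditionMessage(e))
      FALSE
    })
  }
  invisible(dir)
}
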
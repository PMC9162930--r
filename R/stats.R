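# Aggregation and reporting.
#
# Scopes nest: ROI (one line profile) -> z-image (ten ROIs) -> electrode
# (ten z-images taken at random positions) -> condition (replicate
# electrodes). The image statistic is the mean over measured ROIs; the
# electrode statistic is the unweighted mean of image means, with the SD
# across image means quantifying thickness homogeneity over the electrode.

#' Summarize ROI thicknesses of one z-image
#'
#' Descriptive statistics over the non-missing ROI thicknesses of a single
#' image: count, mean, sample SD (n - 1 denominator), median, quartiles
#' (linear interpolation), min and max. Missing thicknesses (ROIs flagged
#' `no_signal`) are excluded from the statistics but counted via
#' `n_roi_total`.
#'
#' @param results Tibble from [compute_thickness()], restricted to one
#'   `image_id` (an error otherwise).
#' @return A one-row tibble: `image_id`, `n_roi_total`, `n_roi_measured`,
#'   `mean_um`, `sd_um`, `median_um`, `q1_um`, `q3_um`, `min_um`, `max_um`.
#' @export
summarize_image <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  ids <- unique(results$image_id)
  if (length(ids) != 1L) {
    stop("summarize_image() expects results of exactly one image; got ",
         length(ids), " (use summarize_images() for batches)", call. = FALSE)
  }
  th <- results$thickness_um[!is.na(results$thickness_um)]
  n <- length(th)
  if (n == 0L) {
    return(tibble::tibble(
      image_id = ids, n_roi_total = nrow(results), n_roi_measured = 0L,
      mean_um = NA_real_, sd_um = NA_real_, median_um = NA_real_,
      q1_um = NA_real_, q3_um = NA_real_, min_um = NA_real_,
      max_um = NA_real_
    ))
  }
  q <- stats::quantile(th, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    image_id = ids,
    n_roi_total = nrow(results),
    n_roi_measured = n,
    mean_um = mean(th),
    sd_um = if (n >= 2L) stats::sd(th) else NA_real_,
    median_um = q[2],
    q1_um = q[1],
    q3_um = q[3],
    min_um = min(th),
    max_um = max(th)
  )
}

#' @rdname summarize_image
#' @export
summarize_images <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  parts <- split(results, factor(results$image_id,
                                 levels = unique(results$image_id)))
  dplyr::bind_rows(lapply(parts, summarize_image))
}

#' Summarize an electrode from its image summaries
#'
#' The electrode-level thickness is the unweighted mean of the image means,
#' and its SD is the sample SD across image means — the spread over the
#' z-images imaged at different positions, i.e. a measure of how
#' homogeneously the electrode is covered. Images with no measured ROI are
#' excluded.
#'
#' @param image_summaries Tibble from [summarize_images()], one row per
#'   z-image of this electrode.
#' @param electrode_id Identifier for the summary row.
#' @return A one-row tibble: `electrode_id`, `n_images`, `mean_um`,
#'   `sd_um` (`NA` for fewer than two images), plus the input summaries in
#'   the list-column `per_image`.
#' @export
summarize_electrode <- function(image_summaries, electrode_id = "electrode") {
  stopifnot(is.data.frame(image_summaries))
  ok <- image_summaries[image_summaries$n_roi_measured > 0L, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("no image with measured ROIs to summarize", call. = FALSE)
  }
  m <- ok$mean_um
  tibble::tibble(
    electrode_id = electrode_id,
    n_images = nrow(ok),
    mean_um = mean(m),
    sd_um = if (nrow(ok) >= 2L) stats::sd(m) else NA_real_,
    per_image = list(image_summaries)
  )
}

#' Pearson correlation with t-based p-value
#'
#' Correlates a performance indicator (e.g. maximum current density) with
#' biofilm thickness across experiments: the standard Pearson coefficient
#' with the two-sided p-value from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither may be
#'   constant.
#' @return A one-row tibble with `r`, `p` and `n`.
#' @examples
#' pearson_cor(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("x and y differ in length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs, got ", n, call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Positional homogeneity report
#'
#' Five-number summary of ROI thickness per imaged position, with an
#' exploratory outlier flag: a position is flagged when its median lies
#' outside 1.5 times the interquartile range beyond the quartiles of the
#' position medians (the usual boxplot whisker rule). This is a
#' descriptive screen for heterogeneous coverage — e.g. one end of an
#' electrode recruiting much thicker biofilm — not a hypothesis test.
#'
#' @param image_summaries Tibble from [summarize_images()], ordered by
#'   position on the electrode (at least 2 rows).
#' @param positions Optional position labels; defaults to 1..n in row
#'   order.
#' @return A tibble with one row per position: `position`, `image_id`,
#'   `n_roi_measured`, `min_um`, `q1_um`, `median_um`, `q3_um`, `max_um`,
#'   `flagged`.
#' @export
homogeneity_report <- function(image_summaries, positions = NULL) {
  stopifnot(is.data.frame(image_summaries), nrow(image_summaries) >= 2L)
  n <- nrow(image_summaries)
  if (is.null(positions)) positions <- seq_len(n)
  stopifnot(length(positions) == n)
  med <- image_summaries$median_um
  q <- stats::quantile(med, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  tibble::tibble(
    position = positions,
    image_id = image_summaries$image_id,
    n_roi_measured = image_summaries$n_roi_measured,
    min_um = image_summaries$min_um,
    q1_um = image_summaries$q1_um,
    median_um = med,
    q3_um = image_summaries$q3_um,
    max_um = image_summaries$max_um,
    flagged = !is.na(med) & (med < lo | med > hi)
  )
}

#' Boxplot of ROI thickness by image position
#'
#' Visual companion to [homogeneity_report()]: one box per z-image, in
#' acquisition/position order, of its ROI thicknesses.
#'
#' @param results Tibble from [compute_thickness()].
#' @return A ggplot object.
#' @export
plot_homogeneity <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_homogeneity() needs the ggplot2 package", call. = FALSE)
  }
  df <- results[!is.na(results$thickness_um), ]
  df$image_id <- factor(df$image_id, levels = unique(results$image_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image_id,
                                   y = .data$thickness_um)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "z-image (position on electrode)",
                  y = "biofilm thickness [µm]")
}
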
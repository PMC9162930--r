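# Extracting ROI line profiles from xz-section images.
#
# The microscope's histogram export is a mean-intensity line profile per
# ROI strip. Reproducing that aggregation directly from grayscale TIFF
# sections lets the whole pipeline run from images, without the vendor
# software in the loop.

#' An xz-section image
#'
#' A grayscale vertical section through a biofilm: rows are depth (z),
#' columns are lateral position (x).
#'
#' @param pixels Numeric matrix of intensities, rows = z, columns = x;
#'   at least 3 rows.
#' @param pixel_size_x_um,pixel_size_z_um Physical pixel size in
#'   micrometres (> 0).
#' @param image_id Character identifier.
#' @return An object of class `section_image`.
#' @export
section_image <- function(pixels, pixel_size_x_um = 1, pixel_size_z_um = 1,
                          image_id = "image") {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            nrow(pixels) >= 3L, ncol(pixels) >= 1L,
            pixel_size_x_um > 0, pixel_size_z_um > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel intensities must be finite and >= 0", call. = FALSE)
  }
  structure(
    list(pixels = pixels,
         pixel_size_x_um = as.numeric(pixel_size_x_um),
         pixel_size_z_um = as.numeric(pixel_size_z_um),
         image_id = as.character(image_id)),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> '%s': %d z x %d x pixels (%g x %g um each)\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_z_um, x$pixel_size_x_um))
  invisible(x)
}

#' Read an xz-section from a grayscale TIFF
#'
#' Reads a single-plane grayscale TIFF as a [section_image()]. Pixel sizes
#' are taken from the TIFF resolution tags when present (resolution unit
#' inch or cm); otherwise the values supplied as arguments are used, and
#' failing both, 1 micrometre per pixel with a warning. Multi-channel
#' (e.g. RGB) files are refused unless `channel` selects the quantitative
#' channel explicitly — for the usual nucleic-acid double staining that is
#' the green Syto9 channel.
#'
#' @param path Path to a TIFF file.
#' @param channel Integer channel to extract from a multi-channel image
#'   (1 = red, 2 = green, 3 = blue for RGB). `NULL` for grayscale input.
#' @param pixel_size_x_um,pixel_size_z_um Fallback pixel sizes in
#'   micrometres when the file carries no resolution metadata.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [section_image()].
#' @export
read_stack <- function(path, channel = NULL,
                       pixel_size_x_um = NULL, pixel_size_z_um = NULL,
                       image_id = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file",
                               call. = FALSE)
  if (is.null(image_id)) image_id <- tools::file_path_sans_ext(basename(path))
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) stop("cannot read '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  info <- attributes(img)
  if (length(dim(img)) == 3L) {
    if (is.null(channel)) {
      stop("'", path, "' has ", dim(img)[3],
           " channels; select one with channel = (2 for the green/Syto9 ",
           "channel of an RGB export)", call. = FALSE)
    }
    stopifnot(channel >= 1L, channel <= dim(img)[3])
    img <- img[, , channel]
  }
  px <- resolve_pixel_sizes(info, pixel_size_x_um, pixel_size_z_um)
  section_image(img, pixel_size_x_um = px[1], pixel_size_z_um = px[2],
                image_id = image_id)
}

resolve_pixel_sizes <- function(info, px_x, px_z) {
  unit_um <- switch(as.character(info$resolution.unit %||% ""),
                    inch = 25400, cm = 10000, NULL)
  from_tag <- function(res) {
    if (!is.null(unit_um) && !is.null(res) && is.finite(res) && res > 0) {
      unit_um / res
    } else NULL
  }
  x <- from_tag(info$x.resolution) %||% px_x
  z <- from_tag(info$y.resolution) %||% px_z
  if (is.null(x) || is.null(z)) {
    warning("no pixel-size metadata found; assuming 1 um per pixel",
            call. = FALSE)
    x <- x %||% 1
    z <- z %||% 1
  }
  c(x, z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract per-ROI line profiles from an xz-section
#'
#' Partitions the image columns into `n_roi` equal-width vertical strips
#' (any remainder columns join the last strip) and records, for each strip,
#' the aggregate pixel intensity at every depth — by default the arithmetic
#' mean across the strip's columns, emulating the microscope software's
#' histogram export. For the standard acquisition geometry of a 185 um wide
#' section and ten ROIs, each strip is 18.5 um wide.
#'
#' @param image A [section_image()].
#' @param n_roi Number of ROI strips (default 10).
#' @param agg Aggregation across strip columns: `"mean"` (default) or
#'   `"median"`.
#' @param orientation Profile orientation, see [z_profile()]. Row 0 of the
#'   image is the first acquired plane (z = 0).
#' @return A [profile_set()] with `image_width_um` and `roi_width_um` set.
#' @export
extract_profiles <- function(image, n_roi = 10L,
                             agg = c("mean", "median"),
                             orientation = c("electrode_low_z",
                                             "electrode_high_z")) {
  agg <- match.arg(agg)
  orientation <- match.arg(orientation)
  stopifnot(inherits(image, "section_image"))
  w <- ncol(image$pixels)
  n_roi <- as.integer(n_roi)
  if (n_roi < 1L || n_roi > w) {
    stop("n_roi (", n_roi, ") must be between 1 and the image width (",
         w, " columns)", call. = FALSE)
  }
  base <- w %/% n_roi
  starts <- (seq_len(n_roi) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, w)  # last strip absorbs the remainder
  z <- (seq_len(nrow(image$pixels)) - 1L) * image$pixel_size_z_um
  fun <- if (agg == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  profiles <- lapply(seq_len(n_roi), function(i) {
    strip <- image$pixels[, starts[i]:ends[i], drop = FALSE]
    z_profile(z, fun(strip), roi_id = i, image_id = image$image_id,
              orientation = orientation)
  })
  width_um <- w * image$pixel_size_x_um
  profile_set(profiles, image_width_um = width_um,
              roi_width_um = width_um / n_roi)
}

#' Write an xz-section to a 16-bit grayscale TIFF
#'
#' Intensities are rounded to integers and must fit 0..65535. The TIFF
#' writer does not persist resolution tags, so pixel sizes must be passed
#' to [read_stack()] explicitly when re-reading files written here.
#'
#' @param image A [section_image()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  px <- round(image$pixels)
  if (max(px) > 65535) stop("intensities exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
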
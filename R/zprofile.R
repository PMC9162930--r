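#' Fluorescence intensity z-profile for one ROI
#'
#' A `z_profile` holds the fluorescence intensity of one region of interest
#' (ROI) of a confocal xz-section as a function of depth `z`. It is the unit
#' of input for boundary detection: one z-image contributes one profile per
#' ROI (typically ten vertical strips spanning the image width).
#'
#' @param z Numeric vector of depth positions in micrometres. Must be
#'   strictly monotonic (increasing or decreasing) and of length >= 3.
#' @param intensity Numeric vector of fluorescence intensities in arbitrary
#'   detector units; same length as `z`, finite and non-negative.
#' @param roi_id Small integer ROI label (1..n within an image).
#' @param image_id Character identifier of the z-image the ROI belongs to.
#' @param orientation Which physical end of the profile touches the
#'   electrode: `"electrode_low_z"` (default; electrode at the start of the
#'   z axis, buffer and planktonic cells at the end) or `"electrode_high_z"`.
#'
#' @return An object of class `z_profile`: a list with fields `z`,
#'   `intensity`, `roi_id`, `image_id`, `orientation`.
#' @examples
#' p <- z_profile(z = 0:6, intensity = c(1, 1, 8, 9, 8, 1, 1))
#' roi_thickness(p)
#' @export
z_profile <- function(z, intensity, roi_id = 1L, image_id = "image",
                      orientation = c("electrode_low_z", "electrode_high_z")) {
  orientation <- match.arg(orientation)
  z <- as.numeric(z)
  intensity <- as.numeric(intensity)
  p <- structure(
    list(z = z, intensity = intensity, roi_id = as.integer(roi_id),
         image_id = as.character(image_id), orientation = orientation),
    class = "z_profile"
  )
  validate_z_profile(p)
}

#' @rdname z_profile
#' @param x Object to validate or test.
#' @export
validate_z_profile <- function(x) {
  stopifnot(inherits(x, "z_profile"))
  n <- length(x$z)
  if (n < 3L) {
    stop("z_profile needs at least 3 samples, got ", n, call. = FALSE)
  }
  if (length(x$intensity) != n) {
    stop("z and intensity differ in length (", n, " vs ",
         length(x$intensity), ")", call. = FALSE)
  }
  dz <- diff(x$z)
  if (any(!is.finite(x$z)) || !(all(dz > 0) || all(dz < 0))) {
    stop("z must be finite and strictly monotonic", call. = FALSE)
  }
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (length(x$roi_id) != 1L || is.na(x$roi_id)) {
    stop("roi_id must be a single integer", call. = FALSE)
  }
  x
}

#' @rdname z_profile
#' @export
is_z_profile <- function(x) inherits(x, "z_profile")

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("<z_profile> image '%s', ROI %d: %d samples, z %g..%g um, %s\n",
              x$image_id, x$roi_id, length(x$z), x$z[1],
              x$z[length(x$z)], x$orientation))
  invisible(x)
}

#' @export
length.z_profile <- function(x) length(x$z)

#' Collection of z-profiles grouped by image
#'
#' A `profile_set` bundles the [z_profile()] objects of one or more z-images,
#' e.g. everything read from one microscope CSV export or extracted from one
#' xz-section image. Profiles of the same image must share an identical z
#' grid and carry unique ROI ids.
#'
#' @param profiles List of [z_profile()] objects.
#' @param image_width_um Optional physical width of the imaged area in
#'   micrometres (e.g. 185 for the standard acquisition geometry).
#' @param roi_width_um Optional width of one ROI strip in micrometres. When
#'   both widths are given, `roi_width_um` must equal
#'   `image_width_um / n_roi`.
#'
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(profiles, image_width_um = NULL, roi_width_um = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  for (p in profiles) validate_z_profile(p)
  ids <- vapply(profiles, function(p) p$image_id, character(1))
  for (img in unique(ids)) {
    grp <- profiles[ids == img]
    rois <- vapply(grp, function(p) p$roi_id, integer(1))
    if (anyDuplicated(rois)) {
      stop("duplicate roi_id within image '", img, "'", call. = FALSE)
    }
    z0 <- grp[[1]]$z
    same <- vapply(grp, function(p) identical(p$z, z0), logical(1))
    if (!all(same)) {
      stop("profiles of image '", img, "' do not share one z grid",
           call. = FALSE)
    }
  }
  if (!is.null(image_width_um) && !is.null(roi_width_um)) {
    n_roi <- max(lengths(split(seq_along(ids), ids)))
    expected <- image_width_um / n_roi
    if (abs(roi_width_um - expected) > 1e-9 * max(1, expected)) {
      stop("roi_width_um (", roi_width_um, ") != image_width_um / n_roi (",
           expected, ")", call. = FALSE)
    }
  }
  structure(
    list(profiles = profiles,
         image_width_um = image_width_um,
         roi_width_um = roi_width_um),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  ids <- vapply(x$profiles, function(p) p$image_id, character(1))
  cat(sprintf("<profile_set> %d profiles across %d image(s)\n",
              length(x$profiles), length(unique(ids))))
  if (!is.null(x$image_width_um)) {
    cat(sprintf("  image width %g um", x$image_width_um))
    if (!is.null(x$roi_width_um)) cat(sprintf(", ROI width %g um", x$roi_width_um))
    cat("\n")
  }
  invisible(x)
}

#' @export
length.profile_set <- function(x) length(x$profiles)
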
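#' Configuration for threshold-based boundary detection
#'
#' Bundles the tunable parameters of the boundary-detection algorithm. The
#' detection threshold on each side of the intensity maximum is
#' `multiplier` times the mean background intensity estimated on that side.
#' The default multiplier of 3 suits low-background substrata such as ITO
#' glass; for brighter electrode materials a smaller multiplier (e.g. 2)
#' may be needed to find the biofilm at all.
#'
#' @param multiplier Positive factor applied to the mean background
#'   intensity to form the detection threshold. Default 3.
#' @param background_window_fraction Fraction (0, 0.5] of the profile, taken
#'   at each outer end, over which the background mean is computed.
#'   Default 0.10; at least one sample is always used.
#' @param require_contiguity_below If `TRUE`, the electrode-side boundary is
#'   the start of the contiguous above-threshold run containing the maximum
#'   (symmetric with the buffer side) instead of the first exceedance
#'   scanning from the electrode edge. Default `FALSE`.
#' @param orientation Default profile orientation applied when a profile
#'   does not specify one; see [z_profile()].
#' @param peak_anchor How the film-interior anchor index is chosen:
#'   `"longest_run"` (default) anchors on the maximum of the longest
#'   contiguous above-threshold run, so an isolated planktonic spot that
#'   outshines the film peak cannot hijack the boundary search;
#'   `"global_max"` anchors on the raw intensity maximum (the literal
#'   histogram-maximum rule). The two agree whenever the brightest sample
#'   lies inside the widest above-threshold structure, i.e. on any
#'   profile without a brighter-than-film artifact.
#' @param iterative_background If `TRUE`, the background mean is refined by
#'   repeatedly recomputing it over the sub-threshold samples of its side
#'   until the threshold stops changing. Default `FALSE` (plain
#'   trailing-window mean).
#' @param saturation_level Optional detector saturation value; profiles
#'   whose maximum reaches it are flagged `saturated`. Default `NA`
#'   (disabled).
#'
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(multiplier = 3,
                             background_window_fraction = 0.10,
                             require_contiguity_below = FALSE,
                             orientation = c("electrode_low_z",
                                             "electrode_high_z"),
                             peak_anchor = c("longest_run", "global_max"),
                             iterative_background = FALSE,
                             saturation_level = NA_real_) {
  orientation <- match.arg(orientation)
  peak_anchor <- match.arg(peak_anchor)
  stopifnot(is.numeric(multiplier), length(multiplier) == 1L, multiplier > 0,
            is.numeric(background_window_fraction),
            background_window_fraction > 0,
            background_window_fraction <= 0.5)
  structure(
    list(multiplier = multiplier,
         background_window_fraction = background_window_fraction,
         require_contiguity_below = isTRUE(require_contiguity_below),
         orientation = orientation,
         peak_anchor = peak_anchor,
         iterative_background = isTRUE(iterative_background),
         saturation_level = as.numeric(saturation_level)),
    class = "threshold_config"
  )
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(paste0("<threshold_config> multiplier %g, background window ",
                     "%g%%, %s lower boundary, %s\n"),
              x$multiplier, 100 * x$background_window_fraction,
              if (x$require_contiguity_below) "contiguous-run" else
                "first-exceedance",
              x$orientation))
  invisible(x)
}

#' Locate the intensity maximum of a profile
#'
#' Returns the index of the maximum fluorescence intensity, the split point
#' between the electrode side and the buffer side of the profile. Ties
#' break to the smallest index so that the result is deterministic. A
#' constant profile returns index 1; downstream thickness computation then
#' reports `no_signal` because no sample can exceed the background
#' threshold.
#'
#' @param profile A [z_profile()].
#' @return Integer index (1-based) into the profile.
#' @examples
#' find_peak(z_profile(0:4, c(1, 5, 9, 5, 1)))  # 3
#' @export
find_peak <- function(profile) {
  validate_z_profile(profile)
  which.max(profile$intensity)
}

#' Estimate the background intensity on one side of the peak
#'
#' The electrode (below the biofilm) and the buffer with planktonic cells
#' (above it) have different background levels, so the background mean is
#' estimated separately per side, from the trailing window of samples at
#' the profile end farthest from the peak on that side. The window never
#' includes the peak itself and always contains at least one sample.
#'
#' @param profile A [z_profile()].
#' @param side `"electrode"` or `"buffer"`.
#' @param id_max Index of the profile maximum; defaults to [find_peak()].
#' @param config A [threshold_config()].
#' @return A list of class `background_estimate` with fields `side`,
#'   `mean_intensity`, `n_samples`, `window_fraction`.
#' @export
estimate_background <- function(profile, side = c("electrode", "buffer"),
                                id_max = find_peak(profile),
                                config = threshold_config()) {
  side <- match.arg(side)
  validate_z_profile(profile)
  n <- length(profile$z)
  # index 1 = electrode end after orientation normalization
  int <- oriented_intensity(profile)
  im <- if (profile$orientation == "electrode_high_z") n + 1L - id_max else id_max
  w <- max(1L, floor(config$background_window_fraction * n))
  if (side == "electrode") {
    w <- min(w, max(1L, im - 1L))      # never swallow the peak
    idx <- seq_len(w)
  } else {
    w <- min(w, max(1L, n - im))
    idx <- seq.int(n - w + 1L, n)
  }
  m <- mean(int[idx])
  if (config$iterative_background) {
    half <- if (side == "electrode") seq_len(max(im - 1L, 1L)) else
      seq.int(min(im + 1L, n), n)
    repeat {
      thr <- config$multiplier * m
      sub <- int[half][int[half] <= thr]
      if (length(sub) == 0L) break
      m2 <- mean(sub)
      if (isTRUE(all.equal(m2, m))) break
      m <- m2
    }
    idx <- half
  }
  structure(
    list(side = side, mean_intensity = m, n_samples = length(idx),
         window_fraction = config$background_window_fraction),
    class = "background_estimate"
  )
}

# intensity vector with electrode at index 1, regardless of stored orientation
oriented_intensity <- function(profile) {
  if (profile$orientation == "electrode_high_z") rev(profile$intensity)
  else profile$intensity
}

# Workers on plain vectors with electrode at index 1. "Above threshold"
# means strictly greater: samples at exactly the threshold count as
# background, matching NA-masking of non-exceeding pixels.

lower_boundary_idx <- function(int, threshold, id_max, contiguous = FALSE) {
  out <- list(index = NA_integer_, found = FALSE, at_edge = FALSE)
  if (contiguous) {
    if (int[id_max] <= threshold) return(out)
    i <- id_max
    while (i > 1L && int[i - 1L] > threshold) i <- i - 1L
    out$index <- i
    out$found <- TRUE
    out$at_edge <- i == 1L
    return(out)
  }
  hits <- which(int[seq_len(id_max)] > threshold)
  if (length(hits) == 0L) return(out)
  out$index <- hits[1L]
  out$found <- TRUE
  out$at_edge <- out$index == 1L
  out
}

# Anchor index for the boundary search: the maximum within the longest
# contiguous above-threshold run (ties: brighter run, then lower index).
# Falls back to the global maximum when nothing exceeds the threshold.
film_anchor_idx <- function(int, threshold) {
  above <- int > threshold
  if (!any(above)) return(which.max(int))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  len <- ends - starts + 1L
  mx <- mapply(function(s, e) max(int[s:e]), starts, ends)
  best <- order(-len, -mx, starts)[1L]
  starts[best] + which.max(int[starts[best]:ends[best]]) - 1L
}

upper_boundary_idx <- function(int, threshold, id_max) {
  out <- list(index = NA_integer_, found = FALSE, at_edge = FALSE,
              spike_rejected = FALSE)
  if (int[id_max] <= threshold) return(out)
  n <- length(int)
  j <- id_max
  while (j < n && int[j + 1L] > threshold) j <- j + 1L
  out$index <- j
  out$found <- TRUE
  out$at_edge <- j == n
  if (j < n) out$spike_rejected <- any(int[seq.int(j + 1L, n)] > threshold)
  out
}

#' Boundary between electrode and biofilm
#'
#' Scanning from the electrode edge toward the intensity maximum, returns
#' the first index whose intensity strictly exceeds the threshold. With
#' `contiguous = TRUE` the start of the contiguous above-threshold run
#' containing the maximum is returned instead (robust against isolated
#' bright pixels near the electrode).
#'
#' @param profile A [z_profile()].
#' @param threshold Detection threshold in intensity units (>= 0).
#' @param id_max Index of the profile maximum.
#' @param contiguous Use run-contiguity semantics instead of first
#'   exceedance.
#' @return A list with `index` (into the profile as stored), `found`, and
#'   `at_edge` (boundary coincides with the electrode-side profile edge).
#' @export
find_lower_boundary <- function(profile, threshold,
                                id_max = find_peak(profile),
                                contiguous = FALSE) {
  validate_z_profile(profile)
  n <- length(profile$z)
  flipped <- profile$orientation == "electrode_high_z"
  im <- if (flipped) n + 1L - id_max else id_max
  res <- lower_boundary_idx(oriented_intensity(profile), threshold, im,
                            contiguous)
  if (flipped && res$found) res$index <- n + 1L - res$index
  res
}

#' Boundary between biofilm and buffer
#'
#' Returns the last index of the contiguous above-threshold run containing
#' the intensity maximum on the buffer side: equivalently, one before the
#' first sample past the maximum that falls below the threshold. Bright
#' samples beyond that first sub-threshold gap originate from planktonic
#' cells floating above the biofilm; they are ignored and reported via
#' `spike_rejected`, so the biofilm end is never overestimated.
#'
#' @inheritParams find_lower_boundary
#' @return A list with `index`, `found`, `at_edge` (run reaches the buffer
#'   edge of the profile) and `spike_rejected`.
#' @export
find_upper_boundary <- function(profile, threshold,
                                id_max = find_peak(profile)) {
  validate_z_profile(profile)
  n <- length(profile$z)
  flipped <- profile$orientation == "electrode_high_z"
  im <- if (flipped) n + 1L - id_max else id_max
  res <- upper_boundary_idx(oriented_intensity(profile), threshold, im)
  if (flipped && res$found) res$index <- n + 1L - res$index
  res
}

#' Biofilm thickness of one ROI profile
#'
#' Runs the full per-ROI pipeline: locate the intensity maximum, estimate
#' the background mean separately on the electrode and the buffer side,
#' form the side-specific thresholds (`multiplier` x mean background),
#' locate both boundaries and report the thickness as the z-distance
#' between them. If either boundary cannot be found the thickness is
#' missing (`NA`), never zero, and the result is flagged `no_signal`.
#'
#' @param profile A [z_profile()].
#' @param config A [threshold_config()].
#' @return A one-row [tibble::tibble()] with columns `image_id`, `roi_id`,
#'   `thickness_um`, `lower_z`, `upper_z`, `lower_idx`, `upper_idx`,
#'   `id_max`, `threshold_left`, `threshold_right`, `bg_electrode`,
#'   `bg_buffer`, `lower_found`, `upper_found` and `flags`
#'   (comma-separated subset of `no_signal`, `saturated`, `spike_rejected`,
#'   `boundary_at_edge`). `lower_*` refers to the smaller-z boundary.
#' @examples
#' p <- z_profile(0:6, c(1, 1, 8, 9, 8, 1, 1))
#' roi_thickness(p, threshold_config(background_window_fraction = 2 / 7))
#' @export
roi_thickness <- function(profile, config = threshold_config()) {
  validate_z_profile(profile)
  gmax <- find_peak(profile)
  bg_e <- estimate_background(profile, "electrode", gmax, config)
  bg_b <- estimate_background(profile, "buffer", gmax, config)
  thr_left <- config$multiplier * bg_e$mean_intensity
  thr_right <- config$multiplier * bg_b$mean_intensity
  id_max <- if (config$peak_anchor == "longest_run") {
    n <- length(profile$z)
    a <- film_anchor_idx(oriented_intensity(profile), thr_right)
    if (profile$orientation == "electrode_high_z") n + 1L - a else a
  } else {
    gmax
  }
  lo <- find_lower_boundary(profile, thr_left, id_max,
                            contiguous = config$require_contiguity_below)
  up <- find_upper_boundary(profile, thr_right, id_max)

  flags <- character(0)
  if (!is.na(config$saturation_level) &&
      max(profile$intensity) >= config$saturation_level) {
    flags <- c(flags, "saturated")
  }
  if (isTRUE(up$spike_rejected)) flags <- c(flags, "spike_rejected")
  if (isTRUE(lo$at_edge) || isTRUE(up$at_edge)) {
    flags <- c(flags, "boundary_at_edge")
  }

  thickness <- NA_real_
  lower_z <- upper_z <- NA_real_
  lower_idx <- upper_idx <- NA_integer_
  if (lo$found && up$found) {
    za <- profile$z[lo$index]
    zb <- profile$z[up$index]
    thickness <- abs(zb - za)
    lower_z <- min(za, zb)
    upper_z <- max(za, zb)
    lower_idx <- min(lo$index, up$index)
    upper_idx <- max(lo$index, up$index)
  } else {
    flags <- c(flags, "no_signal")
  }

  tibble::tibble(
    image_id = profile$image_id,
    roi_id = profile$roi_id,
    thickness_um = thickness,
    lower_z = lower_z,
    upper_z = upper_z,
    lower_idx = lower_idx,
    upper_idx = upper_idx,
    id_max = id_max,
    threshold_left = thr_left,
    threshold_right = thr_right,
    bg_electrode = bg_e$mean_intensity,
    bg_buffer = bg_b$mean_intensity,
    lower_found = lo$found,
    upper_found = up$found,
    flags = paste(flags, collapse = ",")
  )
}

#' Biofilm thickness for every profile of a set
#'
#' Applies [roi_thickness()] to each profile of a [profile_set()] and binds
#' the per-ROI rows into one tidy table.
#'
#' @param profiles A [profile_set()] or a list of [z_profile()] objects.
#' @param config A [threshold_config()].
#' @return A [tibble::tibble()] with one row per ROI; see [roi_thickness()].
#' @export
compute_thickness <- function(profiles, config = threshold_config()) {
  if (inherits(profiles, "profile_set")) profiles <- profiles$profiles
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  dplyr::bind_rows(lapply(profiles, roi_thickness, config = config))
}

#' Test whether results carry a given flag
#'
#' @param results Tibble from [roi_thickness()] / [compute_thickness()].
#' @param flag One of `"no_signal"`, `"saturated"`, `"spike_rejected"`,
#'   `"boundary_at_edge"`.
#' @return Logical vector, one element per result row.
#' @export
has_flag <- function(results, flag) {
  vapply(strsplit(results$flags, ",", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}
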
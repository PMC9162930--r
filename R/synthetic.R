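# Synthetic profiles and sections with known ground truth.
#
# The signal model mirrors what the thresholding algorithm has to cope
# with on real data: a biofilm slab of roughly constant intensity sitting
# on a dim electrode background, a different (usually brighter) buffer
# background above it, Gaussian detector noise, and isolated bright
# "planktonic" spikes above the slab that must not extend the detected
# biofilm end.

#' Ground truth for a synthetic profile
#'
#' @param z0_um,z1_um True biofilm boundaries in micrometres
#'   (`0 <= z0 < z1 <= max z`). Defaults give a 30 um film starting at
#'   10 um, within the 20-40 um thickness range typical of electroactive
#'   anode biofilms.
#' @param amplitude Biofilm intensity in detector units.
#' @param bg_electrode,bg_buffer Background means below and above the film.
#'   Both must stay below `amplitude / 3` so that the default threshold can
#'   separate film from background.
#' @param noise_sd Gaussian noise SD (additive, clipped at zero).
#' @param spikes List of planktonic spikes, each
#'   `list(z_um =, amplitude =, width_um =)`, entirely on the buffer side
#'   and separated from the slab by at least one background-only sample.
#' @param n_samples Profile length; with `z_step_um` this sets the imaged
#'   depth range (default 161 samples of 0.5 um = 0..80 um).
#' @param z_step_um Sampling interval in micrometres.
#' @param seed Integer RNG seed; all randomness is derived from it.
#' @return An object of class `synthetic_truth`; field `thickness_um`
#'   holds the true thickness `z1_um - z0_um`.
#' @export
synthetic_truth <- function(z0_um = 10, z1_um = 40, amplitude = 100,
                            bg_electrode = 5, bg_buffer = 8,
                            noise_sd = 0, spikes = list(),
                            n_samples = 161L, z_step_um = 0.5,
                            seed = 1L) {
  t <- structure(
    list(z0_um = z0_um, z1_um = z1_um, amplitude = amplitude,
         bg_electrode = bg_electrode, bg_buffer = bg_buffer,
         noise_sd = noise_sd, spikes = spikes,
         n_samples = as.integer(n_samples), z_step_um = z_step_um,
         seed = as.integer(seed), thickness_um = z1_um - z0_um),
    class = "synthetic_truth"
  )
  validate_synthetic_truth(t)
}

validate_synthetic_truth <- function(t) {
  stopifnot(inherits(t, "synthetic_truth"))
  z_max <- (t$n_samples - 1L) * t$z_step_um
  if (t$z0_um < 0 || t$z1_um <= t$z0_um || t$z1_um > z_max) {
    stop("need 0 <= z0 < z1 <= ", z_max, " um", call. = FALSE)
  }
  if (t$amplitude <= 0 || t$bg_electrode < 0 || t$bg_buffer < 0) {
    stop("amplitude must be > 0 and backgrounds >= 0", call. = FALSE)
  }
  if (max(t$bg_electrode, t$bg_buffer) >= t$amplitude / 3) {
    stop("backgrounds must stay below amplitude / 3 for the film to be ",
         "separable at the default threshold", call. = FALSE)
  }
  if (t$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (s in t$spikes) {
    if (!all(c("z_um", "amplitude", "width_um") %in% names(s))) {
      stop("each spike needs z_um, amplitude and width_um", call. = FALSE)
    }
    if (s$z_um <= t$z1_um + t$z_step_um) {
      stop("spike at z = ", s$z_um, " um is not separated from the slab ",
           "(needs center > z1 + one z-step)", call. = FALSE)
    }
    gap_ok <- any_gap_sample(t, s)
    if (!gap_ok) {
      stop("spike at z = ", s$z_um,
           " um leaves no background-only sample between slab and spike",
           call. = FALSE)
    }
  }
  t
}

# at least one grid sample strictly between slab end and spike support
any_gap_sample <- function(t, s) {
  z <- (seq_len(t$n_samples) - 1L) * t$z_step_um
  any(z > t$z1_um & z < s$z_um - s$width_um / 2)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> film %g..%g um (%g um thick), ",
                     "amplitude %g, bg %g/%g, noise sd %g, %d spike(s), ",
                     "%d samples @ %g um, seed %d\n"),
              x$z0_um, x$z1_um, x$thickness_um, x$amplitude,
              x$bg_electrode, x$bg_buffer, x$noise_sd, length(x$spikes),
              x$n_samples, x$z_step_um, x$seed))
  invisible(x)
}

# evaluate noiseless signal on a z grid for given boundaries
signal_on_grid <- function(z, z0, z1, amplitude, bg_e, bg_b, spikes) {
  base <- ifelse(z < z0, bg_e, ifelse(z <= z1, amplitude, bg_b))
  for (s in spikes) {
    hit <- abs(z - s$z_um) <= s$width_um / 2
    base[hit] <- base[hit] + s$amplitude
  }
  base
}

# run code with a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one ROI profile from ground truth
#'
#' Evaluates the piecewise-constant signal model on the z grid —
#' electrode background below `z0_um`, film amplitude between the
#' boundaries, buffer background above `z1_um`, plus any spike bumps —
#' adds Gaussian noise and clips at zero. Deterministic for a fixed
#' `truth$seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param roi_id,image_id Labels for the generated profile.
#' @return A list with elements `profile` (a [z_profile()]) and `truth`.
#' @export
simulate_profile <- function(truth, roi_id = 1L, image_id = "synthetic") {
  validate_synthetic_truth(truth)
  z <- (seq_len(truth$n_samples) - 1L) * truth$z_step_um
  base <- signal_on_grid(z, truth$z0_um, truth$z1_um, truth$amplitude,
                         truth$bg_electrode, truth$bg_buffer, truth$spikes)
  int <- if (truth$noise_sd > 0) {
    with_seed(truth$seed,
              pmax(0, base + stats::rnorm(length(base), 0, truth$noise_sd)))
  } else {
    base
  }
  list(profile = z_profile(z, int, roi_id = roi_id, image_id = image_id,
                           orientation = "electrode_low_z"),
       truth = truth)
}

#' Simulate an xz-section image from ground truth
#'
#' Builds a section of `width_px` columns, each an independent realization
#' of the profile model. Boundaries can vary laterally via `z0_fun` /
#' `z1_fun` (functions of the column's x position in micrometres) to
#' emulate position-dependent coverage; by default the slab is flat. The
#' default width of 185 um matches the standard acquisition geometry.
#'
#' @param truth A [synthetic_truth()]; its `seed` drives all columns.
#' @param width_px Number of columns (>= n_roi downstream).
#' @param width_um Physical image width in micrometres.
#' @param z0_fun,z1_fun Optional `function(x_um)` returning the boundary
#'   for a column at lateral position `x_um`; default constant truth
#'   boundaries.
#' @param image_id Identifier of the generated section.
#' @return A [section_image()] with attribute `truth_by_column`, a tibble
#'   of per-column true boundaries.
#' @export
simulate_stack <- function(truth, width_px = 100L, width_um = 185,
                           z0_fun = NULL, z1_fun = NULL,
                           image_id = "synthetic_stack") {
  validate_synthetic_truth(truth)
  width_px <- as.integer(width_px)
  stopifnot(width_px >= 1L, width_um > 0)
  px_x <- width_um / width_px
  x <- (seq_len(width_px) - 0.5) * px_x
  z <- (seq_len(truth$n_samples) - 1L) * truth$z_step_um
  z0 <- if (is.null(z0_fun)) rep(truth$z0_um, width_px) else
    vapply(x, z0_fun, numeric(1))
  z1 <- if (is.null(z1_fun)) rep(truth$z1_um, width_px) else
    vapply(x, z1_fun, numeric(1))
  z_max <- (truth$n_samples - 1L) * truth$z_step_um
  if (any(z0 < 0 | z1 <= z0 | z1 > z_max)) {
    stop("lateral boundary profile violates 0 <= z0 < z1 <= ", z_max,
         call. = FALSE)
  }
  pixels <- matrix(0, nrow = truth$n_samples, ncol = width_px)
  for (j in seq_len(width_px)) {
    pixels[, j] <- signal_on_grid(z, z0[j], z1[j], truth$amplitude,
                                  truth$bg_electrode, truth$bg_buffer,
                                  truth$spikes)
  }
  if (truth$noise_sd > 0) {
    pixels <- with_seed(truth$seed, {
      noisy <- pmax(0, pixels + stats::rnorm(length(pixels), 0,
                                             truth$noise_sd))
      matrix(noisy, nrow = nrow(pixels), ncol = ncol(pixels))
    })
  }
  img <- section_image(pixels, pixel_size_x_um = px_x,
                       pixel_size_z_um = truth$z_step_um,
                       image_id = image_id)
  attr(img, "truth_by_column") <- tibble::tibble(x_um = x, z0_um = z0,
                                                 z1_um = z1)
  img
}

#' Thickness-recovery experiment on synthetic profiles
#'
#' Samples `n` ground truths with boundaries drawn uniformly from the
#' given ranges, runs the full per-ROI pipeline on each simulated profile
#' and compares estimated with true thickness.
#'
#' Boundaries are snapped to the sampling grid: the ground truth of a
#' discretely sampled profile is defined at acquisition resolution, as in
#' a rasterized image where the film occupies whole pixels. Noise-free
#' recovery is therefore exact, and any error measures the effect of
#' noise, not of sub-pixel truth placement.
#'
#' @param n Number of profiles (>= 1).
#' @param thickness_range True thickness range in micrometres.
#' @param z0_range Range of the lower boundary in micrometres. Must leave
#'   the background estimation windows clear of the film.
#' @param noise_sd,amplitude,bg_electrode,bg_buffer,n_samples,z_step_um
#'   Forwarded to [synthetic_truth()].
#' @param spikes_per_profile Number of planktonic spikes added to each
#'   profile (amplitudes up to 3x the film amplitude, placed with at least
#'   one background sample of separation from the slab).
#' @param config [threshold_config()] used for estimation.
#' @param seed Integer seed for the experiment.
#' @return An object of class `recovery_experiment`: list with `results`
#'   (tibble of `true_um`, `estimated_um`, `error_um`), `bias_um`,
#'   `mae_um`, `mare` (mean absolute relative error), and
#'   `frac_within_step` (fraction with |error| <= one z-step).
#' @export
recovery_experiment <- function(n = 100L,
                                thickness_range = c(20, 40),
                                z0_range = c(9, 15),
                                noise_sd = 0, amplitude = 100,
                                bg_electrode = 5, bg_buffer = 8,
                                n_samples = 161L, z_step_um = 0.5,
                                spikes_per_profile = 0L,
                                config = threshold_config(),
                                seed = 1L) {
  stopifnot(n >= 1L)
  # independent sub-seed per profile: the geometry draws of profile i are
  # unaffected by how many spike parameters were drawn for profile i - 1
  sub_seeds <- with_seed(seed, sample.int(2147483646L, n))
  z_max <- (n_samples - 1L) * z_step_um
  snap <- function(v) round(v / z_step_um) * z_step_um
  truths <- lapply(seq_len(n), function(i) {
    with_seed(sub_seeds[i], {
      th <- snap(stats::runif(1, thickness_range[1], thickness_range[2]))
      z0 <- snap(stats::runif(1, z0_range[1], z0_range[2]))
      z1 <- min(z0 + max(th, z_step_um), snap(z_max))
      spikes <- make_spikes(spikes_per_profile, z1, z_max, z_step_um,
                            amplitude)
      synthetic_truth(z0_um = z0, z1_um = z1, amplitude = amplitude,
                      bg_electrode = bg_electrode, bg_buffer = bg_buffer,
                      noise_sd = noise_sd, spikes = spikes,
                      n_samples = n_samples, z_step_um = z_step_um,
                      seed = sub_seeds[i])
    })
  })
  rows <- lapply(seq_along(truths), function(i) {
    sim <- simulate_profile(truths[[i]], roi_id = 1L,
                            image_id = sprintf("sim%03d", i))
    est <- roi_thickness(sim$profile, config)
    tibble::tibble(true_um = truths[[i]]$thickness_um,
                   estimated_um = est$thickness_um)
  })
  res <- dplyr::bind_rows(rows)
  res$error_um <- res$estimated_um - res$true_um
  err <- res$error_um[!is.na(res$error_um)]
  structure(
    list(results = res,
         bias_um = mean(err),
         mae_um = mean(abs(err)),
         mare = mean(abs(err) / res$true_um[!is.na(res$error_um)]),
         frac_within_step = mean(!is.na(res$error_um) &
                                   abs(res$error_um) <= z_step_um)),
    class = "recovery_experiment"
  )
}

# Random planktonic spikes above the slab, guaranteed to leave >= 1
# background-only grid sample between slab and spike support. Spikes are
# placed below the outer 15% of the depth range: floating cells sit just
# above the film, and the outermost samples are the buffer-background
# estimation window.
make_spikes <- function(k, z1, z_max, z_step, amplitude) {
  if (k < 1L) return(list())
  lo <- z1 + 3 * z_step
  hi <- 0.85 * z_max
  if (hi <= lo) return(list())
  lapply(seq_len(k), function(i) {
    width <- z_step * stats::runif(1, 0.5, 2)
    center <- stats::runif(1, lo + width / 2, max(lo + width / 2, hi))
    list(z_um = center, amplitude = amplitude * stats::runif(1, 0.5, 3),
         width_um = width)
  })
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf(paste0("<recovery_experiment> n = %d: bias %.3f um, ",
                     "MAE %.3f um, MARE %.2f%%, %.1f%% within one z-step\n"),
              nrow(x$results), x$bias_um, x$mae_um, 100 * x$mare,
              100 * x$frac_within_step))
  invisible(x)
}

#' Write a profile set as a wide-layout CSV
#'
#' Companion to the simulator: writes profiles of one image in the wide
#' export layout (`z` column plus one `ROI<i>` column each) so generated
#' data can exercise the reader path.
#'
#' @param profiles A [profile_set()] whose profiles share one image.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "profile_set"))
  ps <- profiles$profiles
  ids <- unique(vapply(ps, function(p) p$image_id, character(1)))
  if (length(ids) != 1L) {
    stop("write_profiles() writes one image per file; got ", length(ids),
         call. = FALSE)
  }
  df <- data.frame(z = ps[[1]]$z)
  for (p in ps) df[[paste0("ROI", p$roi_id)]] <- p$intensity
  write_full_precision_csv(df, path)
  invisible(path)
}
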
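# Boundary detection: peak finding, per-side background, boundary scans,
# thickness, and the algorithm's invariants.

test_that("find_peak returns the first maximum", {
  expect_equal(find_peak(zp(c(1, 5, 9, 5, 1))), 3)
  expect_equal(find_peak(zp(c(1, 9, 9, 1))), 2)   # tie -> smallest index
  expect_equal(find_peak(zp(c(3, 3, 3))), 1)      # constant -> first
})

test_that("background mean is taken from the outer window of each side", {
  p <- zp(c(2, 2, 10, 10, 4, 4))
  cfg <- threshold_config(background_window_fraction = 1 / 3)
  e <- estimate_background(p, "electrode", config = cfg)
  b <- estimate_background(p, "buffer", config = cfg)
  expect_equal(e$mean_intensity, 2)
  expect_equal(b$mean_intensity, 4)
  expect_equal(e$n_samples, 2)
  u <- zp(rep(7, 6))
  expect_equal(estimate_background(u, "electrode", config = cfg)$mean_intensity, 7)
  expect_equal(estimate_background(u, "buffer", config = cfg)$mean_intensity, 7)
})

test_that("background window shrinks rather than swallowing the peak", {
  p <- zp(c(9, 1, 1, 1, 1, 1, 1, 1, 1, 1))  # peak at the electrode edge
  cfg <- threshold_config(background_window_fraction = 0.5)
  e <- estimate_background(p, "electrode", id_max = 1, config = cfg)
  expect_equal(e$n_samples, 1)  # cannot avoid the edge; one sample minimum
})

test_that("lower boundary is the first exceedance from the electrode edge", {
  lo <- find_lower_boundary(zp(c(1, 1, 4, 9, 9)), 3, id_max = 4)
  expect_equal(lo$index, 3)
  expect_true(lo$found)
  expect_false(lo$at_edge)
  edge <- find_lower_boundary(zp(c(9, 9, 9)), 3, id_max = 1)
  expect_equal(edge$index, 1)
  expect_true(edge$at_edge)
  none <- find_lower_boundary(zp(c(1, 1, 1)), 3, id_max = 1)
  expect_false(none$found)
  expect_true(is.na(none$index))
})

test_that("upper boundary ends the run containing the peak and rejects spikes", {
  up <- find_upper_boundary(zp(c(1, 9, 9, 9, 1, 5, 1)), 3, id_max = 2)
  expect_equal(up$index, 4)       # the 5 beyond the gap is planktonic
  expect_true(up$spike_rejected)
  expect_false(up$at_edge)
  run_to_edge <- find_upper_boundary(zp(c(1, 9, 9)), 3, id_max = 2)
  expect_equal(run_to_edge$index, 3)
  expect_true(run_to_edge$at_edge)
  single <- find_upper_boundary(zp(c(1, 9, 1)), 3, id_max = 2)
  expect_equal(single$index, 2)   # single-sample biofilm
  expect_false(single$spike_rejected)
})

test_that("roi_thickness reproduces the full hand trace", {
  p <- zp(c(1, 1, 8, 9, 8, 1, 1))  # z = 0..6 um
  res <- roi_thickness(p, threshold_config(background_window_fraction = 2 / 7))
  expect_equal(res$bg_electrode, 1)
  expect_equal(res$bg_buffer, 1)
  expect_equal(res$threshold_left, 3)
  expect_equal(res$threshold_right, 3)
  expect_equal(res$lower_idx, 3)
  expect_equal(res$upper_idx, 5)
  expect_equal(res$lower_z, 2)
  expect_equal(res$upper_z, 4)
  expect_equal(res$thickness_um, 2)
  expect_equal(res$flags, "")
})

test_that("flat profiles yield missing thickness flagged no_signal", {
  res <- roi_thickness(zp(rep(4, 9)))
  expect_true(is.na(res$thickness_um))
  expect_true(has_flag(res, "no_signal"))
  zero <- roi_thickness(zp(rep(0, 9)))
  expect_true(is.na(zero$thickness_um))
})

test_that("boundaries are scale-equivariant in overall intensity", {
  tr <- synthetic_truth(noise_sd = 4, spikes = list(
    list(z_um = 60, amplitude = 150, width_um = 1)), seed = 5)
  p <- simulate_profile(tr)$profile
  for (c_mult in c(0.25, 10, 1000)) {
    scaled <- z_profile(p$z, p$intensity * c_mult)
    a <- roi_thickness(p)
    b <- roi_thickness(scaled)
    expect_identical(b$lower_idx, a$lower_idx)
    expect_identical(b$upper_idx, a$upper_idx)
    expect_identical(b$thickness_um, a$thickness_um)
  }
})

test_that("raising the multiplier never increases thickness", {
  set.seed(42)
  for (i in 1:20) {
    tr <- synthetic_truth(z0_um = 10 + i / 5, z1_um = 30 + i, noise_sd = 6,
                          seed = 100 + i)
    p <- simulate_profile(tr)$profile
    ths <- vapply(c(1.5, 2, 2.5, 3, 4, 5), function(m) {
      t <- roi_thickness(p, threshold_config(multiplier = m))$thickness_um
      if (is.na(t)) 0 else t
    }, numeric(1))
    expect_true(all(diff(ths) <= 1e-12))
  }
})

test_that("appending separated above-threshold samples never moves boundaries", {
  # at fixed threshold: anything beyond the first sub-threshold gap can
  # never extend the run containing the peak
  set.seed(7)
  for (i in 1:20) {
    tr <- synthetic_truth(noise_sd = 3, seed = 200 + i)
    p <- simulate_profile(tr)$profile
    thr <- 3 * mean(utils::tail(p$intensity, 16))
    id_max <- find_peak(p)
    base <- find_upper_boundary(p, thr, id_max)
    z2 <- c(p$z, max(p$z) + c(0.5, 1, 1.5))
    i2 <- c(p$intensity, 0, 400, 400)
    spiked <- find_upper_boundary(z_profile(z2, i2), thr, id_max)
    expect_identical(spiked$index, base$index)
    expect_true(spiked$spike_rejected)
  }
})

test_that("thickness never exceeds the z-range and is non-negative", {
  set.seed(9)
  for (i in 1:30) {
    int <- sample(c(0, 1, 4, 9), 15, replace = TRUE)
    res <- roi_thickness(zp(int))
    if (!is.na(res$thickness_um)) {
      expect_gte(res$thickness_um, 0)
      expect_lte(res$thickness_um, 14)
    }
  }
})

test_that("orientation flip leaves thickness unchanged", {
  tr <- synthetic_truth(noise_sd = 4, seed = 31)
  p <- simulate_profile(tr)$profile
  flipped <- z_profile(p$z, rev(p$intensity),
                       orientation = "electrode_high_z")
  a <- roi_thickness(p)
  b <- roi_thickness(flipped)
  expect_equal(b$thickness_um, a$thickness_um)
  # boundary z positions mirror around the z mid-point
  expect_equal(b$upper_z, max(p$z) - a$lower_z)
  expect_equal(b$lower_z, max(p$z) - a$upper_z)
})

test_that("contiguous lower-boundary mode skips isolated bright pixels", {
  # isolated hot pixel near the electrode ahead of the film
  int <- c(1, 8, 1, 1, 9, 9, 9, 1, 1, 1)
  p <- zp(int)
  first <- find_lower_boundary(p, 3, id_max = 5)
  run <- find_lower_boundary(p, 3, id_max = 5, contiguous = TRUE)
  expect_equal(first$index, 2)
  expect_equal(run$index, 5)
  cfg <- threshold_config(require_contiguity_below = TRUE,
                          background_window_fraction = 0.1)
  expect_equal(roi_thickness(p, cfg)$lower_z, 4)
})

test_that("iterative background refinement converges and stays side-specific", {
  tr <- synthetic_truth(noise_sd = 2, seed = 77)
  p <- simulate_profile(tr)$profile
  cfg <- threshold_config(iterative_background = TRUE)
  e <- estimate_background(p, "electrode", config = cfg)
  b <- estimate_background(p, "buffer", config = cfg)
  expect_lt(e$mean_intensity, 100 / 3)
  expect_lt(b$mean_intensity, 100 / 3)
  res <- roi_thickness(p, cfg)
  expect_lt(abs(res$thickness_um - tr$thickness_um), 0.51)
})

test_that("saturation flag fires only at the configured level", {
  p <- zp(c(1, 1, 255, 255, 1, 1))
  cfg <- threshold_config(saturation_level = 255,
                          background_window_fraction = 1 / 3)
  expect_true(has_flag(roi_thickness(p, cfg), "saturated"))
  expect_false(has_flag(roi_thickness(p), "saturated"))
})
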
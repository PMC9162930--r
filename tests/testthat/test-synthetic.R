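# Generator with ground truth: determinism, validation, recovery.

test_that("noiseless profiles recover the true thickness exactly", {
  tr <- synthetic_truth(z0_um = 10, z1_um = 40, z_step_um = 1,
                        n_samples = 81L, noise_sd = 0)
  sim <- simulate_profile(tr)
  res <- roi_thickness(sim$profile)
  expect_equal(res$thickness_um, 30)
  expect_equal(res$lower_z, 10)
  expect_equal(res$upper_z, 40)
})

test_that("a separated spike leaves the estimate unchanged and is flagged", {
  base <- synthetic_truth(z0_um = 10, z1_um = 40, z_step_um = 1,
                          n_samples = 81L)
  spiked <- synthetic_truth(z0_um = 10, z1_um = 40, z_step_um = 1,
                            n_samples = 81L,
                            spikes = list(list(z_um = 50, amplitude = 200,
                                               width_um = 2)))
  a <- roi_thickness(simulate_profile(base)$profile)
  b <- roi_thickness(simulate_profile(spiked)$profile)
  expect_identical(b$thickness_um, a$thickness_um)
  expect_identical(b$upper_z, a$upper_z)
  expect_true(has_flag(b, "spike_rejected"))
})

test_that("generation is deterministic for a fixed seed", {
  tr <- synthetic_truth(noise_sd = 5, seed = 42)
  p1 <- simulate_profile(tr)$profile
  p2 <- simulate_profile(tr)$profile
  expect_identical(p1$intensity, p2$intensity)
  p3 <- simulate_profile(synthetic_truth(noise_sd = 5, seed = 43))$profile
  expect_false(identical(p1$intensity, p3$intensity))

  s1 <- simulate_stack(tr, width_px = 20)
  s2 <- simulate_stack(tr, width_px = 20)
  expect_identical(s1$pixels, s2$pixels)
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(simulate_profile(synthetic_truth(noise_sd = 5, seed = 9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("inconsistent truths are refused", {
  expect_error(synthetic_truth(z0_um = 40, z1_um = 10), "z0 < z1")
  expect_error(synthetic_truth(z1_um = 1000), "z0 < z1")
  expect_error(synthetic_truth(bg_buffer = 50), "amplitude / 3")
  # spike touching the slab: no background sample between them
  expect_error(
    synthetic_truth(z1_um = 40, spikes = list(list(z_um = 40.4,
                                                   amplitude = 100,
                                                   width_um = 1))),
    "not separated")
})

test_that("flat slab stacks give ten equal ROI thicknesses", {
  tr <- synthetic_truth(z0_um = 10, z1_um = 35, noise_sd = 0)
  res <- compute_thickness(extract_profiles(simulate_stack(tr, 50),
                                            n_roi = 10))
  expect_equal(unique(res$thickness_um), 25)
})

test_that("a lateral thickness ramp gives monotone ROI thickness", {
  tr <- synthetic_truth(z0_um = 10, z1_um = 20, noise_sd = 0)
  img <- simulate_stack(tr, width_px = 100, width_um = 185,
                        z1_fun = function(x) 20 + 40 * x / 185)
  res <- compute_thickness(extract_profiles(img, n_roi = 10))
  expect_true(all(diff(res$thickness_um) >= 0))
  expect_gt(res$thickness_um[10], res$thickness_um[1] + 20)
})

test_that("recovery experiments report MAE, bias and the within-step fraction", {
  one <- recovery_experiment(n = 1, seed = 3)
  expect_equal(nrow(one$results), 1)

  clean <- recovery_experiment(n = 40, noise_sd = 0, seed = 5)
  expect_equal(clean$frac_within_step, 1)
  expect_lte(clean$mae_um, 0.5)
  expect_equal(clean$bias_um, 0)

  noisy <- recovery_experiment(n = 60, noise_sd = 5, seed = 5)
  expect_lt(noisy$mare, 0.07)
  # deterministic for the seed; frozen from the first run of this
  # configuration
  expect_equal(noisy$mae_um, 1.6583333333, tolerance = 1e-8)
})

test_that("spiked recovery runs match their spike-free twins estimate-for-estimate", {
  for (k in 1:2) {
    plain <- recovery_experiment(n = 30, noise_sd = 0, seed = 11,
                                 spikes_per_profile = 0L)
    spiked <- recovery_experiment(n = 30, noise_sd = 0, seed = 11,
                                  spikes_per_profile = k)
    expect_identical(plain$results$true_um, spiked$results$true_um)
    expect_identical(plain$results$estimated_um, spiked$results$estimated_um)
  }
})
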
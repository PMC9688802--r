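test_that("noiseless spot hits the model response exactly on the true mask", {
  m <- response_model()
  for (conc in c(0.5, 1, 5, 20)) {
    sim <- simulate_spot(m, quiet_scene(), conc)
    got <- mean(rgb_to_gray(extract_roi_pixels(sim$image, sim$truth$true_mask))[, "response"])
    expect_equal(got, evaluate_response(m, conc), tolerance = 0.5 / 60,
                 label = sprintf("mean response at %g mM", conc))
  }
})

test_that("radial development profile is mean-preserving over the true mask", {
  m <- response_model()
  sc <- quiet_scene(); sc$radial_amplitude <- 0.08
  sim <- simulate_spot(m, sc, 5)
  got <- mean(rgb_to_gray(extract_roi_pixels(sim$image, sim$truth$true_mask))[, "response"])
  expect_equal(got, evaluate_response(m, 5), tolerance = 0.5 / 100)
})

test_that("identical seed and parameters give bit-identical images", {
  m <- response_model()
  s1 <- simulate_spot(m, noisy_scene(seed = 42L), 5)
  s2 <- simulate_spot(m, noisy_scene(seed = 42L), 5)
  expect_identical(s1$image, s2$image)
  s3 <- simulate_spot(m, noisy_scene(seed = 43L), 5)
  expect_false(identical(s1$image, s3$image))
})

test_that("noisy spot mean satisfies the CLT bound around the target", {
  m <- response_model()
  sc <- scene_params(image_size = c(128L, 128L), spot_radius = 57,
                     noise_sd = 4, radial_amplitude = 0, seed = 11L)
  sim <- simulate_spot(m, sc, 1)
  n <- sum(sim$truth$true_mask)
  expect_gt(n, 10000)
  got <- mean(rgb_to_gray(extract_roi_pixels(sim$image, sim$truth$true_mask))[, "response"])
  expect_lt(abs(got - 61.367), 3 * 4 / sqrt(n) + 0.05)  # 0.05 for [0,1] clipping
})

test_that("unattainable targets name the offending bound", {
  m <- response_model()
  expect_error(simulate_spot(m, quiet_scene(), 0.05), "below the paper background")
  pale <- quiet_scene(stain_rgb = c(0.97, 0.96, 0.93))
  expect_error(simulate_spot(m, pale, 5), "darker than paper")
})

test_that("dataset simulation counts rows and is seed-reproducible", {
  m <- response_model()
  sc <- noisy_scene()
  concs <- c(0.5, 1, 2, 5, 8, 11, 14, 17, 20)
  d1 <- simulate_dataset(m, sc, concs, replicates = 3, seed = 5L)
  expect_equal(nrow(d1$manifest), 27L)
  expect_equal(length(d1$images), 27L)
  # all mM-range targets inside the clamp bounds
  expect_true(all(vapply(d1$truths, `[[`, numeric(1), "target_response") > 0))
  expect_true(all(vapply(d1$truths, `[[`, numeric(1), "target_response") < 255))
  d2 <- simulate_dataset(m, sc, concs, replicates = 3, seed = 5L)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$images, d2$images)
  expect_error(simulate_dataset(m, sc, numeric(0)), "empty")
})

test_that("stability series decays linearly to the requested fraction", {
  m <- response_model()
  sc <- quiet_scene()
  days <- c(0L, 3L, 7L, 14L)
  s <- simulate_stability_series(m, sc, conc = 8, days = days,
                                 decay_fraction_at_end = 0.62, replicates = 1)
  tg <- s$manifest$target_response
  t0 <- evaluate_response(m, 8)
  expect_equal(tg[1], t0)
  expect_equal(tg[length(tg)], t0 * 0.38)
  expect_true(all(diff(tg) < 0))
  expect_true(all(tg[-c(1, length(tg))] < tg[1] & tg[-c(1, length(tg))] > tg[length(tg)]))

  s0 <- simulate_stability_series(m, sc, 8, days, decay_fraction_at_end = 0,
                                  replicates = 1)
  expect_true(all(abs(s0$manifest$target_response - t0) < 1e-9))
  expect_error(simulate_stability_series(m, sc, 8, c(3, 1)), "ascending")
  expect_error(simulate_stability_series(m, sc, 8, days, decay_fraction_at_end = 1),
               "decay_fraction")
})

test_that("rendered stability images match their decayed targets", {
  m <- response_model()
  s <- simulate_stability_series(m, quiet_scene(), conc = 8, days = c(0L, 7L, 14L),
                                 decay_fraction_at_end = 0.5, replicates = 1)
  for (i in seq_along(s$images)) {
    got <- mean(rgb_to_gray(extract_roi_pixels(s$images[[i]],
                                               s$truths[[i]]$true_mask))[, "response"])
    expect_equal(got, s$manifest$target_response[i], tolerance = 0.5 / 70)
  }
})

test_that("scene validation rejects bad geometry and noise", {
  expect_error(scene_params(image_size = c(64, 64), spot_radius = 40), "inside")
  expect_error(scene_params(noise_sd = -1), "noise_sd")
  expect_error(scene_params(illum_gradient = 0.7), "illum_gradient")
})
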
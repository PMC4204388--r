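test_that("generate_phantom builds one mask per layer, all disjoint, deterministically", {
  spec <- phantom_spec(64, 64, layer_tops = c(17, 33, 49),
                       layer_reflectivities = c(0.5, 1, 0.25),
                       wave_amplitude = 0, seed = 7L)
  scene <- generate_phantom(spec)
  expect_s3_class(scene, "phantom_scene")
  expect_length(scene$rois$regions, 3L)
  expect_true(all(scene$clean >= 0))
  # pairwise disjoint: background vs regions and region vs region
  masks <- c(list(scene$rois$background), scene$rois$regions)
  for (a in seq_along(masks)) for (b in seq_along(masks)) {
    if (a < b) expect_false(any(masks[[a]] & masks[[b]]))
  }
  # background mask sits in the zero-reflectivity band
  expect_true(all(scene$clean[scene$rois$background] == 0))
  expect_true(all(vapply(masks, sum, 0) >= 50))
  # identical seed + spec => bit-identical scenes
  expect_identical(scene, generate_phantom(spec))
  # a different seed moves the curved boundaries
  spec2 <- default_phantom_spec(seed = 1L)
  spec3 <- default_phantom_spec(seed = 2L)
  expect_false(identical(generate_phantom(spec2)$labels,
                         generate_phantom(spec3)$labels))
})

test_that("phantom spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(64, 64, c(20, 20, 40), c(1, 1, 1)),
               class = "nchr_invalid_spec")
  expect_error(phantom_spec(64, 64, c(40, 20), c(1, 1)),
               class = "nchr_invalid_spec")
  # background must be strictly darker than every layer
  expect_error(phantom_spec(64, 64, c(20, 40), c(0.5, 1),
                            background_reflectivity = 0.5),
               class = "nchr_invalid_spec")
  expect_error(phantom_spec(64, 64, c(20, 40), c(-0.1, 1)),
               class = "nchr_invalid_spec")
})

test_that("inclusions override layer reflectivity and are excluded from ROI masks", {
  spec <- phantom_spec(64, 64, layer_tops = c(17, 33, 49),
                       layer_reflectivities = c(0.5, 1, 0.25),
                       wave_amplitude = 0, seed = 1L,
                       inclusions = list(list(center = c(24, 32), radius = 3,
                                              reflectivity = 0.05)))
  scene <- generate_phantom(spec)
  expect_equal(scene$clean[24, 32], 0.05)
  expect_false(scene$rois$regions[[1]][24, 32])
})

test_that("speckle is multiplicative with unit mean intensity", {
  expect_identical(apply_speckle(matrix(0, 16, 16), seed = 3L),
                   matrix(0, 16, 16))
  clean <- matrix(1, 256, 256)
  sp <- apply_speckle(clean, seed = 11L)
  expect_true(all(sp >= 0))
  expect_gt(mean(sp^2), 0.95)   # Monte-Carlo bound, n = 65536
  expect_lt(mean(sp^2), 1.05)
  expect_identical(sp, apply_speckle(clean, seed = 11L))
  expect_false(identical(sp, apply_speckle(clean, seed = 12L)))
  expect_error(apply_speckle(matrix(-1, 4, 4)), class = "nchr_domain_error")
})

test_that("acquisition forward model is exact in the noiseless limit", {
  scene <- generate_phantom(small_phantom_spec(64, 64))
  acq <- acquisition_model(speed_factor = 1, base_noise_std = 0,
                           speckle = FALSE, seed = 5L)
  meas <- simulate_acquisition(scene, acq)
  expect_identical(meas$coefficients, forward_transform(scene$clean))
  expect_error(acquisition_model(speed_factor = 0.5),
               class = "nchr_invalid_model")
})

test_that("detector noise variance scales as speed_factor * base_noise_std^2", {
  scene <- generate_phantom(small_phantom_spec(64, 64))
  acq <- acquisition_model(speed_factor = 4, base_noise_std = 0.1,
                           speckle = FALSE, seed = 2L)
  meas <- simulate_acquisition(scene, acq)
  noise <- meas$coefficients - forward_transform(scene$clean)
  v <- mean(Mod(noise)^2)   # sample-variance oracle over 4096 coefficients
  expect_gt(v, 0.04 * 0.9)
  expect_lt(v, 0.04 * 1.1)

  # background image variance ratio ~ 8 between speed factors 8 and 1,
  # same speckle seed, averaged over 10 noise seeds
  ratios <- vapply(1:10, function(ns) {
    m8 <- simulate_acquisition(scene,
      acquisition_model(8, 0.05, speckle = TRUE, seed = 2L), noise_seed = ns)
    m1 <- simulate_acquisition(scene,
      acquisition_model(1, 0.05, speckle = TRUE, seed = 2L), noise_seed = ns)
    bg <- scene$rois$background
    var(naive_reconstruction(m8)[bg]) / var(naive_reconstruction(m1)[bg])
  }, 0)
  expect_gt(mean(ratios), 8 * 0.8)
  expect_lt(mean(ratios), 8 * 1.2)
})

test_that("naive-reconstruction SNR strictly decreases with acquisition speed", {
  scene <- generate_phantom(small_phantom_spec(64, 64))
  mean_snr <- vapply(c(1, 4, 8), function(speed) {
    mean(vapply(1:5, function(ns) {
      m <- simulate_acquisition(scene,
        acquisition_model(speed, 0.03, seed = 2L), noise_seed = ns)
      snr(naive_reconstruction(m), scene$rois)
    }, 0))
  }, 0)
  expect_true(all(diff(mean_snr) < 0))
})

test_that("speckle field and detector noise are independent", {
  scene <- generate_phantom(small_phantom_spec(64, 64))
  # noise realization is unchanged by toggling speckle
  m_on <- simulate_acquisition(scene,
    acquisition_model(4, 0.05, speckle = TRUE, seed = 9L), noise_seed = 33L)
  m_off <- simulate_acquisition(scene,
    acquisition_model(4, 0.05, speckle = FALSE, seed = 9L), noise_seed = 33L)
  speckled <- apply_speckle(scene$clean, seed = 9L)
  n_on <- m_on$coefficients - forward_transform(speckled)
  n_off <- m_off$coefficients - forward_transform(scene$clean)
  expect_equal(n_on, n_off, tolerance = 1e-12)
  # speckle realization is unchanged by disabling detector noise
  m_quiet <- simulate_acquisition(scene,
    acquisition_model(4, 0, speckle = TRUE, seed = 9L))
  expect_identical(m_quiet$coefficients, forward_transform(speckled))
})
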
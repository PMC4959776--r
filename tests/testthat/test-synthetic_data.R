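test_that("phantoms are seeded-deterministic and internally consistent", {
  sp <- phantom_spec(seed = 123)
  p1 <- generate_phantom(sp); p2 <- generate_phantom(sp)
  expect_identical(p1$image$junction_channel, p2$image$junction_channel)
  expect_identical(p1$image$reporter_channel, p2$image$reporter_channel)
  expect_identical(p1$truth$disc_mask$mask, p2$truth$disc_mask$mask)
  # ground truth: GFP region inside the disc, index near the target fraction
  set.seed(1)
  for (i in 1:8) {
    sp <- phantom_spec(disc_radius = runif(1, 50, 100),
                       boundary_irregularity = runif(1, 0, 0.2),
                       stripe_fraction = runif(1, 0.05, 0.9),
                       seed = 200 + i)
    ph <- generate_phantom(sp)
    expect_true(all(ph$truth$disc_mask$mask[ph$truth$gfp_mask$mask]))
    expect_lte(abs(ph$truth$true_index - sp$stripe_fraction), 0.02)
  }
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(image_size = c(128, 128), disc_radius = 70),
               "margin")
  expect_error(phantom_spec(boundary_irregularity = 0.3), "boundary_irregularity")
  expect_error(phantom_spec(stripe_fraction = 1.2), "stripe_fraction")
})

test_that("an empty stripe yields a dark reporter and a zero index", {
  sp <- phantom_spec(stripe_fraction = 0, noise_sd = 0, photon_scale = 0,
                     seed = 9)
  ph <- generate_phantom(sp)
  expect_identical(max(ph$image$reporter_channel), 0)
  expect_identical(recover_index(ph$image, canny_params(), threshold_spec(0.4)),
                   0)
})

test_that("recovered index increases with the stripe fraction", {
  idx <- vapply(c(0.1, 0.2, 0.3), function(f) {
    ph <- generate_phantom(phantom_spec(stripe_fraction = f, noise_sd = 0,
                                        photon_scale = 0, seed = 42))
    recover_index(ph$image, canny_params(), threshold_spec(0.4))
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
  expect_true(all(abs(idx - c(0.1, 0.2, 0.3)) < 0.02))
})

test_that("area recovery does not degrade across documented noise levels", {
  noise_levels <- c(0.02, 0.1, 0.2)
  curve <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:4, function(s) {
      ph <- generate_phantom(phantom_spec(image_size = c(128, 128),
                                          disc_radius = 45, noise_sd = ns,
                                          seed = 300 + s))
      abs(area_px(segment_disc(ph$image$junction_channel)) -
            area_px(ph$truth$disc_mask)) / area_px(ph$truth$disc_mask)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  # errors stay bounded and the low-noise end is never worse than the
  # high-noise end beyond sampling jitter
  expect_true(all(curve < 0.10))
  expect_lte(curve[1], curve[3] + 0.02)
})

test_that("experiment simulation is reproducible and validated", {
  groups <- data.frame(genotype = c("a", "b"),
                       mean_fraction = c(0.1, 0.25), sd_fraction = c(0.03, 0.03))
  expect_error(simulate_experiment(groups, n_per_group = 1, seed = 1),
               "at least 2")
  s1 <- simulate_experiment(groups, n_per_group = 2, seed = 5,
                            base_spec = sim_base_spec())
  s2 <- simulate_experiment(groups, n_per_group = 2, seed = 5,
                            base_spec = sim_base_spec())
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$images[[3]]$reporter_channel, s2$images[[3]]$reporter_channel)
  expect_equal(nrow(s1$truth), 4L)
  expect_true(all(s1$truth$stripe_fraction >= 0 & s1$truth$stripe_fraction <= 1))
  expect_true(all(s1$truth$seed < 2^31))
})

test_that("written experiments load back as a valid batch", {
  dir <- withr::local_tempdir()
  groups <- data.frame(genotype = c("ctrl", "mut"),
                       mean_fraction = c(0.15, 0.3), sd_fraction = c(0.02, 0.02))
  exp <- generate_experiment(groups, n_per_group = 2, dir = dir, seed = 31,
                             base_spec = sim_base_spec())
  man <- load_manifest(exp$manifest_path)
  expect_equal(nrow(man), 4L)
  # round trip: written TIFFs reload to the generated intensities
  sim <- simulate_experiment(groups, n_per_group = 2, seed = 31,
                             base_spec = sim_base_spec())
  img <- load_disc_image(c(junction = man$junction_path[1],
                           reporter = man$reporter_path[1]),
                         image_id = man$image_id[1])
  expect_lte(max(abs(img$junction_channel - sim$images[[1]]$junction_channel)),
             1 / 65535)
  res <- quantify_batch(man, canny_params(), threshold_spec(0.4))
  expect_true(all(res$status == "ok"))
  expect_true(all(abs(res$proliferation_index - exp$truth$true_index) < 0.03))
})
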
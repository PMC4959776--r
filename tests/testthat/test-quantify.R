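test_that("the proliferation index is exact mask arithmetic", {
  d <- matrix(FALSE, 100, 100); d[1:100, 1:100] <- TRUE
  g0 <- matrix(FALSE, 100, 100)
  expect_identical(proliferation_index(region_mask(g0), region_mask(d)), 0)
  expect_identical(proliferation_index(region_mask(d), region_mask(d)), 1)
  g <- matrix(FALSE, 100, 100); g[1:25, ] <- TRUE
  expect_identical(proliferation_index(region_mask(g), region_mask(d)), 0.25)
  expect_error(proliferation_index(region_mask(g), region_mask(g0))," zero")
})

test_that("the index is invariant under rotating both channels together", {
  ph <- generate_phantom(phantom_spec(seed = 17))
  spec <- threshold_spec(0.4)
  i1 <- recover_index(ph$image, canny_params(), spec)
  rot <- disc_image(rotate90(ph$image$junction_channel),
                    rotate90(ph$image$reporter_channel), "rot")
  i2 <- recover_index(rot, canny_params(), spec)
  expect_identical(i1, i2)
})

test_that("quantify_batch recovers known indices in manifest order", {
  dir <- withr::local_tempdir()
  fractions <- c(0.1, 0.2, 0.3)
  rows <- lapply(seq_along(fractions), function(i) {
    ph <- generate_phantom(phantom_spec(stripe_fraction = fractions[i],
                                        noise_sd = 0, photon_scale = 0,
                                        seed = 60 + i),
                           image_id = paste0("ph", i), genotype = "synthetic")
    jp <- file.path(dir, paste0("ph", i, "_j.tif"))
    rp <- file.path(dir, paste0("ph", i, "_r.tif"))
    write_channel_tiff(ph$image$junction_channel, jp)
    write_channel_tiff(ph$image$reporter_channel, rp)
    data.frame(image_id = paste0("ph", i), genotype = "synthetic",
               junction_path = jp, reporter_path = rp,
               true_index = ph$truth$true_index)
  })
  manifest <- do.call(rbind, rows)
  res <- quantify_batch(manifest, canny_params(), threshold_spec(0.4))
  expect_identical(res$image_id, manifest$image_id)
  expect_true(all(res$status == "ok"))
  expect_true(all(abs(res$proliferation_index - manifest$true_index) < 0.02))
  expect_true(all(res$gfp_area_px <= res$disc_area_px))
  expect_true(all(res$gfp_area_unrestricted_px >= res$gfp_area_px))

  # one unreadable file: an explicit failure row, never a dropped image
  bad <- manifest[, 1:4]
  bad <- rbind(bad, data.frame(image_id = "broken", genotype = "synthetic",
                               junction_path = file.path(dir, "nope.tif"),
                               reporter_path = file.path(dir, "nope.tif")))
  res2 <- quantify_batch(bad, canny_params(), threshold_spec(0.4))
  expect_equal(nrow(res2), 4L)
  expect_equal(sum(res2$status == "ok"), 3L)
  fail <- res2[res2$status == "failed", ]
  expect_equal(fail$image_id, "broken")
  expect_match(fail$reason, "nope.tif")

  # reruns with identical config are byte-identical
  f1 <- file.path(dir, "res1.csv"); f2 <- file.path(dir, "res2.csv")
  write_results_csv(res2, f1)
  write_results_csv(quantify_batch(bad, canny_params(), threshold_spec(0.4)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # a batch in which everything fails is an error
  allbad <- bad[4, ]
  expect_error(quantify_batch(allbad, canny_params(), threshold_spec(0.4)),
               "failed")
})

test_that("batch output records the threshold and a parameter fingerprint", {
  dir <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(seed = 64), image_id = "a")
  jp <- file.path(dir, "a_j.tif"); rp <- file.path(dir, "a_r.tif")
  write_channel_tiff(ph$image$junction_channel, jp)
  write_channel_tiff(ph$image$reporter_channel, rp)
  man <- data.frame(image_id = "a", genotype = "g", junction_path = jp,
                    reporter_path = rp)
  r1 <- quantify_batch(man, canny_params(), threshold_spec(0.4))
  r2 <- quantify_batch(man, canny_params(smoothing_sigma = 3), threshold_spec(0.4))
  expect_identical(r1$threshold_used, 0.4)
  expect_false(identical(r1$params_fingerprint, r2$params_fingerprint))
})
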
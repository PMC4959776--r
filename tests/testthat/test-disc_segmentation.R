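test_that("a constant image yields an empty edge map", {
  expect_equal(area_px(detect_edges(matrix(0.5, 64, 64))), 0L)
  expect_equal(area_px(detect_edges(matrix(0, 64, 64))), 0L)
})

test_that("edges of an ideal step-edge circle localize within 2 px", {
  n <- 160
  rowm <- matrix(seq_len(n), n, n); colm <- t(rowm)
  rho <- sqrt((rowm - 80.5)^2 + (colm - 80.5)^2)
  img <- (rho <= 60) * 1.0
  ed <- detect_edges(img, canny_params(smoothing_sigma = 2,
                                       low_threshold = 0.1, high_threshold = 0.3))
  px <- which(ed$mask, arr.ind = TRUE)
  expect_gt(nrow(px), 200)
  dev <- abs(sqrt((px[, 1] - 80.5)^2 + (px[, 2] - 80.5)^2) - 60)
  expect_lt(max(dev), 2)
})

test_that("edge detection is linear: halved intensities with halved thresholds", {
  set.seed(5)
  img <- matrix(runif(100 * 100), 100, 100)
  e1 <- detect_edges(img, canny_params(low_threshold = 0.05, high_threshold = 0.12))
  e2 <- detect_edges(img * 0.5,
                     canny_params(low_threshold = 0.025, high_threshold = 0.06))
  expect_identical(e1$mask, e2$mask)
})

test_that("a closed square outline fills to its full area", {
  m <- matrix(FALSE, 14, 14)
  m[3:12, c(3, 12)] <- TRUE; m[c(3, 12), 3:12] <- TRUE  # 10x10 outline
  filled <- close_and_fill(m, canny_params(closing_radius = 0))
  expect_equal(area_px(filled), 100L)
})

test_that("closing bridges outline gaps; without it the interior leaks", {
  n <- 40
  rowm <- matrix(seq_len(n), n, n); colm <- t(rowm)
  rho <- sqrt((rowm - 20.5)^2 + (colm - 20.5)^2)
  ring <- abs(rho - 12) < 0.7
  ring[19:21, colm[1, ] > 31] <- FALSE            # 3 px gap on the right
  closed <- close_and_fill(ring, canny_params(closing_radius = 2))
  leaked <- close_and_fill(ring, canny_params(closing_radius = 0))
  expect_gt(area_px(closed), pi * 12^2 * 0.8)     # interior filled
  expect_lt(area_px(leaked), sum(ring) * 2)       # interior escaped to border
})

test_that("fill equals the border flood-fill oracle on random masks", {
  set.seed(101)
  p0 <- canny_params(closing_radius = 0)
  for (i in 1:40) {
    m <- random_edge_mask(32, 32, runif(1, 0.1, 0.5))
    filled <- close_and_fill(m, p0)
    expect_identical(filled$mask, !flood_outside_oracle(m))
  }
})

test_that("fill output contains its input and refilling changes nothing", {
  set.seed(102)
  for (r in c(0L, 3L)) {
    pr <- canny_params(closing_radius = r)
    m <- random_edge_mask(48, 48, 0.25)
    f1 <- close_and_fill(m, pr)
    expect_true(all(f1$mask[m]))                  # superset of the edge mask
  }
  # fill alone is exactly idempotent
  p0 <- canny_params(closing_radius = 0)
  m <- random_edge_mask(48, 48, 0.3)
  f1 <- close_and_fill(m, p0)
  expect_identical(close_and_fill(f1, p0)$mask, f1$mask)
  # and on a realistic disc mask the full close-and-fill is too
  ph <- generate_phantom(phantom_spec(seed = 31))
  pd <- canny_params()
  e <- detect_edges(ph$image$junction_channel, pd)
  fd <- close_and_fill(e, pd)
  expect_identical(close_and_fill(fd, pd)$mask, fd$mask)
})

test_that("select_disc keeps the largest component and honours the size floor", {
  m <- matrix(FALSE, 100, 100)
  m[6:55, 1:100] <- TRUE         # 5000 px blob
  m[70:89, 10:49] <- TRUE        # 800 px blob
  sel <- select_disc(m, canny_params(min_area_fraction = 0.01))
  expect_equal(area_px(sel), 5000L)
  expect_error(select_disc(matrix(FALSE, 50, 50)), class = "wq_no_disc_error")
  # boundary component exactly at min_area_fraction is retained (>=)
  m2 <- matrix(FALSE, 100, 100); m2[1:20, 1:25] <- TRUE   # 500 px = 5%
  expect_equal(area_px(select_disc(m2, canny_params(min_area_fraction = 0.05))),
               500L)
  # the error carries the largest observed fraction for tuning
  err <- tryCatch(select_disc(m2, canny_params(min_area_fraction = 0.10)),
                  wq_no_disc_error = function(e) conditionMessage(e))
  expect_match(err, "0.05")
})

test_that("segment_disc recovers phantom disc areas and reports failures", {
  # noise-free phantom
  ph0 <- generate_phantom(phantom_spec(noise_sd = 0, photon_scale = 0, seed = 5))
  a0 <- area_px(segment_disc(ph0$image$junction_channel))
  expect_lt(abs(a0 - area_px(ph0$truth$disc_mask)) / area_px(ph0$truth$disc_mask),
            0.05)
  # noisy phantom at read-noise 0.05 (SNR about 5 for the interior signal)
  ph1 <- generate_phantom(phantom_spec(noise_sd = 0.05, seed = 6))
  a1 <- area_px(segment_disc(ph1$image$junction_channel))
  expect_lt(abs(a1 - area_px(ph1$truth$disc_mask)) / area_px(ph1$truth$disc_mask),
            0.05)
  # blank image
  expect_error(segment_disc(matrix(0.5, 128, 128)), class = "wq_no_disc_error")
})

test_that("segment_disc commutes with 90-degree rotation", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  a1 <- area_px(segment_disc(ph$image$junction_channel))
  a2 <- area_px(segment_disc(rotate90(ph$image$junction_channel)))
  expect_identical(a1, a2)
})
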
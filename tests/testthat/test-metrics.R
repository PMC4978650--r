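test_that("subtraction images are signed, antisymmetric and shape-checked", {
  a <- image_volume(matrix(runif(48), 6L, 8L))
  b <- image_volume(matrix(runif(48), 6L, 8L))
  expect_true(all(subtraction_image(a, a)$values == 0))
  expect_equal(subtraction_image(a, b)$values, -subtraction_image(b, a)$values)
  expect_error(subtraction_image(a, image_volume(matrix(0, 4L, 4L))), "shapes")
  expect_error(subtraction_image(a, image_volume(matrix(0, 6L, 8L),
                                                 pixel_spacing_mm = c(2, 2))),
               "spacing")
})

test_that("ROI statistics match hand computation and the enumeration oracle", {
  img <- matrix(0, 9L, 9L)
  img[4:6, 4:6] <- 1:9
  # pixel count of a fractional-radius circle vs the brute-force enumeration
  s <- roi_stats(img, roi_spec(c(5, 5), 1.9))
  expect_equal(s$n, circle_pixel_count_oracle(dim(img), 5, 5, 1.9))

  blk <- matrix(1:9, 3L, 3L)
  big <- matrix(0, 11L, 11L); big[5:7, 5:7] <- blk
  sb <- roi_stats(big, roi_spec(c(6, 6), 1.9))
  expect_equal(sb$n, 9L)
  expect_equal(sb$mean, 5)
  expect_equal(sb$sd, sqrt(sum((1:9 - 5)^2) / 8))

  expect_equal(roi_stats(matrix(3, 10L, 10L), roi_spec(c(5, 5), 2))$sd, 0)
  expect_error(roi_stats(big, roi_spec(c(1, 1), 3)), "outside")
  expect_error(roi_stats(big, roi_spec(c(6, 6), 1)), ">= 8")
})

test_that("SNR follows the mean-over-SD definition averaged across 3 ROIs", {
  set.seed(4)
  img <- matrix(10 + rnorm(64 * 64), 64L, 64L)
  rois <- list(roi_spec(c(16, 16), 5, "left_lobe"),
               roi_spec(c(16, 48), 5, "anterior"),
               roi_spec(c(48, 32), 5, "posterior"))
  m <- compute_snr(img, rois)
  expect_equal(m$snr_average, mean(m$per_roi$snr))
  expect_equal(m$per_roi$snr, m$per_roi$mean / m$per_roi$sd)

  # identical ROI statistics -> average equals the per-ROI value
  same <- list(roi_spec(c(16, 16), 5), roi_spec(c(16, 16), 5),
               roi_spec(c(16, 16), 5))
  ms <- compute_snr(img, same)
  expect_equal(ms$snr_average, ms$per_roi$snr[1L])

  expect_error(compute_snr(matrix(5, 32L, 32L),
                           list(roi_spec(c(16, 16), 4), roi_spec(c(16, 16), 4),
                                roi_spec(c(16, 16), 4))),
               "zero SD")
  expect_error(compute_snr(img, rois[1:2]), "exactly 3")

  # scale invariance: mean and SD scale together
  m2 <- compute_snr(7.3 * img, rois)
  expect_equal(m2$snr_average, m$snr_average, tolerance = 1e-12)
})

test_that("measured SNR matches the Monte-Carlo magnitude-image prediction", {
  mu <- 1; sigma <- 0.08
  img <- image_volume(matrix(mu, 96L, 96L))
  k <- simulate_kspace(img, NULL, sigma, 6L)
  rec <- recon_full(k)
  rois <- list(roi_spec(c(24, 24), 10, "left_lobe"),
               roi_spec(c(24, 72), 10, "anterior"),
               roi_spec(c(72, 48), 10, "posterior"))
  measured <- compute_snr(rec, rois)$snr_average
  # independent oracle: 1e5 draws of |mu + complex noise|
  set.seed(99)
  mags <- Mod(complex(real = mu + rnorm(1e5, 0, sigma),
                      imaginary = rnorm(1e5, 0, sigma)))
  predicted <- mean(mags) / stats::sd(mags)
  expect_lt(abs(measured - predicted) / predicted, 0.10)
})

test_that("edge sharpness is scale invariant and detects boxcar blur", {
  # ideal vertical step edge between columns 16 and 17
  step <- matrix(0, 32L, 32L); step[, 17:32] <- 1
  # same edge convolved with a 3-pixel boxcar along the rows
  blur <- matrix(0, 32L, 32L); blur[, 16] <- 1 / 3; blur[, 17] <- 2 / 3
  blur[, 18:32] <- 1
  roi <- list(roi_spec(c(16, 16.5), 3, normal = c(0, 1)))
  s_step <- edge_sharpness(step, roi)
  s_blur <- edge_sharpness(blur, roi)
  expect_equal(s_step, 1)          # an aligned ideal step scores 1
  expect_lt(s_blur, s_step)
  expect_equal(s_blur, 1 / 3, tolerance = 1e-9)

  expect_equal(edge_sharpness(2 * step, roi), s_step, tolerance = 1e-12)
  # without a known normal the structure tensor finds the same edge
  expect_equal(edge_sharpness(step, list(roi_spec(c(16, 16.5), 3))), s_step,
               tolerance = 1e-9)
  expect_error(edge_sharpness(step, list()), "non-empty")
})

test_that("full reconstruction scores sharper than zero-fill on a noiseless phantom", {
  lp <- make_liver_phantom(small_liver_spec(seed = 17L, noise_sigma = 0))
  k <- simulate_kspace(lp$image, lp$phase, 0, 1L)
  sc <- make_pf_mask(nrow(lp$image$values), 6 / 8)
  rois <- pocsrecon:::.vessel_edge_rois(lp$image)
  s_full <- edge_sharpness(recon_full(k), rois)
  s_zf <- edge_sharpness(recon_zerofill(zero_fill(apply_mask(k, sc))), rois)
  expect_gt(s_full, s_zf)
})

test_that("surrogate grades follow the quartile calibration with upward ties", {
  cal <- fit_grade_calibration(c(1:100) / 10)
  expect_identical(surrogate_grade(100, cal), 4L)       # above top threshold
  expect_identical(surrogate_grade(0, cal), 1L)         # constant image score
  expect_identical(surrogate_grade(cal$thresholds[2L], cal), 3L)  # tie -> upper
  expect_identical(surrogate_grade(c(0.1, 5.05, 10), cal), c(1L, 3L, 4L))
  expect_true(all(diff(surrogate_grade(seq(0, 11, by = 0.1), cal)) >= 0))
  expect_error(surrogate_grade(1, list(thresholds = 1:3)), "fitted")
})
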
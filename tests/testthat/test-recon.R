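test_that("full reconstruction inverts the forward model", {
  ph <- make_resolution_phantom(small_phantom_spec())
  k <- simulate_kspace(ph, NULL, 0, 1L)
  r <- recon_full(k)
  expect_lt(rel_rmse(r, ph), 1e-10)

  # unit impulse at DC -> constant magnitude image
  n <- 16L
  kk <- matrix(0 + 0i, n, n); kk[n / 2 + 1L, n / 2 + 1L] <- 1 + 0i
  r2 <- recon_full(kspace_data(kk))
  expect_lt(diff(range(r2$values)), 1e-12)

  # linearity: scaling k scales magnitudes by |alpha|
  alpha <- 2 - 3i
  r3 <- recon_full(kspace_data(alpha * k$values, geometry = k$geometry))
  expect_equal(r3$values, Mod(alpha) * r$values, tolerance = 1e-12)

  sc <- make_pf_mask(nrow(ph$values), 6 / 8)
  expect_error(recon_full(apply_mask(k, sc)), "fully sampled")
})

test_that("zero-filled recon blurs but preserves the background mean", {
  ph <- make_resolution_phantom(small_phantom_spec())
  k <- simulate_kspace(ph, NULL, 0, 1L)
  sc <- make_pf_mask(nrow(ph$values), 6 / 8)
  km <- apply_mask(k, sc)
  z <- recon_zerofill(zero_fill(km))
  p <- recon_pocs(km, sc, recon_config())$image
  expect_gt(rel_rmse(z, ph), rel_rmse(p, ph))

  # full mask: equals recon_full
  zf_full <- recon_zerofill(apply_mask(k, make_pf_mask(nrow(ph$values), 1)))
  expect_equal(zf_full$values, recon_full(k)$values, tolerance = 1e-12)

  # background-only ROI mean within 1% of the full recon's
  roi <- roi_spec(c(38, 56), 3, "background")
  expect_lt(abs(roi_stats(z, roi)$mean / roi_stats(recon_full(k), roi)$mean - 1),
            0.01)
})

test_that("phase estimation recovers constant and smooth phases", {
  ph <- make_resolution_phantom(small_phantom_spec())
  sc <- make_pf_mask(nrow(ph$values), 6 / 8)
  k <- simulate_kspace(ph, NULL, 0, 1L)
  km <- apply_mask(k, sc)

  # real phantom, rectangular window: band data Hermitian -> phase exactly 0
  # wherever the low-resolution image is positive
  est0 <- estimate_phase(km, sc, "rectangular")
  support <- ph$values > 0.01 * max(ph$values)
  expect_lt(max(abs(est0$values[support])), 1e-6)

  # a constant phase offset passes straight through
  cphase <- 0.8
  kc <- apply_mask(simulate_kspace(ph, matrix(cphase, nrow(ph$values),
                                              ncol(ph$values)), 0, 1L), sc)
  estc <- estimate_phase(kc, sc, "rectangular")
  expect_lt(max(abs(estc$values[support] - cphase)), 1e-6)

  # smooth band-limited phase at the default geometry: the windowed
  # estimate tracks the truth on the object interior with either window
  lp <- make_liver_phantom(liver_phantom_spec(seed = 8L, noise_sigma = 0))
  klm <- apply_mask(simulate_kspace(lp$image, lp$phase, 0, 1L),
                    make_pf_mask(nrow(lp$image$values), 6 / 8))
  interior <- lp$image$values > 0.5 * max(lp$image$values)
  for (win in c("rectangular", "hann")) {
    est <- estimate_phase(klm, window = win)
    expect_lt(max(abs(est$values[interior] - lp$phase$values[interior])), 0.05)
  }

  expect_error(make_pf_mask(nrow(ph$values), 0.5), "1/2")
})

test_that("phase projection is the idempotent projection onto the phase line", {
  phi <- matrix(stats::runif(64, -pi, pi), 8L, 8L)
  # rho already on the line -> unchanged
  rho <- 2 * exp(1i * phi)
  expect_equal(project_phase(rho, phi), rho, tolerance = 1e-12)
  # orthogonal component annihilated
  rho_perp <- 3 * exp(1i * (phi + pi / 2))
  expect_lt(max(Mod(project_phase(rho_perp, phi))), 1e-12)
  # hand example: 1 + i projected onto phase 0 is its real part
  expect_equal(project_phase(matrix(1 + 1i), matrix(0)), matrix(1 + 0i),
               tolerance = 1e-12)
  # idempotence on random complex images
  set.seed(1)
  z <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8L, 8L)
  once <- project_phase(z, phi)
  expect_equal(project_phase(once, phi), once, tolerance = 1e-13)
})

test_that("data consistency matches the piecewise oracle", {
  set.seed(2)
  n <- 16L
  k0v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  sc <- make_pf_mask(n, 6 / 8)
  k0 <- apply_mask(kspace_data(k0v), sc)
  est <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  out <- data_consistency(est, k0, sc)
  # brute-force elementwise oracle
  for (i in seq_len(n)) {
    expected <- if ((i - 1L) %in% sc$acquired_indices) k0$values[i, ] else est[i, ]
    expect_identical(out[i, ], expected)
  }
  # full mask returns the measured data
  kf <- kspace_data(k0v)
  expect_identical(data_consistency(est, kf, make_pf_mask(n, 1)), k0v)
  expect_error(data_consistency(est[1:8, 1:8], k0, sc), "shapes differ")
})

test_that("merging filter weights are a monotone partition of unity", {
  n <- 32L
  sc <- make_pf_mask(n, 6 / 8)
  m <- length(sc$acquired_indices)
  w <- pocsrecon:::.merge_weights(sc, 8L)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[setdiff(seq_len(n), sc$acquired_indices + 1L)] == 0))
  expect_true(all(w[seq_len(m - 4L)] == 1))          # deep acquired
  expect_true(all(diff(w[seq_len(m)]) <= 0))          # monotone across ramp

  set.seed(3)
  k0v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  k0 <- apply_mask(kspace_data(k0v), sc)
  est <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  merged <- merge_filter(est, k0, sc, 8L)
  # lines more than ramp/2 inside the acquired region equal K0 exactly
  expect_identical(merged[seq_len(m - 4L), ], k0$values[seq_len(m - 4L), ])
  # ramp 0 reduces to the hard data-consistency switch
  expect_identical(merge_filter(est, k0, sc, 0L), data_consistency(est, k0, sc))
  expect_error(merge_filter(est, k0, sc, 2L * n), "wider than the acquired block")
})

test_that("POCS with a full mask reduces to the full reconstruction", {
  ph <- make_resolution_phantom(small_phantom_spec())
  k <- simulate_kspace(ph, NULL, 0.02, 5L)
  full_sc <- make_pf_mask(nrow(ph$values), 1)
  res <- recon_pocs(apply_mask(k, full_sc), full_sc, recon_config())
  expect_lt(rel_rmse(res$image, recon_full(k)), 1e-10)
})

test_that("POCS agrees with the brute-force Hermitian oracle on real phantoms", {
  cfg <- recon_config(n_iterations = 4L, phase_window = "rectangular",
                      merge_ramp_lines = 0L)
  for (seed in 1:3) {
    ph <- make_liver_phantom(small_liver_spec(seed = seed,
                                              phase_amplitude_rad = 0,
                                              noise_sigma = 0))
    k <- simulate_kspace(ph$image, NULL, 0, 1L)
    sc <- make_pf_mask(nrow(ph$image$values), 6 / 8)
    km <- apply_mask(k, sc)
    pocs <- recon_pocs(km, sc, cfg)$image
    oracle <- hermitian_recon_oracle(km, sc)
    expect_lt(rel_rmse(pocs$values, oracle), 0.01)
  }
})

test_that("POCS error is non-increasing in the iteration count", {
  lp <- make_liver_phantom(small_liver_spec(seed = 13L, noise_sigma = 0))
  k <- simulate_kspace(lp$image, lp$phase, 0, 1L)
  sc <- make_pf_mask(nrow(lp$image$values), 6 / 8)
  km <- apply_mask(k, sc)
  errs <- vapply(1:5, function(it) {
    rel_rmse(recon_pocs(km, sc, recon_config(n_iterations = it))$image,
             lp$image)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("the POCS state trace honours the data-consistency contract", {
  lp <- make_liver_phantom(small_liver_spec(seed = 21L))
  k <- simulate_kspace(lp$image, lp$phase, 0.05, 2L)
  sc <- make_pf_mask(nrow(lp$image$values), 6 / 8)
  km <- apply_mask(k, sc)
  cfg <- recon_config(n_iterations = 3L)
  res <- recon_pocs(km, sc, cfg)
  st <- res$state
  expect_length(st$iterations, 3L)
  acq <- sc$acquired_indices + 1L
  for (it in st$iterations) {
    if (!it$final) {
      expect_identical(it$K_est[acq, ], km$values[acq, ])
    }
  }
  # after merging, acquired lines outside the ramp equal the measured data
  w <- pocsrecon:::.merge_weights(sc, cfg$merge_ramp_lines)
  hard <- which(w == 1)
  last <- st$iterations[[3L]]
  expect_identical(last$K_est[hard, ], km$values[hard, ])
  # early stop via convergence tolerance shortens the trace but still merges
  res2 <- recon_pocs(km, sc, recon_config(n_iterations = 10L,
                                          convergence_tol = 0.5))
  expect_lt(length(res2$state$iterations), 10L)
  expect_true(res2$state$iterations[[length(res2$state$iterations)]]$final)
})
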
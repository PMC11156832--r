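test_that("Otsu threshold separates well-separated modes exactly", {
  m <- matrix(c(rep(10, 200), rep(200, 200)), 20, 20)
  t0 <- otsu_threshold(image2d(m))
  expect_gte(t0, 10)
  expect_lt(t0, 200)
  b <- binarize(image2d(m), t0)
  expect_identical(b$data, (m > 100) * 1.0)

  expect_error(otsu_threshold(image2d(matrix(3, 5, 5))), "constant")
})

test_that("Otsu equals the brute-force between-class-variance argmax", {
  set.seed(31)
  # overlapping modes: the between-class-variance maximum is then unique,
  # so independent implementations must agree (a gapped histogram has a
  # plateau of tied maxima and any tie-break is valid)
  m <- matrix(runif(200 * 200), 200)
  m[60:140, 60:140] <- m[60:140, 60:140] + 0.8
  t_pkg <- otsu_threshold(image2d(m))
  rng <- range(m)
  h <- tabulate(pmin(floor((m - rng[1]) / diff(rng) * 256) + 1, 256), 256)
  sb <- vapply(1:255, function(t) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) return(-Inf)
    m0 <- sum(h[1:t] * (1:t)) / w0
    m1 <- sum(h[(t + 1):256] * ((t + 1):256)) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1))
  t_brute <- rng[1] + which.max(sb) * diff(rng) / 256
  expect_equal(t_pkg, t_brute, tolerance = 1e-12)
  # cross-check against an independent implementation (EBImage expects [0,1])
  m01 <- (m - rng[1]) / diff(rng)
  t_ref <- EBImage::otsu(m01, range = c(0, 1), levels = 256)
  expect_lt(abs((t_pkg - rng[1]) / diff(rng) - t_ref), 2 / 256)
})

test_that("inverting intensities swaps the Otsu classes", {
  set.seed(32)
  m <- matrix(runif(80 * 80), 80)
  m[20:60, 20:60] <- m[20:60, 20:60] + 1.5
  cls <- binarize(image2d(m))$data
  inv <- binarize(image2d(max(m) - m))$data
  expect_gt(mean(cls == 1 - inv), 0.99)
})

test_that("single-band scores: identity, global phase, and a formula oracle", {
  set.seed(33)
  cx <- matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)), 64)
  expect_identical(cwssi_band(cx, cx, 1e-8), 1)

  # a rigid global phase leaves the score at 1 (the translation signature)
  cy <- cx * exp(1i * 0.83)
  expect_lt(abs(cwssi_band(cx, cy, 1e-8) - 1), 1e-6)

  # independent grids: direct evaluation of the printed formula
  cy2 <- matrix(complex(real = rnorm(64 * 64), imaginary = rnorm(64 * 64)), 64)
  K <- 0.37
  direct <- (2 * abs(sum(cx * Conj(cy2))) + K) /
    (sum(abs(cx)^2) + sum(abs(cy2)^2) + K)
  expect_equal(cwssi_band(cx, cy2, K), direct, tolerance = 1e-12)

  expect_error(cwssi_band(cx, cy2[1:32, ], 1), "shape")
  expect_error(cwssi_band(cx, cy2, 0), "K")
})

test_that("the two printed forms of the band score are one formula", {
  set.seed(34)
  for (i in 1:25) {
    cx <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16)
    cy <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16)
    expect_lt(abs(cwssi_band(cx, cy, 0.1) - cwssi_band_factored(cx, cy, 0.1)),
              1e-12)
  }
  cx <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8)
  expect_equal(cwssi_band_factored(cx, cx, 1e-8), 1, tolerance = 1e-12)
  # the magnitude factor alone is 1 whenever |cy| = |cx| pointwise
  phases <- matrix(runif(64, 0, 2 * pi), 8)
  cy <- Mod(cx) * exp(1i * phases)
  mag_term <- (2 * sum(Mod(cx) * Mod(cy)) + 1e-8) /
    (sum(Mod(cx)^2) + sum(Mod(cy)^2) + 1e-8)
  expect_equal(mag_term, 1, tolerance = 1e-9)
})

test_that("whole-image similarity: identity, bounds, and shift tolerance", {
  img <- mip_fixture()
  m <- img$data
  expect_identical(cwssi(img, img)$cwssi, 1)

  # shifts of 1-3 px stay above the package's documented contract of 0.9
  for (d in 1:3) {
    s <- cwssi(img, image2d(shift_image(m, d, d), img$pixel_size))$cwssi
    expect_gte(s, 0.9)
    expect_lte(s, 1 + 1e-12)
  }
  # a 3-degree in-plane rotation stays above 0.85
  rot <- image2d(angioqa:::rotate_image(m, 3), img$pixel_size)
  expect_gte(cwssi(img, rot)$cwssi, 0.85)

  # independent noise images score below the documented null ceiling (the
  # 95th percentile of the measured null distribution is 0.38)
  for (s in 1:10) {
    set.seed(s)
    nx <- image2d(matrix(runif(256 * 256), 256))
    ny <- image2d(matrix(runif(256 * 256), 256))
    expect_lt(cwssi(nx, ny)$cwssi, 0.45)
  }
})

test_that("cwssi stays within [0, 1] on random image pairs", {
  set.seed(35)
  for (i in 1:40) {
    a <- image2d(matrix(rnorm(64 * 64), 64))
    b <- image2d(matrix(rnorm(64 * 64), 64))
    v <- cwssi(a, b)$cwssi
    expect_gte(v, 0)
    expect_lte(v, 1 + 1e-12)
  }
})

test_that("halving K leaves non-degenerate scores essentially unchanged", {
  img <- mip_fixture()
  sh <- image2d(shift_image(img$data, 2, 2), img$pixel_size)
  v1 <- cwssi(img, sh, similarity_config(K = 1e-6))$cwssi
  v2 <- cwssi(img, sh, similarity_config(K = 5e-7))$cwssi
  expect_lt(abs(v1 - v2), 1e-3)
})

test_that("cross-modality comparison discriminates anatomy and orientation", {
  img <- mip_fixture()
  expect_equal(compare_modality(img, img)$cwssi, 1, tolerance = 1e-12)

  spec <- phantom_spec(grid_shape = c(256, 256, 64),
                       voxel_size = c(0.2, 0.2, 0.3))
  vol <- suppressWarnings(rasterize(build_vessel_tree(seed = 3,
                                                      extent = c(48, 48, 17)),
                                    spec))
  same <- numeric(0); diff <- numeric(0)
  for (s in 1:3) {
    dsa <- project_dsa_like(vol, "axial", rotation_deg = 2, blur_sigma_px = 1,
                            intensity_gamma = 1.5, noise_sigma = 0.01,
                            seed = s)
    other <- suppressWarnings(rasterize(
      build_vessel_tree(seed = 90 + s, extent = c(48, 48, 17)), spec))
    dsa_other <- project_dsa_like(other, "axial", rotation_deg = 2,
                                  blur_sigma_px = 1, intensity_gamma = 1.5,
                                  noise_sigma = 0.01, seed = s)
    same <- c(same, compare_modality(img, dsa)$cwssi)
    diff <- c(diff, compare_modality(img, dsa_other)$cwssi)
    # mirroring the DSA image strictly decreases the similarity
    flip <- image2d(dsa$data[, ncol(dsa$data):1], dsa$pixel_size)
    expect_lt(compare_modality(img, flip)$cwssi,
              compare_modality(img, dsa)$cwssi)
  }
  expect_true(all(same > diff))
})

test_that("compare_modality resamples mismatched grids and logs its steps", {
  img <- mip_fixture()
  small <- angioqa:::resample_image(img, c(128, 128))
  res <- compare_modality(img, small)
  expect_gt(res$cwssi, 0.8) # same anatomy at half resolution
  expect_true(any(grepl("resampled", res$preprocessing_log)))
  expect_true(any(grepl("Otsu", res$preprocessing_log)))

  flat <- image2d(matrix(1, 64, 64))
  expect_error(compare_modality(img, flat), "dsa_image")
})
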
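test_that("seed statistics use the clipped window and population variance", {
  img <- matrix(7, 10, 10)
  st <- collect_seed_stats(img, seed_point(5, 5))
  expect_equal(st$mean, 7)
  expect_equal(st$variance, 0)
  expect_equal(st$sample_size, 9L)

  img2 <- matrix(0, 5, 5)
  img2[2:4, 2:4] <- matrix(1:9, 3, 3)
  st2 <- collect_seed_stats(img2, seed_point(3, 3))
  expect_equal(st2$mean, 5)
  expect_equal(st2$variance, 20 / 3)

  corner <- collect_seed_stats(img, seed_point(1, 1))
  expect_equal(corner$sample_size, 4L)

  expect_error(collect_seed_stats(img, seed_point(11, 1)),
               class = "mwdhseg_index_error")
})

test_that("clustering threshold hits the two-delta fixed point exactly", {
  band <- matrix(c(rep(4, 90), rep(12, 10)), 10, 10)
  st <- collect_seed_stats(matrix(12, 5, 5), seed_point(3, 3))
  t_low <- compute_low_threshold(band, st)
  expect_equal(as.numeric(t_low), 8)
  expect_equal(sort(attr(t_low, "class_means")), c(4, 12))
})

test_that("clustering threshold separates two Gaussian classes across seeds", {
  for (s in 1:10) {
    set.seed(s)
    v <- c(rnorm(1200, 30, 2), rnorm(800, 60, 2))
    band <- matrix(sample(v), 40, 50)
    st <- structure(list(mean = 60, variance = 4, sample_size = 9),
                    class = "mwdh_seed_stats")
    t_low <- as.numeric(compute_low_threshold(band, st))
    expect_gt(t_low, 40); expect_lt(t_low, 50)
  }
})

test_that("clustering threshold is affine-equivariant and order-invariant", {
  set.seed(21)
  band <- matrix(c(rnorm(70, 10, 1), rnorm(30, 25, 1)), 10, 10)
  st <- structure(list(mean = 25, variance = 1, sample_size = 9),
                  class = "mwdh_seed_stats")
  t0 <- as.numeric(compute_low_threshold(band, st))
  for (ab in list(c(2, 5), c(0.5, -3))) {
    st2 <- structure(list(mean = ab[1] * 25 + ab[2], variance = ab[1]^2,
                          sample_size = 9), class = "mwdh_seed_stats")
    t2 <- as.numeric(compute_low_threshold(ab[1] * band + ab[2], st2))
    expect_equal(t2, ab[1] * t0 + ab[2], tolerance = 1e-8)
  }
  perm <- matrix(sample(as.vector(band)), 10, 10)
  expect_equal(as.numeric(compute_low_threshold(perm, st)), t0)
})

test_that("constant band is rejected as degenerate", {
  st <- structure(list(mean = 5, variance = 0, sample_size = 9),
                  class = "mwdh_seed_stats")
  expect_error(compute_low_threshold(matrix(5, 6, 6), st),
               class = "mwdhseg_degenerate_error")
})

test_that("low-band classification follows the seed's side of the threshold", {
  band <- matrix(c(1, 1, 9, 9), 2, 2)
  expect_equal(apply_low_threshold(band, 5, seed_point(1, 2)),
               matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_equal(apply_low_threshold(band, 5, seed_point(1, 1)),
               matrix(c(1L, 1L, 0L, 0L), 2, 2))
  # seed value exactly at the threshold counts as "above"
  tie <- matrix(c(5, 1, 9, 1), 2, 2)
  m <- apply_low_threshold(tie, 5, seed_point(1, 1))
  expect_equal(m[1, 1], 1L)
})

test_that("labeled fraction tracks the seed class's mixing fraction", {
  set.seed(5)
  frac <- 0.3
  n <- 10000
  v <- c(rnorm(round(n * frac), 60, 2), rnorm(round(n * (1 - frac)), 20, 2))
  band <- matrix(sample(v), 100, 100)
  st <- structure(list(mean = 60, variance = 4, sample_size = 9),
                  class = "mwdh_seed_stats")
  t_low <- as.numeric(compute_low_threshold(band, st))
  hi <- which(band >= t_low, arr.ind = TRUE)[1, ]
  mask <- apply_low_threshold(band, t_low, seed_point(hi[1], hi[2]))
  expect_lt(abs(mean(mask) - frac), 0.02)
})

test_that("MAD noise estimate is consistent and robust to outliers", {
  set.seed(9)
  band <- matrix(rnorm(100 * 100, 0, 2), 100, 100)
  s <- estimate_noise_sigma(band)
  expect_gt(s, 1.9); expect_lt(s, 2.1)
  expect_equal(estimate_noise_sigma(matrix(0, 20, 20)), 0)
  set.seed(10)
  v <- rnorm(10000)
  v[sample(10000, 100)] <- sample(c(-50, 50), 100, TRUE)
  s2 <- estimate_noise_sigma(matrix(v, 100, 100))
  expect_gt(s2, 0.95); expect_lt(s2, 1.1)
  # dispatch on a full sub-band set picks the finest diagonal band
  set.seed(11)
  img <- matrix(rnorm(40 * 40, 100, 3), 40, 40)
  bands <- mwdh_analyze_2d(img)
  expect_equal(estimate_noise_sigma(bands), estimate_noise_sigma(bands[["11"]]))
})

test_that("Lee filter: identity at zero noise, mean in flat regions, hand value", {
  set.seed(13)
  band <- matrix(rnorm(36), 6, 6)
  expect_equal(lee_filter(band, lee_params(1, 0)), band)
  # variance below the noise floor collapses to the local window mean
  flat <- matrix(1, 5, 5); flat[3, 3] <- 1.01
  out <- lee_filter(flat, lee_params(1, 10))
  expect_equal(out[3, 3], mean(flat[2:4, 2:4]))
  # hand evaluation: window {0,0,0,10,10,10,0,0,0}, sigma_n^2 = 1:
  # m = 10/3, v = 200/9, k = 191/200, m + k (10 - m) = 9.7
  w <- matrix(c(0, 0, 0, 10, 10, 10, 0, 0, 0), 3, 3)
  got <- lee_filter(w, lee_params(1, 1))
  expect_equal(got[2, 2], 10 / 3 + (191 / 200) * (10 - 10 / 3), tolerance = 1e-12)
  expect_equal(got[2, 2], 9.7, tolerance = 1e-12)
})

test_that("Lee filter matches the brute-force per-pixel oracle exactly", {
  set.seed(17)
  for (dims in list(c(4, 6), c(6, 6), c(5, 3))) {
    band <- matrix(rnorm(prod(dims), 0, 3), dims[1], dims[2])
    for (p in list(lee_params(1, 1.5), lee_params(2, 0.5)))
      expect_identical(lee_filter(band, p), lee_oracle(band, p))
  }
})

test_that("Lee filter is idempotent on constant images", {
  const <- matrix(4, 6, 6)
  p <- lee_params(1, 2)
  expect_equal(lee_filter(const, p), const)
  expect_equal(lee_filter(lee_filter(const, p), p), const)
})

test_that("hard thresholding follows the magnitude rule and is monotone", {
  band <- matrix(c(-5, -2, 0, 2, 5, 1), 2, 3)
  expect_equal(apply_high_threshold(band, 0), band)
  expect_equal(apply_high_threshold(band, 3),
               matrix(c(-5, 0, 0, 0, 5, 0), 2, 3))
  expect_equal(apply_high_threshold(band, 100), matrix(0, 2, 3))
  set.seed(19)
  b <- matrix(rnorm(400), 20, 20)
  zeroed <- sapply(c(0, 0.5, 1, 2, 4), function(t) sum(apply_high_threshold(b, t) == 0))
  expect_true(all(diff(zeroed) >= 0))
  expect_error(apply_high_threshold(b, -1), class = "mwdhseg_validation_error")
})
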
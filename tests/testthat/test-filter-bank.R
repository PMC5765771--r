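test_that("bank taps satisfy the moment and perfect-reconstruction identities", {
  bank <- double_haar_bank()
  expect_equal(sum(bank$analysis$h0), 1)
  expect_equal(sum(bank$analysis$h1), 0)
  expect_equal(sum(bank$analysis$h2), 0)
  expect_lt(reconstruction_defect(bank), 1e-12)
})

test_that("1D analysis annihilates constants and ramps in the high channels", {
  ch <- mwdh_analyze_1d(rep(5, 5))
  expect_equal(ch$x0, rep(5, 5))
  expect_equal(ch$x1, rep(0, 5))
  expect_equal(ch$x2, rep(0, 5))
  # second-difference channel of a linear ramp is zero away from the ends
  ramp <- mwdh_analyze_1d(0:4)
  expect_equal(ramp$x2[2:4], rep(0, 3))
})

test_that("1D impulse response reproduces the reversed taps at center offsets", {
  x <- numeric(7); x[4] <- 1
  ch <- mwdh_analyze_1d(x)
  bank <- double_haar_bank()
  # center-aligned correlation: channel values at offsets -1, 0, +1 around
  # the impulse are the taps in reverse order
  expect_equal(ch$x0[3:5], rev(bank$analysis$h0))
  expect_equal(ch$x1[3:5], rev(bank$analysis$h1))
  expect_equal(ch$x2[3:5], rev(bank$analysis$h2))
  expect_equal(ch$x1[c(1, 2, 6, 7)], rep(0, 4))
})

test_that("1D round trip is exact for random signals and trivial channels", {
  set.seed(42)
  worst <- max(vapply(1:100, function(i) {
    x <- rnorm(64)
    max(abs(mwdh_synthesize_1d(mwdh_analyze_1d(x)) - x))
  }, numeric(1)))
  expect_lt(worst, 1e-9)
  zero <- structure(list(x0 = numeric(10), x1 = numeric(10), x2 = numeric(10)),
                    class = "mwdh_channels")
  expect_equal(mwdh_synthesize_1d(zero), numeric(10))
  expect_equal(mwdh_synthesize_1d(mwdh_analyze_1d(rep(5, 12))), rep(5, 12))
})

test_that("1D input shorter than the filter support and ragged channels error", {
  expect_error(mwdh_analyze_1d(c(1, 2)), class = "mwdhseg_shape_error")
  bad <- structure(list(x0 = numeric(5), x1 = numeric(4), x2 = numeric(5)),
                   class = "mwdh_channels")
  expect_error(mwdh_synthesize_1d(bad), class = "mwdhseg_shape_error")
})

test_that("2D analysis: constants and planes land where the theory says", {
  b <- mwdh_analyze_2d(matrix(7, 9, 11))
  expect_equal(b[["00"]], matrix(7, 9, 11))
  for (nm in setdiff(names(b), "00")) expect_equal(max(abs(b[[nm]])), 0)
  # plane a*row + b*col + c: annihilated by any channel-2 factor and by (1,1)
  r <- matrix(seq_len(10), 10, 12)
  cc <- matrix(seq_len(12), 10, 12, byrow = TRUE)
  plane <- 2 * r - 3 * cc + 5
  bp <- mwdh_analyze_2d(plane)
  for (nm in c("20", "02", "21", "12", "22", "11"))
    expect_equal(max(abs(bp[[nm]][2:9, 2:11])), 0)
})

test_that("2D round trip, linearity, and mean preservation hold", {
  set.seed(7)
  img <- matrix(rnorm(32 * 32), 32, 32)
  bands <- mwdh_analyze_2d(img)
  expect_lt(max(abs(mwdh_synthesize_2d(bands) - img)), 1e-9)
  expect_lt(abs(mean(bands[["00"]]) - mean(img)), 1e-9)
  img2 <- matrix(rnorm(32 * 32), 32, 32)
  b2 <- mwdh_analyze_2d(img2)
  mix <- bands
  for (nm in names(mix)) mix[[nm]] <- 2 * bands[[nm]] - 0.5 * b2[[nm]]
  expect_lt(max(abs(mwdh_synthesize_2d(mix) -
                      (2 * mwdh_synthesize_2d(bands) - 0.5 * mwdh_synthesize_2d(b2)))),
            1e-10)
})

test_that("2D sub-bands equal brute-force 3x3 windowed dot products exactly", {
  set.seed(11)
  img <- matrix(rnorm(25), 5, 5)
  got <- mwdh_analyze_2d(img)
  want <- subband_oracle(img)
  for (nm in names(want)) expect_identical(got[[nm]], want[[nm]])
})

test_that("zeroing the high bands of a noisy constant image denoises it", {
  set.seed(3)
  clean <- matrix(50, 24, 24)
  noisy <- clean + matrix(rnorm(24 * 24, 0, 4), 24, 24)
  b <- mwdh_analyze_2d(noisy)
  for (nm in setdiff(names(b), "00")) b[[nm]] <- b[[nm]] * 0
  sm <- mwdh_synthesize_2d(b)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
})

test_that("2D analysis rejects non-finite pixels and missing bands", {
  img <- matrix(1, 5, 5); img[2, 2] <- NA
  expect_error(mwdh_analyze_2d(img), class = "mwdhseg_validation_error")
  b <- mwdh_analyze_2d(matrix(rnorm(25), 5, 5))
  b[["21"]] <- NULL
  expect_error(mwdh_synthesize_2d(b), class = "mwdhseg_shape_error")
  b2 <- mwdh_analyze_2d(matrix(rnorm(25), 5, 5))
  b2[["21"]] <- b2[["21"]][1:4, ]
  expect_error(mwdh_synthesize_2d(b2), class = "mwdhseg_shape_error")
})
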
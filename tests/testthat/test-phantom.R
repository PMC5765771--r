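test_that("phantom generation is deterministic and truth is noise-free analytic", {
  spec <- default_scenarios()$baseline
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth_masks, b$truth_masks)

  # truth masks equal analytic point-in-ellipse membership, pairwise disjoint
  for (k in seq_along(spec$organs)) {
    o <- spec$organs[[k]]
    r <- matrix(seq_len(spec$shape[1]), spec$shape[1], spec$shape[2]) - o$center[1]
    cc <- matrix(seq_len(spec$shape[2]), spec$shape[1], spec$shape[2], byrow = TRUE) - o$center[2]
    u <- r * cos(o$rotation) + cc * sin(o$rotation)
    v <- -r * sin(o$rotation) + cc * cos(o$rotation)
    inside <- (u / o$axes[1])^2 + (v / o$axes[2])^2 <= 1
    expect_equal(a$truth_masks[[o$name]] == 1L, inside)
  }
  expect_equal(max(a$truth_masks$bladder + a$truth_masks$prostate +
                     a$truth_masks$rectum), 1L)

  # masks and seeds do not depend on the noise realization
  spec2 <- spec; spec2$rng_seed <- 999L
  c2 <- generate_phantom(spec2)
  expect_identical(a$truth_masks, c2$truth_masks)
  expect_identical(a$suggested_seeds, c2$suggested_seeds)
  expect_false(identical(a$image, c2$image))

  # each suggested seed sits inside its own mask
  for (org in names(a$truth_masks))
    expect_equal(a$truth_masks[[org]][a$suggested_seeds[[org]]$row,
                                      a$suggested_seeds[[org]]$col], 1L)
})

test_that("organ mean intensity is recovered within the CLT bound", {
  spec <- default_scenarios()$baseline
  ph <- generate_phantom(spec)
  bl <- spec$organs[[1]]
  inside <- ph$truth_masks$bladder == 1L
  n <- sum(inside)
  tot_sd <- sqrt(spec$noise_sigma^2 + bl$texture_sigma^2)
  expect_lt(abs(mean(ph$image[inside]) - bl$mean_intensity), 3 * tot_sd / sqrt(n))
})

test_that("overlapping organ ellipses are rejected", {
  bad <- phantom_spec(
    shape = c(64L, 64L), background_intensity = 50, noise_sigma = 1,
    organs = list(
      organ_spec("bladder", c(30, 30), c(10, 10), mean_intensity = 100),
      organ_spec("prostate", c(35, 30), c(10, 10), mean_intensity = 120)
    ))
  expect_error(generate_phantom(bad), class = "mwdhseg_validation_error")
})

test_that("beacon artifacts: disc contract, streak envelope, empty list", {
  img <- matrix(100, 41, 41)
  expect_identical(add_beacon_artifacts(img, list()), img)

  bc <- beacon_spec(center = c(21, 21), radius = 3, peak_intensity = 400,
                    streak_count = 8L, streak_amplitude = 40,
                    streak_decay = 0.1, streak_offset = 0.3)
  out <- add_beacon_artifacts(img, list(bc))
  d <- sqrt(outer((1:41 - 21)^2, (1:41 - 21)^2, `+`))
  expect_true(all(out[d <= 3] >= 400))

  # single horizontal ray: perturbation magnitude follows amp * exp(-d * decay)
  one <- beacon_spec(center = c(21, 21), radius = 1, peak_intensity = 400,
                     streak_count = 1L, streak_amplitude = 40,
                     streak_decay = 0.1, streak_offset = 0)
  out1 <- add_beacon_artifacts(img, list(one))
  for (t in 2:20)
    expect_lt(abs((out1[21 + t, 21] - 100) - 40 * exp(-t * 0.1)), 1e-9)
})

test_that("shipped scenarios are valid and bracket easy and hard regimes", {
  sc <- default_scenarios()
  expect_gte(length(sc), 4L)
  expect_true(all(c("baseline", "beacons", "low_contrast_prostate",
                    "gas_filled_rectum") %in% names(sc)))
  for (s in sc) expect_s3_class(generate_phantom(s), "mwdh_phantom")

  cnr <- function(spec, name) {
    o <- spec$organs[[which(vapply(spec$organs, `[[`, character(1), "name") == name)]]
    abs(o$mean_intensity - spec$background_intensity) / spec$noise_sigma
  }
  for (org in c("bladder", "prostate", "rectum"))
    expect_gte(cnr(sc$baseline, org), 5)
  expect_lte(cnr(sc$low_contrast_prostate, "prostate"), 2)
  expect_gte(sc$gas_filled_rectum$gas_fraction, 0.3)

  # the three implanted beacons lie wholly inside the prostate truth mask
  ph <- generate_phantom(sc$beacons)
  expect_equal(length(sc$beacons$beacons), 3L)
  pros <- ph$truth_masks$prostate
  for (b in sc$beacons$beacons) {
    d <- sqrt(outer((seq_len(160) - b$center[1])^2,
                    (seq_len(160) - b$center[2])^2, `+`))
    expect_true(all(pros[d <= b$radius] == 1L))
  }
})
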
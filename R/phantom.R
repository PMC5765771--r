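#' Elliptical organ description for the pelvic phantom
#'
#' @param name Organ label, one of `"bladder"`, `"prostate"`, `"rectum"`.
#' @param center Numeric length-2, `(row, col)` centre in pixels.
#' @param axes Numeric length-2, semi-axes in pixels (row direction,
#'   column direction before rotation), both > 0.
#' @param rotation Rotation angle in radians (default 0).
#' @param mean_intensity Mean intensity inside the organ.
#' @param texture_sigma Standard deviation of additive intra-organ texture
#'   noise, >= 0.
#' @return Object of class `mwdh_organ_spec`.
#' @export
organ_spec <- function(name, center, axes, rotation = 0,
                       mean_intensity, texture_sigma = 0) {
  if (!name %in% c("bladder", "prostate", "rectum"))
    stop_validation("organ `name` must be bladder, prostate or rectum")
  if (length(center) != 2L || length(axes) != 2L || any(axes <= 0))
    stop_validation("`center` and `axes` must be length-2 with axes > 0")
  check_scalar(mean_intensity, "mean_intensity")
  check_scalar(texture_sigma, "texture_sigma", lower = 0)
  structure(list(name = name, center = as.numeric(center),
                 axes = as.numeric(axes), rotation = rotation,
                 mean_intensity = mean_intensity,
                 texture_sigma = texture_sigma),
            class = "mwdh_organ_spec")
}

#' Implanted-transponder (beacon) artifact description
#'
#' Models the imaging footprint of a small metallic electromagnetic
#' transponder: a saturated bright disc plus radial streaks of
#' alternating sign whose amplitude decays exponentially with distance
#' from the beacon, the qualitative signature of metal streak artifacts in
#' cone-beam CT.
#'
#' @param center `(row, col)` beacon centre in pixels.
#' @param radius Disc radius in pixels, >= 1.
#' @param peak_intensity Intensity assigned to the disc.
#' @param streak_count Number of radial streaks, >= 0.
#' @param streak_amplitude Streak amplitude at unit distance scale.
#' @param streak_decay Exponential decay rate per pixel of distance, > 0.
#' @param streak_offset Angular offset of the first streak in radians;
#'   `NA` (default) draws it from the generator's RNG.
#' @return Object of class `mwdh_beacon_spec`.
#' @export
beacon_spec <- function(center, radius, peak_intensity,
                        streak_count = 8L, streak_amplitude = 0,
                        streak_decay = 0.1, streak_offset = NA) {
  if (length(center) != 2L) stop_validation("`center` must be length-2")
  check_scalar(radius, "radius", lower = 1)
  check_scalar(peak_intensity, "peak_intensity")
  if (streak_count < 0 || streak_count != round(streak_count))
    stop_validation("`streak_count` must be a non-negative integer")
  if (streak_decay <= 0) stop_validation("`streak_decay` must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 peak_intensity = peak_intensity,
                 streak_count = as.integer(streak_count),
                 streak_amplitude = streak_amplitude,
                 streak_decay = streak_decay,
                 streak_offset = streak_offset),
            class = "mwdh_beacon_spec")
}

#' Full phantom description
#'
#' @param shape `(rows, cols)` of the slice.
#' @param background_intensity Background (soft-tissue/fat mix) intensity.
#' @param noise_sigma Standard deviation of the global additive Gaussian
#'   noise, >= 0.
#' @param organs List of [organ_spec()]s, pairwise non-overlapping.
#' @param beacons List of [beacon_spec()]s (may be empty).
#' @param gas_fraction Fraction in `[0, 1)` of the rectum area replaced by
#'   a low-intensity (air) pocket; requires a rectum organ when > 0.
#' @param rng_seed Integer seed; the generated image is bit-identical for
#'   a fixed spec and seed.
#' @return Object of class `mwdh_phantom_spec`.
#' @export
phantom_spec <- function(shape, background_intensity, noise_sigma,
                         organs, beacons = list(), gas_fraction = 0,
                         rng_seed = 0L) {
  if (length(shape) != 2L || any(shape < 8))
    stop_validation("`shape` must be (rows, cols), each >= 8")
  check_scalar(background_intensity, "background_intensity")
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (gas_fraction < 0 || gas_fraction >= 1)
    stop_validation("`gas_fraction` must be in [0, 1)")
  if (gas_fraction > 0 &&
      !any(vapply(organs, function(o) o$name == "rectum", logical(1))))
    stop_validation("`gas_fraction` > 0 requires a rectum organ")
  structure(list(shape = as.integer(shape),
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, organs = organs,
                 beacons = beacons, gas_fraction = gas_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "mwdh_phantom_spec")
}

# Analytic point-in-ellipse membership on the pixel grid.
ellipse_mask <- function(shape, center, axes, rotation = 0) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  u <- r * cos(rotation) + c * sin(rotation)
  v <- -r * sin(rotation) + c * cos(rotation)
  m <- (u / axes[1])^2 + (v / axes[2])^2 <= 1
  mode(m) <- "integer"
  m
}

#' Add beacon discs and streak artifacts to an image
#'
#' For every beacon, `streak_count` rays leave the centre at evenly spaced
#' angles (plus a common offset, random unless fixed in the spec). Ray `i`
#' perturbs the pixels it crosses by
#' `(-1)^i * streak_amplitude * exp(-d * streak_decay)` at stepped
#' distance `d = 1, 2, ...` (each crossed pixel perturbed once, at its
#' first crossing). The disc pixels (distance <= `radius`) are then set to
#' `peak_intensity`. Uses the current RNG state for the angular offsets;
#' seed beforehand for reproducibility (done by [generate_phantom()]).
#'
#' @param image Numeric matrix.
#' @param beacons List of [beacon_spec()]s.
#' @return Perturbed image.
#' @export
add_beacon_artifacts <- function(image, beacons) {
  check_image(image)
  n <- nrow(image); p <- ncol(image)
  for (b in beacons) {
    if (b$center[1] < 1 || b$center[1] > n || b$center[2] < 1 || b$center[2] > p)
      stop_index("beacon centre outside the image")
    if (b$streak_count > 0L && b$streak_amplitude != 0) {
      offset <- if (is.na(b$streak_offset)) stats::runif(1, 0, 2 * pi) else b$streak_offset
      for (i in seq_len(b$streak_count) - 1L) {
        theta <- offset + 2 * pi * i / b$streak_count
        sgn <- (-1)^i
        seen <- integer(0)
        t <- 1
        repeat {
          pr <- round(b$center[1] + t * cos(theta))
          pc <- round(b$center[2] + t * sin(theta))
          if (pr < 1 || pr > n || pc < 1 || pc > p) break
          idx <- (pc - 1L) * n + pr
          if (!idx %in% seen) {
            image[idx] <- image[idx] + sgn * b$streak_amplitude * exp(-t * b$streak_decay)
            seen <- c(seen, idx)
          }
          t <- t + 1
        }
      }
    }
    disc <- ellipse_mask(c(n, p), b$center, c(b$radius, b$radius))
    image[disc == 1L] <- b$peak_intensity
  }
  image
}

#' Generate a synthetic pelvic phantom slice with ground truth
#'
#' Renders background, elliptical organs with per-organ texture, an
#' optional rectal gas pocket, beacon artifacts and global Gaussian noise,
#' in that order. Ground-truth masks are the analytic noise-free ellipses
#' and are unaffected by noise, gas or artifacts; the suggested seed for
#' each organ is its centroid. The gas pocket is a concentric interior
#' ellipse of the rectum scaled so its area is `gas_fraction` of the
#' rectum's, at near-air intensity (5% of the background).
#'
#' @param spec [phantom_spec()].
#' @return Object of class `mwdh_phantom`: list with `image`,
#'   `truth_masks` (named by organ), `suggested_seeds` (named
#'   [seed_point()]s) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "mwdh_phantom_spec"))
    stop_validation("`spec` must come from phantom_spec()")
  shape <- spec$shape
  masks <- lapply(spec$organs, function(o)
    ellipse_mask(shape, o$center, o$axes, o$rotation))
  names(masks) <- vapply(spec$organs, `[[`, character(1), "name")
  if (length(masks) > 1L) {
    for (i in seq_along(masks)[-1L]) for (j in seq_len(i - 1L)) {
      if (any(masks[[i]] & masks[[j]]))
        stop_validation(sprintf("organs %s and %s overlap",
                                names(masks)[j], names(masks)[i]))
    }
  }
  image <- with_rng_seed(spec$rng_seed, {
    img <- matrix(spec$background_intensity, shape[1], shape[2])
    for (k in seq_along(spec$organs)) {
      o <- spec$organs[[k]]
      inside <- masks[[k]] == 1L
      img[inside] <- o$mean_intensity
      if (o$texture_sigma > 0)
        img[inside] <- img[inside] + stats::rnorm(sum(inside), 0, o$texture_sigma)
    }
    if (spec$gas_fraction > 0) {
      ro <- spec$organs[[which(names(masks) == "rectum")[1]]]
      gas <- ellipse_mask(shape, ro$center, ro$axes * sqrt(spec$gas_fraction),
                          ro$rotation)
      img[gas == 1L] <- 0.05 * spec$background_intensity
    }
    img <- add_beacon_artifacts(img, spec$beacons)
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          shape[1], shape[2])
    img
  })
  seeds <- lapply(masks, mask_centroid)
  structure(list(image = image, truth_masks = masks,
                 suggested_seeds = seeds, spec = spec),
            class = "mwdh_phantom")
}

#' Shipped phantom scenarios
#'
#' Four seeded scenarios spanning the operating range of the method:
#' \describe{
#'   \item{`baseline`}{high contrast, no artifacts; every organ has
#'     contrast-to-noise ratio >= 5.}
#'   \item{`beacons`}{baseline plus three beacons implanted in the
#'     prostate (mirroring the clinical implant count) with streaks.}
#'   \item{`low_contrast_prostate`}{prostate contrast-to-noise ratio
#'     <= 2; a stated failure mode (over-segmentation).}
#'   \item{`gas_filled_rectum`}{35% of the rectum replaced by an air
#'     pocket; a stated failure mode (the gas, not the rectum, is
#'     segmented).}
#' }
#'
#' @return Named list of [phantom_spec()]s.
#' @export
default_scenarios <- function() {
  organs <- function(prostate_intensity = 120) list(
    organ_spec("bladder",  center = c(48, 80),  axes = c(26, 32),
               mean_intensity = 180, texture_sigma = 2),
    organ_spec("prostate", center = c(95, 80),  axes = c(17, 20),
               mean_intensity = prostate_intensity, texture_sigma = 2),
    organ_spec("rectum",   center = c(130, 80), axes = c(13, 17),
               mean_intensity = 150, texture_sigma = 2)
  )
  beacons <- list(
    beacon_spec(center = c(90, 72),  radius = 2, peak_intensity = 400,
                streak_count = 8L, streak_amplitude = 50, streak_decay = 0.08),
    beacon_spec(center = c(95, 88),  radius = 2, peak_intensity = 400,
                streak_count = 8L, streak_amplitude = 50, streak_decay = 0.08),
    beacon_spec(center = c(101, 76), radius = 2, peak_intensity = 400,
                streak_count = 8L, streak_amplitude = 50, streak_decay = 0.08)
  )
  base <- function(...) phantom_spec(shape = c(160L, 160L),
                                     background_intensity = 50,
                                     noise_sigma = 5, ...)
  list(
    baseline = base(organs = organs(), rng_seed = 101L),
    beacons = base(organs = organs(), beacons = beacons, rng_seed = 102L),
    low_contrast_prostate = base(organs = organs(prostate_intensity = 58),
                                 rng_seed = 103L),
    gas_filled_rectum = base(organs = organs(), gas_fraction = 0.35,
                             rng_seed = 104L)
  )
}
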
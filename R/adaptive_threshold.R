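#' Seed point inside an image
#'
#' A seed point marks one pixel inside the structure of interest and is the
#' only user interaction the segmentation requires. Indices are 1-based
#' (`row`, `col`), as usual in R; the command-line interface accepts
#' 0-based coordinates and converts.
#'
#' @param row,col Integer pixel indices, 1-based.
#' @return Object of class `mwdh_seed`.
#' @export
seed_point <- function(row, col) {
  if (length(row) != 1L || length(col) != 1L ||
      !is.finite(row) || !is.finite(col) ||
      row != round(row) || col != round(col) || row < 1 || col < 1)
    stop_validation("`row` and `col` must be positive integers")
  structure(list(row = as.integer(row), col = as.integer(col)),
            class = "mwdh_seed")
}

check_seed <- function(seed, image) {
  if (!inherits(seed, "mwdh_seed")) stop_validation("`seed` must be a seed_point()")
  if (seed$row > nrow(image) || seed$col > ncol(image))
    stop_index(sprintf("seed (%d, %d) is outside the %dx%d image",
                       seed$row, seed$col, nrow(image), ncol(image)))
  invisible(seed)
}

window_indices <- function(image, seed, radius) {
  list(rows = max(1L, seed$row - radius):min(nrow(image), seed$row + radius),
       cols = max(1L, seed$col - radius):min(ncol(image), seed$col + radius))
}

#' Local intensity statistics around the seed point
#'
#' Collects mean and population variance over the `(2r+1)^2` window centred
#' on the seed, clipped to the image bounds. These statistics initialize the
#' clustering threshold of the low-frequency sub-band.
#'
#' @param image Numeric matrix (typically the low-frequency sub-band).
#' @param seed [seed_point()] inside the image.
#' @param window_radius Integer >= 1; the default 1 gives the 3x3 window.
#' @return Object of class `mwdh_seed_stats` with fields `mean`, `variance`
#'   (population, i.e. divided by the pixel count) and `sample_size`.
#' @export
collect_seed_stats <- function(image, seed, window_radius = 1L) {
  check_image(image)
  check_seed(seed, image)
  check_scalar(window_radius, "window_radius", lower = 1)
  w <- window_indices(image, seed, as.integer(window_radius))
  vals <- as.vector(image[w$rows, w$cols])
  structure(list(
    mean = mean(vals),
    variance = mean((vals - mean(vals))^2),
    sample_size = length(vals)
  ), class = "mwdh_seed_stats")
}

#' Clustering threshold for the low-frequency sub-band
#'
#' Two-class iterative mean clustering (Ridler-Calvard / ISODATA style)
#' with seed-informed initialization: class A starts at the seed-window
#' mean; class B starts at the mean of all pixels lying farther from the
#' seed mean than the global mean does. Pixels are then repeatedly
#' reassigned to the nearer class mean and the means updated, until both
#' means move by less than `tol` or `max_iter` iterations are reached. The
#' threshold is the midpoint of the converged class means, which is the
#' fixed point of the classic iterative threshold-selection scheme.
#'
#' @param low_band Numeric matrix, the `"00"` sub-band. Must not be
#'   constant (two classes cannot exist otherwise).
#' @param seed_stats Statistics from [collect_seed_stats()].
#' @param tol Convergence tolerance on the class-mean movement.
#' @param max_iter Iteration cap.
#' @return Threshold `t_low` (scalar) with attributes `class_means` (the
#'   two converged means, seed class first) and `iterations`.
#' @examples
#' b <- matrix(c(rep(4, 90), rep(12, 10)), 10, 10)
#' st <- list(mean = 12, variance = 0, sample_size = 9)
#' class(st) <- "mwdh_seed_stats"
#' compute_low_threshold(b, st)  # 8
#' @export
compute_low_threshold <- function(low_band, seed_stats, tol = 1e-6, max_iter = 100L) {
  check_image(low_band, arg = "low_band")
  if (!inherits(seed_stats, "mwdh_seed_stats"))
    stop_validation("`seed_stats` must come from collect_seed_stats()")
  v <- as.vector(low_band)
  if (diff(range(v)) == 0)
    stop_degenerate("low band is constant; no two intensity classes exist")
  m_a <- seed_stats$mean
  g <- mean(v)
  far <- abs(v - m_a) > abs(g - m_a)
  m_b <- if (any(far)) mean(v[far]) else v[which.max(abs(v - m_a))]
  if (m_a == m_b)
    stop_degenerate("cluster initialization is degenerate (identical class means)")
  it <- 0L
  repeat {
    it <- it + 1L
    thr <- (m_a + m_b) / 2
    in_a <- if (m_a < m_b) v < thr else v >= thr
    if (!any(in_a) || all(in_a)) break
    new_a <- mean(v[in_a])
    new_b <- mean(v[!in_a])
    moved <- max(abs(new_a - m_a), abs(new_b - m_b))
    m_a <- new_a
    m_b <- new_b
    if (moved < tol || it >= max_iter) break
  }
  structure((m_a + m_b) / 2, class_means = c(m_a, m_b), iterations = it)
}

#' Classify the low-frequency sub-band by a threshold, keeping the seed side
#'
#' Labels 1 every pixel lying on the same side of `t_low` as the seed's
#' low-band value, 0 the others. A seed value exactly equal to the
#' threshold is resolved as "above".
#'
#' @param low_band Numeric matrix.
#' @param t_low Finite threshold.
#' @param seed [seed_point()].
#' @return Binary (0/1) matrix of the band's shape.
#' @export
apply_low_threshold <- function(low_band, t_low, seed) {
  check_image(low_band, min_dim = 1L, arg = "low_band")
  check_seed(seed, low_band)
  check_scalar(as.numeric(t_low), "t_low")
  s <- low_band[seed$row, seed$col]
  mask <- if (s >= t_low) low_band >= t_low else low_band < t_low
  mode(mask) <- "integer"
  mask
}

#' Robust noise-level estimate from the finest diagonal sub-band
#'
#' Estimates the coefficient noise standard deviation as
#' `median(|w|) / 0.6745` over the finest diagonal band `"11"`, the usual
#' MAD-based estimator that is insensitive to the sparse large coefficients
#' contributed by edges.
#'
#' @param bands An `mwdh_subbands` set (band `"11"` is used) or a single
#'   numeric matrix taken as the diagonal band itself.
#' @return Non-negative scalar; 0 for an all-zero band.
#' @export
estimate_noise_sigma <- function(bands) {
  w <- if (is.matrix(bands)) bands
       else if (!is.null(bands[["11"]])) bands[["11"]]
       else stop_validation("`bands` must be a matrix or contain band \"11\"")
  if (!all(is.finite(w))) stop_validation("band contains non-finite values")
  stats::median(abs(w)) / 0.6745
}

#' Parameters of the Lee minimum-mean-square-error filter
#'
#' @param window_radius Integer >= 1 local-statistics window radius
#'   (default 1: a 3x3 window).
#' @param noise_sigma Noise standard deviation on the coefficient scale,
#'   >= 0 (typically from [estimate_noise_sigma()]).
#' @param multiplier Threshold multiplier `c` > 0 used downstream as
#'   `t_high = c * noise_sigma`; 3 is the standard detection threshold.
#' @return Object of class `mwdh_lee_params`.
#' @export
lee_params <- function(window_radius = 1L, noise_sigma = 0, multiplier = 3) {
  check_scalar(window_radius, "window_radius", lower = 1)
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop_validation("`multiplier` must be > 0")
  structure(list(window_radius = as.integer(window_radius),
                 noise_sigma = noise_sigma,
                 multiplier = multiplier),
            class = "mwdh_lee_params")
}

# Sum of `m` over the clipped (2r+1)^2 window at every pixel.
box_sum <- function(m, radius) {
  n <- nrow(m); p <- ncol(m)
  shift <- function(x, by, axis) {
    out <- matrix(0, nrow(x), ncol(x))
    if (axis == 1L) {
      if (by >= 0) out[(1 + by):n, ] <- x[1:(n - by), , drop = FALSE]
      else out[1:(n + by), ] <- x[(1 - by):n, , drop = FALSE]
    } else {
      if (by >= 0) out[, (1 + by):p] <- x[, 1:(p - by), drop = FALSE]
      else out[, 1:(p + by)] <- x[, (1 - by):p, drop = FALSE]
    }
    out
  }
  rows <- matrix(0, n, p)
  for (d in -radius:radius) rows <- rows + shift(m, d, 1L)
  out <- matrix(0, n, p)
  for (d in -radius:radius) out <- out + shift(rows, d, 2L)
  out
}

#' Lee filter: local linear minimum-mean-square-error estimate
#'
#' For every pixel, with local window mean `m` and population variance `v`
#' (window clipped at the image border) and noise variance `s2 =
#' noise_sigma^2`, computes the gain `k = max(0, v - s2) / v` (`k = 0`
#' where `v = 0`) and returns `m + k * (w - m)`. Smooth regions
#' (`v <= s2`) collapse to the local mean while strong edges (`v >> s2`)
#' pass nearly unchanged, which is what makes the filter edge-preserving.
#' With `noise_sigma = 0` the filter is the identity.
#'
#' @param band Numeric matrix of wavelet coefficients.
#' @param params [lee_params()].
#' @return Filtered matrix of the same shape.
#' @export
lee_filter <- function(band, params) {
  check_image(band, min_dim = 1L, arg = "band")
  if (!inherits(params, "mwdh_lee_params"))
    stop_validation("`params` must come from lee_params()")
  r <- params$window_radius
  counts <- box_sum(matrix(1, nrow(band), ncol(band)), r)
  m <- box_sum(band, r) / counts
  v <- box_sum(band^2, r) / counts - m^2
  v <- pmax(v, 0)  # guard tiny negative values from cancellation
  s2 <- params$noise_sigma^2
  k <- ifelse(v > 0, pmax(0, v - s2) / v, 0)
  m + k * (band - m)
}

#' Hard threshold on high-frequency coefficients
#'
#' Sets to zero every coefficient with magnitude below `t_high` and keeps
#' the others unchanged. The set of zeroed coefficients grows
#' monotonically with `t_high`.
#'
#' @param band Numeric matrix.
#' @param t_high Non-negative threshold on the coefficient magnitude.
#' @return Matrix of the same shape.
#' @export
apply_high_threshold <- function(band, t_high) {
  check_image(band, min_dim = 1L, arg = "band")
  if (!is.numeric(t_high) || length(t_high) != 1L || !is.finite(t_high) || t_high < 0)
    stop_validation("`t_high` must be a non-negative scalar")
  band * (abs(band) >= t_high)
}
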
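# Independent brute-force oracles and small fixture builders.

# Direct per-pixel evaluation of the nine sub-bands as 3x3 windowed dot
# products with the tensor-product tap masks, on a symmetric-padded image.
# Nested row-then-column summation mirrors the algebraic form of the
# separable transform so agreement is exact, not just approximate.
subband_oracle <- function(image, bank = double_haar_bank()) {
  n <- nrow(image); p <- ncol(image)
  pad <- rbind(image[1, ], image, image[n, ])
  pad <- cbind(pad[, 1], pad, pad[, p])
  h <- bank$analysis
  bands <- list()
  for (r in 0:2) for (cc in 0:2) {
    out <- matrix(0, n, p)
    for (i in seq_len(n)) for (j in seq_len(p)) {
      acc <- 0
      for (b in 1:3) {
        inner <- 0
        for (a in 1:3) inner <- inner + h[[r + 1L]][a] * pad[i + a - 1L, j + b - 1L]
        acc <- acc + h[[cc + 1L]][b] * inner
      }
      out[i, j] <- acc
    }
    bands[[paste0(r, cc)]] <- out
  }
  bands
}

# Per-pixel evaluation of the Lee estimate m + k (w - m) over the clipped
# window, k = max(0, v - s2) / v with population variance v.
lee_oracle <- function(band, params) {
  n <- nrow(band); p <- ncol(band)
  r <- params$window_radius
  s2 <- params$noise_sigma^2
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p)) {
    rows <- max(1L, i - r):min(n, i + r)
    cols <- max(1L, j - r):min(p, j + r)
    s <- 0; s2sum <- 0; cnt <- 0
    for (jj in rev(cols)) {      # scan order mirrors the box-sum
      cs <- 0; cs2 <- 0          # accumulation so agreement is bitwise
      for (ii in rev(rows)) { cs <- cs + band[ii, jj]; cs2 <- cs2 + band[ii, jj]^2 }
      s <- s + cs; s2sum <- s2sum + cs2; cnt <- cnt + length(rows)
    }
    m <- s / cnt
    v <- max(s2sum / cnt - m^2, 0)
    k <- if (v > 0) max(0, v - s2) / v else 0
    out[i, j] <- m + k * (band[i, j] - m)
  }
  out
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(rbinom(nr * nc, 1L, p), nr, nc)
}

# Noiseless image with a bright axis-aligned rectangle on background.
square_image <- function(n = 64L, from = 23L, to = 42L, bg = 20, fg = 100) {
  img <- matrix(bg, n, n)
  img[from:to, from:to] <- fg
  truth <- matrix(0L, n, n)
  truth[from:to, from:to] <- 1L
  list(image = img, truth = truth)
}

segment_scenario <- function(scenario_name, organ) {
  ph <- generate_phantom(default_scenarios()[[scenario_name]])
  res <- segment_slice(ph$image, ph$suggested_seeds[[organ]])
  list(phantom = ph, result = res,
       metrics = evaluate_masks(res$mask, ph$truth_masks[[organ]]))
}
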
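#' Segmentation pipeline configuration
#'
#' Collects the tunable parameters of [segment_slice()] and
#' [segment_volume()].
#'
#' @param stats_window_radius Radius of the seed-statistics window on the
#'   low band (default 1, i.e. 3x3).
#' @param lee_window_radius Radius of the Lee-filter window on the high
#'   bands (default 1).
#' @param threshold_multiplier Multiplier `c` in `t_high = c * sigma_hat`
#'   (default 3).
#' @param binarize_level Fraction of the object level at which the
#'   reconstruction is binarized, in (0, 1) (default 0.5).
#' @param keep_seed_component Keep only the 4-connected mask component
#'   containing the seed (default `TRUE`).
#' @param fill_holes Fill enclosed holes of the mask; a hole is background
#'   not reachable from the border by an 8-connected path (default `TRUE`).
#' @param rng_seed Integer recorded in provenance manifests. The pipeline
#'   itself is deterministic and draws no random numbers; the seed is kept
#'   so that a manifest fully reproduces a run that also generated inputs.
#' @return Object of class `mwdh_config`.
#' @export
pipeline_config <- function(stats_window_radius = 1L,
                            lee_window_radius = 1L,
                            threshold_multiplier = 3,
                            binarize_level = 0.5,
                            keep_seed_component = TRUE,
                            fill_holes = TRUE,
                            rng_seed = 0L) {
  check_scalar(stats_window_radius, "stats_window_radius", lower = 1)
  check_scalar(lee_window_radius, "lee_window_radius", lower = 1)
  if (threshold_multiplier <= 0) stop_validation("`threshold_multiplier` must be > 0")
  if (binarize_level <= 0 || binarize_level >= 1)
    stop_validation("`binarize_level` must be in (0, 1)")
  structure(list(
    stats_window_radius = as.integer(stats_window_radius),
    lee_window_radius = as.integer(lee_window_radius),
    threshold_multiplier = threshold_multiplier,
    binarize_level = binarize_level,
    keep_seed_component = isTRUE(keep_seed_component),
    fill_holes = isTRUE(fill_holes),
    rng_seed = as.integer(rng_seed)
  ), class = "mwdh_config")
}

#' Segment one slice from a seed point
#'
#' End-to-end wavelet-domain segmentation of a single slice:
#' \enumerate{
#'   \item three-channel analysis into nine sub-bands
#'     ([mwdh_analyze_2d()]);
#'   \item seed statistics on the low band, clustering threshold `t_low`
#'     ([compute_low_threshold()]), and replacement of the low band by a
#'     two-level image: the seed-class mean (the "object level") on the
#'     seed's intensity class, the other class's mean elsewhere;
#'   \item Lee filtering and hard thresholding at
#'     `t_high = c * sigma_hat` of the eight high bands, with `sigma_hat`
#'     estimated from the finest diagonal band ([estimate_noise_sigma()]);
#'   \item wavelet synthesis of the modified bands
#'     ([mwdh_synthesize_2d()]);
#'   \item binarization at the `binarize_level` interpolation between the
#'     two class means (ties resolved as foreground) and mask
#'     postprocessing ([postprocess_mask()]).
#' }
#' The retained high-frequency coefficients sharpen the object boundary in
#' the reconstruction before binarization; on a noiseless two-level image
#' the recovered mask is exact.
#'
#' @param image Numeric matrix, at least 3x3, finite, not constant.
#' @param seed [seed_point()] inside the structure of interest.
#' @param config [pipeline_config()].
#' @param bank Filter bank, see [double_haar_bank()].
#' @return Object of class `mwdh_segmentation`: list with `mask` (binary
#'   matrix), `thresholds` (list `t_low`, `t_high`), `reconstructed` (the
#'   pre-binarization image), `object_level`, `background_level`,
#'   `noise_sigma`, `seed`, `config`.
#' @export
segment_slice <- function(image, seed, config = pipeline_config(),
                          bank = double_haar_bank()) {
  check_image(image)
  check_seed(seed, image)
  if (!inherits(config, "mwdh_config")) stop_validation("`config` must be a pipeline_config()")
  if (diff(range(image)) == 0)
    stop_degenerate("image is constant; nothing to segment")

  bands <- mwdh_analyze_2d(image, bank)
  low <- bands[["00"]]
  stats <- collect_seed_stats(low, seed, config$stats_window_radius)
  t_low <- compute_low_threshold(low, stats)
  indicator <- apply_low_threshold(low, as.numeric(t_low), seed)
  object_level <- mean(low[indicator == 1L])
  background_level <- mean(low[indicator == 0L])

  sigma_hat <- estimate_noise_sigma(bands)
  t_high <- config$threshold_multiplier * sigma_hat
  lp <- lee_params(config$lee_window_radius, sigma_hat, config$threshold_multiplier)

  out <- bands
  # two-level relaxation of the seed-class indicator: both converged class
  # means are kept, so a constant intensity shift of the input moves the
  # reconstruction and the binarization cut together (shift equivariance)
  out[["00"]] <- background_level + (object_level - background_level) * indicator
  for (nm in setdiff(band_names(), "00"))
    out[[nm]] <- apply_high_threshold(lee_filter(bands[[nm]], lp), t_high)

  recon <- mwdh_synthesize_2d(out, bank)
  cut <- background_level + config$binarize_level * (object_level - background_level)
  mask <- if (object_level >= background_level) (recon >= cut) else (recon <= cut)
  mode(mask) <- "integer"
  mask <- postprocess_mask(mask, seed, config)

  structure(list(
    mask = mask,
    thresholds = list(t_low = as.numeric(t_low), t_high = t_high),
    reconstructed = recon,
    object_level = object_level,
    background_level = background_level,
    noise_sigma = sigma_hat,
    seed = seed,
    config = config
  ), class = "mwdh_segmentation")
}

# BFS flood fill over `open` (logical matrix) from linear start indices.
# conn = 4 or 8.
flood_fill <- function(open, start, conn = 4L) {
  n <- nrow(open); p <- ncol(open)
  reach <- matrix(FALSE, n, p)
  frontier <- start[open[start] & !reach[start]]
  reach[frontier] <- TRUE
  while (length(frontier)) {
    rows <- (frontier - 1L) %% n + 1L
    cols <- (frontier - 1L) %/% n + 1L
    cand <- c(frontier[rows > 1L] - 1L, frontier[rows < n] + 1L,
              frontier[cols > 1L] - n, frontier[cols < p] + n)
    if (conn == 8L) {
      ul <- frontier[rows > 1L & cols > 1L]; ur <- frontier[rows > 1L & cols < p]
      dl <- frontier[rows < n & cols > 1L]; dr <- frontier[rows < n & cols < p]
      cand <- c(cand, ul - 1L - n, ur - 1L + n, dl + 1L - n, dr + 1L + n)
    }
    cand <- unique(cand)
    cand <- cand[open[cand] & !reach[cand]]
    reach[cand] <- TRUE
    frontier <- cand
  }
  reach
}

#' Postprocess a binary mask around the seed
#'
#' Optionally keeps only the 4-connected foreground component containing
#' the seed, then fills enclosed holes (background pixels with no
#' 8-connected path to the image border). Signals an empty-result error if
#' the seed pixel itself is background, which callers treat as
#' "segmentation failed here".
#'
#' @param mask Binary (0/1) matrix.
#' @param seed [seed_point()].
#' @param config [pipeline_config()]; only `keep_seed_component` and
#'   `fill_holes` are consulted.
#' @return Binary matrix.
#' @export
postprocess_mask <- function(mask, seed, config = pipeline_config()) {
  check_binary(mask)
  check_seed(seed, mask)
  if (mask[seed$row, seed$col] != 1L)
    stop_empty(sprintf("seed (%d, %d) is not inside the segmented region",
                       seed$row, seed$col))
  if (config$keep_seed_component) {
    labels <- EBImage::bwlabel(mask)  # 4-connected labelling
    mask <- (labels == labels[seed$row, seed$col]) & (mask == 1L)
    mode(mask) <- "integer"
  }
  if (config$fill_holes) {
    n <- nrow(mask); p <- ncol(mask)
    border <- unique(c(seq_len(n), (p - 1L) * n + seq_len(n),
                       (seq_len(p) - 1L) * n + 1L, (seq_len(p) - 1L) * n + n))
    outside <- flood_fill(mask == 0L, border, conn = 8L)
    mask[!outside] <- 1L
  }
  mask
}

mask_centroid <- function(mask) {
  idx <- which(mask == 1L, arr.ind = TRUE)
  seed_point(round(mean(idx[, 1])), round(mean(idx[, 2])))
}

#' Segment an ordered stack of slices with seed propagation
#'
#' Segments the slice containing the user seed first, then walks outward in
#' both directions, seeding each neighbouring slice at the centroid of the
#' previous slice's mask. Propagation in a direction stops at the first
#' slice whose segmentation fails (the propagated centroid lands on
#' background, or the slice is degenerate); that slice and the remaining
#' ones in the direction receive empty masks.
#'
#' @param slices List of equal-shaped numeric matrices, in spatial order.
#' @param seed List with `row`, `col`, `slice` (1-based), or an
#'   `mwdh_seed` plus `slice` attribute; `slice` defaults to 1.
#' @param config [pipeline_config()].
#' @param bank Filter bank.
#' @return List of binary masks, one per slice (empty where propagation
#'   terminated), with attribute `results` holding the per-slice
#'   `mwdh_segmentation` objects (or `NULL` where segmentation failed).
#' @export
segment_volume <- function(slices, seed, config = pipeline_config(),
                           bank = double_haar_bank()) {
  if (!is.list(slices) || length(slices) == 0L)
    stop_validation("`slices` must be a non-empty list of matrices")
  dims <- lapply(slices, dim)
  if (length(unique(dims)) != 1L)
    stop_shape("all slices must have the same shape")
  k0 <- if (!is.null(seed$slice)) as.integer(seed$slice) else 1L
  if (k0 < 1L || k0 > length(slices))
    stop_index(sprintf("seed slice %d outside stack of %d", k0, length(slices)))
  s0 <- seed_point(seed$row, seed$col)

  n_slices <- length(slices)
  empty <- matrix(0L, dims[[1]][1], dims[[1]][2])
  masks <- rep(list(empty), n_slices)
  results <- vector("list", n_slices)

  try_segment <- function(k, sd) {
    tryCatch(segment_slice(slices[[k]], sd, config, bank),
             mwdhseg_empty_result_error = function(e) NULL,
             mwdhseg_degenerate_error = function(e) NULL)
  }

  first <- segment_slice(slices[[k0]], s0, config, bank)
  masks[[k0]] <- first$mask
  results[[k0]] <- first

  for (dir in c(-1L, 1L)) {
    prev <- first$mask
    k <- k0 + dir
    while (k >= 1L && k <= n_slices) {
      sd <- mask_centroid(prev)
      res <- try_segment(k, sd)
      if (is.null(res)) {
        message(sprintf("slice %d: segmentation terminated (seed fell on background)", k))
        break
      }
      masks[[k]] <- res$mask
      results[[k]] <- res
      prev <- res$mask
      k <- k + dir
    }
  }
  structure(masks, results = results)
}
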
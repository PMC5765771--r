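#' Double-Haar three-channel filter bank
#'
#' Constructs the analysis/synthesis taps of the undecimated three-channel
#' double-Haar filter bank: one low-pass channel and two high-pass channels,
#' obtained by cascading two Haar stages. The taps have length 3, so one
#' level of the separable 2D transform is exactly a 3x3 moving-window
#' transform of the image.
#'
#' The bank satisfies the perfect-reconstruction identity
#' \eqn{\sum_i G_i(z) H_i(z) = z^{-d}} with overall delay \eqn{d = 2};
#' the delay is compensated internally by center-aligning all filtering,
#' so [mwdh_synthesize_1d()] applied to [mwdh_analyze_1d()] returns the
#' input unchanged (to floating-point precision, including at the image
#' border under the symmetric extension used throughout).
#'
#' @return An object of class `mwdh_filter_bank`: a list with elements
#'   `analysis` (taps `h0`, `h1`, `h2`), `synthesis` (taps `g0`, `g1`,
#'   `g2`), `delay` (integer, 2) and `symmetry` (`+1` for the symmetric
#'   channels 0 and 2, `-1` for the antisymmetric channel 1; used to pick
#'   the boundary extension of each channel during synthesis).
#' @examples
#' bank <- double_haar_bank()
#' reconstruction_defect(bank)  # ~1e-17
#' @seealso [mwdh_analyze_2d()], [reconstruction_defect()]
#' @export
double_haar_bank <- function() {
  structure(list(
    analysis = list(
      h0 = c(1, 2, 1) / 4,
      h1 = c(1, 0, -1) / 2,
      h2 = c(1, -2, 1) / 4
    ),
    synthesis = list(
      g0 = c(1, 2, 1) / 4,
      g1 = c(-1, 0, 1) / 4,
      g2 = c(1, -2, 1) / 4
    ),
    delay = 2L,
    symmetry = c(1, -1, 1)
  ), class = "mwdh_filter_bank")
}

#' Numerical defect of the perfect-reconstruction identity
#'
#' Convolves each analysis tap list with its synthesis counterpart, sums the
#' three products, and measures the maximum absolute deviation from a pure
#' delay impulse. Zero (to machine precision) certifies that analysis
#' followed by synthesis is the identity on unbounded signals.
#'
#' @param bank A filter bank, see [double_haar_bank()].
#' @return Maximum absolute deviation from the delayed unit impulse.
#' @export
reconstruction_defect <- function(bank = double_haar_bank()) {
  validate_bank(bank)
  total <- Reduce(`+`, Map(function(h, g) convolve_full(h, g),
                           bank$analysis, bank$synthesis))
  delta <- numeric(length(total))
  delta[bank$delay + 1L] <- 1
  max(abs(total - delta))
}

convolve_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

validate_bank <- function(bank) {
  if (!inherits(bank, "mwdh_filter_bank"))
    stop_validation("`bank` must be an mwdh_filter_bank")
  h <- bank$analysis
  if (abs(sum(h$h0) - 1) > 1e-12 || abs(sum(h$h1)) > 1e-12 || abs(sum(h$h2)) > 1e-12)
    stop_validation("analysis taps must have sums (1, 0, 0)")
  invisible(bank)
}

# Center-aligned correlation with symmetric boundary extension, applied
# along one axis of a matrix (axis 1: down the row index, each column a
# signal; axis 2: across the column index). `sym = +1` extends by edge
# mirroring x(0) = x(1) (half-sample symmetry); `sym = -1` extends
# antisymmetrically x(0) = -x(1), the natural extension of a channel
# produced by an antisymmetric filter from a symmetrically extended signal.
filter_axis <- function(m, taps, sym = 1, axis = 1L) {
  L <- length(taps)
  if (L %% 2L == 0L) stop_validation("taps must have odd length")
  rad <- (L - 1L) %/% 2L
  if (axis == 2L) return(t(filter_axis(t(m), taps, sym, 1L)))
  n <- nrow(m)
  if (n < L) stop_mwdhseg("signal shorter than filter support", "mwdhseg_shape_error")
  top <- sym * m[rad:1, , drop = FALSE]
  bot <- sym * m[n:(n - rad + 1L), , drop = FALSE]
  p <- rbind(top, m, bot)
  out <- matrix(0, n, ncol(m))
  for (k in seq_len(L))
    out <- out + taps[k] * p[k:(k + n - 1L), , drop = FALSE]
  out
}

filter_vec <- function(x, taps, sym = 1) {
  drop(filter_axis(matrix(x, ncol = 1L), taps, sym, 1L))
}

#' One-dimensional three-channel analysis
#'
#' Splits a signal into one low-frequency channel (`x0`) and two
#' high-frequency channels (`x1`, `x2`) by center-aligned correlation with
#' the analysis taps under symmetric (mirror) boundary extension. No
#' subsampling is performed, so every channel has the length of the input
#' (undecimated, moving-window realization).
#'
#' @param signal Numeric vector, at least as long as the longest tap list.
#' @param bank Filter bank, see [double_haar_bank()].
#' @return Object of class `mwdh_channels`: list with elements `x0`, `x1`,
#'   `x2`, each the length of `signal`.
#' @examples
#' ch <- mwdh_analyze_1d(c(5, 5, 5, 5, 5))
#' ch$x1  # zero: constants are annihilated by the zero-sum high-pass taps
#' @export
mwdh_analyze_1d <- function(signal, bank = double_haar_bank()) {
  validate_bank(bank)
  if (!is.numeric(signal) || !all(is.finite(signal)))
    stop_validation("`signal` must be a finite numeric vector")
  L <- max(lengths(bank$analysis))
  if (length(signal) < L)
    stop_shape(sprintf("signal length %d is shorter than the filter support %d",
                       length(signal), L))
  structure(list(
    x0 = filter_vec(signal, bank$analysis$h0),
    x1 = filter_vec(signal, bank$analysis$h1),
    x2 = filter_vec(signal, bank$analysis$h2)
  ), class = "mwdh_channels")
}

#' One-dimensional three-channel synthesis
#'
#' Delay-compensated sum of the three synthesis-filtered channels. For
#' channels produced by [mwdh_analyze_1d()] and left untouched, the output
#' equals the original signal. Each channel is boundary-extended according
#' to its natural symmetry (`bank$symmetry`), which makes the round trip
#' exact at the signal ends as well.
#'
#' @param channels `mwdh_channels` (or a plain list with `x0`, `x1`, `x2`).
#' @param bank Filter bank.
#' @return Numeric vector of the common channel length.
#' @export
mwdh_synthesize_1d <- function(channels, bank = double_haar_bank()) {
  validate_bank(bank)
  xs <- channels[c("x0", "x1", "x2")]
  if (any(vapply(xs, is.null, logical(1))))
    stop_shape("`channels` must contain x0, x1, x2")
  if (length(unique(lengths(xs))) != 1L)
    stop_shape("channels must all have the same length")
  g <- bank$synthesis
  filter_vec(xs$x0, g$g0, bank$symmetry[1]) +
    filter_vec(xs$x1, g$g1, bank$symmetry[2]) +
    filter_vec(xs$x2, g$g2, bank$symmetry[3])
}

band_names <- function() {
  as.vector(outer(0:2, 0:2, function(r, c) paste0(r, c)))
}

#' Separable two-dimensional analysis into nine sub-bands
#'
#' Applies the three analysis channels along the row axis and then along
#' the column axis, producing nine same-sized coefficient planes named
#' `"rc"` for row channel `r` and column channel `c` in `{0, 1, 2}`. Band
#' `"00"` is the low-frequency sub-band (a 3x3-smoothed copy of the image
#' that preserves its mean); the remaining eight are high-frequency
#' sub-bands and are exactly zero on constant images.
#'
#' @param image Numeric matrix, at least 3x3, all values finite.
#' @param bank Filter bank.
#' @return Object of class `mwdh_subbands`: named list of 9 matrices with
#'   the shape of `image`.
#' @examples
#' b <- mwdh_analyze_2d(matrix(7, 8, 8))
#' range(b[["00"]])  # 7 7
#' max(abs(b[["12"]]))  # 0
#' @export
mwdh_analyze_2d <- function(image, bank = double_haar_bank()) {
  validate_bank(bank)
  check_image(image)
  h <- bank$analysis
  rows <- lapply(h, function(taps) filter_axis(image, taps, 1, axis = 1L))
  bands <- list()
  for (r in 0:2) for (cc in 0:2)
    bands[[paste0(r, cc)]] <- filter_axis(rows[[r + 1L]], h[[cc + 1L]], 1, axis = 2L)
  structure(bands, class = "mwdh_subbands", dim_image = dim(image))
}

#' Separable two-dimensional synthesis from nine sub-bands
#'
#' Reconstructs an image from a (possibly modified) nine-band set by
#' synthesis filtering along both axes and summing. The map is linear in
#' the bands and inverts [mwdh_analyze_2d()] exactly when the bands are
#' untouched.
#'
#' @param bands `mwdh_subbands`, or a named list of 9 equal-shaped matrices
#'   with names `"00"` ... `"22"`.
#' @param bank Filter bank.
#' @return Numeric matrix with the bands' common shape.
#' @export
mwdh_synthesize_2d <- function(bands, bank = double_haar_bank()) {
  validate_bank(bank)
  nm <- band_names()
  if (!all(nm %in% names(bands)))
    stop_shape("`bands` must contain the 9 bands \"00\" ... \"22\"")
  dims <- lapply(nm, function(b) dim(bands[[b]]))
  if (length(unique(dims)) != 1L || is.null(dims[[1]]))
    stop_shape("all 9 bands must be matrices of the same shape")
  g <- bank$synthesis
  sym <- bank$symmetry
  out <- matrix(0, dims[[1]][1], dims[[1]][2])
  for (r in 0:2) for (cc in 0:2) {
    w <- filter_axis(bands[[paste0(r, cc)]], g[[cc + 1L]], sym[cc + 1L], axis = 2L)
    out <- out + filter_axis(w, g[[r + 1L]], sym[r + 1L], axis = 1L)
  }
  out
}
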
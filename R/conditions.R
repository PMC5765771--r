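# Classed conditions so callers can distinguish recoverable failures
# (e.g. an empty segmentation during slice propagation) from programming
# errors. All inherit from "mwdhseg_error".

stop_mwdhseg <- function(message, class) {
  stop(structure(
    class = c(class, "mwdhseg_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_validation <- function(message) stop_mwdhseg(message, "mwdhseg_validation_error")
stop_shape      <- function(message) stop_mwdhseg(message, "mwdhseg_shape_error")
stop_index      <- function(message) stop_mwdhseg(message, "mwdhseg_index_error")
stop_degenerate <- function(message) stop_mwdhseg(message, "mwdhseg_degenerate_error")
stop_empty      <- function(message) stop_mwdhseg(message, "mwdhseg_empty_result_error")
stop_format     <- function(message) stop_mwdhseg(message, "mwdhseg_format_error")
stop_metric     <- function(message) stop_mwdhseg(message, "mwdhseg_metric_error")

check_image <- function(image, min_dim = 3L, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation(sprintf("`%s` must be a numeric matrix", arg))
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_validation(sprintf("`%s` must be at least %dx%d", arg, min_dim, min_dim))
  if (!all(is.finite(image)))
    stop_validation(sprintf("`%s` contains non-finite values", arg))
  invisible(image)
}

check_binary <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop_validation(sprintf("`%s` must be a binary (0/1) matrix", arg))
  invisible(mask)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_validation(sprintf("`%s` must be a finite scalar in [%s, %s]", arg, lower, upper))
  invisible(x)
}

# Run `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
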
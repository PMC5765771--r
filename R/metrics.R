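#' Overlap metrics between a segmentation and its ground truth
#'
#' Computes the four standard overlap quantities between a segmented mask
#' `V_seg` and an expert ground-truth mask `V_ground`:
#' \itemize{
#'   \item Dice similarity coefficient
#'     `DSC = 2 |V_seg on V_ground| / (|V_seg| + |V_ground|)`, in `[0, 1]`
#'     (0 no overlap, 1 complete overlap);
#'   \item `Sensitivity = |V_seg on V_ground| / |V_ground|`;
#'   \item `Inclusiveness = |V_seg on V_ground| / |V_seg|`, the
#'     probability that a segmented pixel truly belongs to the structure;
#'   \item `Delta V = (|V_seg| - |V_ground|) / |V_ground| * 100`, the
#'     signed percent volume difference.
#' }
#' DSC is the harmonic mean of sensitivity and inclusiveness whenever both
#' are positive.
#'
#' @param seg,ground Binary (0/1) matrices (or arrays) of equal shape;
#'   `ground` must be non-empty.
#' @param signed_delta_v If `FALSE`, report `|Delta V|` instead of the
#'   signed value (reporting parity with clinical tables that print
#'   magnitudes).
#' @return Object of class `mwdh_metrics`: list with `dsc`, `sensitivity`,
#'   `inclusiveness`, `delta_v_percent`, `v_seg`, `v_ground`, `v_overlap`,
#'   `empty_seg` (flag: an empty segmentation has undefined inclusiveness,
#'   reported as 0).
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2); b <- matrix(c(1, 0, 1, 0), 2)
#' evaluate_masks(a, b)$dsc  # 0.5
#' @export
evaluate_masks <- function(seg, ground, signed_delta_v = TRUE) {
  if (!identical(dim(seg), dim(ground)))
    stop_shape("`seg` and `ground` must have the same shape")
  if (!all(seg %in% c(0, 1)) || !all(ground %in% c(0, 1)))
    stop_validation("masks must be binary (0/1)")
  v_seg <- sum(seg == 1)
  v_ground <- sum(ground == 1)
  if (v_ground == 0L)
    stop_metric("ground truth is empty; overlap metrics are undefined")
  v_overlap <- sum(seg == 1 & ground == 1)
  empty_seg <- v_seg == 0L
  dsc <- 2 * v_overlap / (v_seg + v_ground)
  sensitivity <- v_overlap / v_ground
  inclusiveness <- if (empty_seg) 0 else v_overlap / v_seg
  delta_v <- (v_seg - v_ground) / v_ground * 100
  if (!signed_delta_v) delta_v <- abs(delta_v)
  structure(list(
    dsc = dsc, sensitivity = sensitivity, inclusiveness = inclusiveness,
    delta_v_percent = delta_v,
    v_seg = v_seg, v_ground = v_ground, v_overlap = v_overlap,
    empty_seg = empty_seg
  ), class = "mwdh_metrics")
}

#' @export
print.mwdh_metrics <- function(x, ...) {
  cat(sprintf("DSC %.3f | sensitivity %.3f | inclusiveness %.3f | dV %+.2f%% (seg %d / truth %d px)\n",
              x$dsc, x$sensitivity, x$inclusiveness, x$delta_v_percent,
              x$v_seg, x$v_ground))
  invisible(x)
}

#' Evaluate a batch of mask pairs
#'
#' Runs [evaluate_masks()] on each case and assembles one row per case.
#' Per-case failures (shape mismatch, empty ground truth) are captured in
#' the `error` column instead of aborting the batch.
#'
#' @param cases List of cases; each a list with elements `seg`, `ground`
#'   and optionally `label`.
#' @param signed_delta_v Passed to [evaluate_masks()].
#' @return `data.frame` with columns `label`, `dsc`, `sensitivity`,
#'   `inclusiveness`, `delta_v_percent`, `v_seg`, `v_ground`, `v_overlap`,
#'   `error` (`NA` for successful rows).
#' @export
batch_evaluate <- function(cases, signed_delta_v = TRUE) {
  cols <- c("label", "dsc", "sensitivity", "inclusiveness",
            "delta_v_percent", "v_seg", "v_ground", "v_overlap", "error")
  if (length(cases) == 0L) {
    out <- data.frame(label = character(), dsc = numeric(),
                      sensitivity = numeric(), inclusiveness = numeric(),
                      delta_v_percent = numeric(), v_seg = integer(),
                      v_ground = integer(), v_overlap = integer(),
                      error = character(), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  rows <- lapply(seq_along(cases), function(i) {
    case <- cases[[i]]
    label <- if (!is.null(case$label)) as.character(case$label) else sprintf("case_%d", i)
    res <- tryCatch(evaluate_masks(case$seg, case$ground, signed_delta_v),
                    mwdhseg_error = function(e) e)
    if (inherits(res, "condition")) {
      data.frame(label = label, dsc = NA_real_, sensitivity = NA_real_,
                 inclusiveness = NA_real_, delta_v_percent = NA_real_,
                 v_seg = NA_integer_, v_ground = NA_integer_,
                 v_overlap = NA_integer_, error = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = label, dsc = res$dsc, sensitivity = res$sensitivity,
                 inclusiveness = res$inclusiveness,
                 delta_v_percent = res$delta_v_percent,
                 v_seg = res$v_seg, v_ground = res$v_ground,
                 v_overlap = res$v_overlap, error = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)[, cols]
}

metrics_report_columns <- c("label", "dsc", "sensitivity", "inclusiveness",
                            "delta_v_percent", "v_seg", "v_ground")

#' Write a metrics table to CSV
#'
#' Fixed column order: `label`, `dsc`, `sensitivity`, `inclusiveness`,
#' `delta_v_percent`, `v_seg`, `v_ground`.
#'
#' @param table Output of [batch_evaluate()] (or a compatible data frame).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(table, path) {
  utils::write.csv(table[, metrics_report_columns, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a metrics table to JSON
#'
#' @inheritParams write_metrics_csv
#' @export
write_metrics_json <- function(table, path) {
  jsonlite::write_json(table[, metrics_report_columns, drop = FALSE], path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
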
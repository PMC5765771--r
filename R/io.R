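# Image input/output. PNG reading goes through libpng (the png package),
# which also decodes 16-bit files; writing 16-bit grayscale PNG is done by
# a small in-package encoder because png::writePNG emits 8-bit only.
# NIfTI goes through RNifti. DICOM reading is a minimal parser for
# uncompressed little-endian series (explicit or implicit VR), the common
# export format of CBCT consoles.

crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    c <- bitwXor(bitwShiftR(c, 8L), crc32_table[bitwAnd(bitwXor(c, b[i]), 255L) + 1L])
  bitwXor(c, -1L)
}

uint32_be <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "big")

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32(body)))
}

#' Write a grayscale PNG (8- or 16-bit)
#'
#' Values must be integers in `[0, 2^bit_depth - 1]`; they are written
#' losslessly, so a write/read round trip reproduces the pixel values
#' exactly.
#'
#' @param image Numeric matrix of integer-valued intensities.
#' @param path Destination file.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_png_gray <- function(image, path, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) stop_validation("`bit_depth` must be 8 or 16")
  check_image(image, min_dim = 1L)
  maxv <- 2^bit_depth - 1
  if (any(image != round(image)) || any(image < 0) || any(image > maxv))
    stop_validation(sprintf("pixel values must be integers in [0, %d]", maxv))
  h <- nrow(image); w <- ncol(image)
  rows <- lapply(seq_len(h), function(r) {
    v <- as.integer(image[r, ])
    if (bit_depth == 16L) c(as.raw(0L), as.raw(rbind(v %/% 256L, v %% 256L)))
    else c(as.raw(0L), as.raw(v))
  })
  stream <- unlist(rows)
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(bit_depth, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(stream, type = "gzip")),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

read_png_gray <- function(path) {
  r <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) stop_format(sprintf("cannot parse PNG: %s", path)))
  depth <- attr(r, "info")$bit.depth
  if (length(dim(r)) == 3L) {
    if (dim(r)[3] >= 3L &&
        max(abs(r[, , 1] - r[, , 2]), abs(r[, , 1] - r[, , 3])) > 0)
      stop_format(sprintf("PNG is not grayscale: %s", path))
    r <- r[, , 1]
  }
  round(r * (2^depth - 1))
}

#' Read an image as a numeric matrix (or slice stack)
#'
#' Supported formats: 8/16-bit grayscale PNG, NIfTI-1 (`.nii`,
#' `.nii.gz`), or a directory holding an uncompressed little-endian DICOM
#' series. PNG intensities are returned on their integer scale
#' (`0 ... 2^depth - 1`); DICOM values have the rescale slope/intercept
#' applied; NIfTI values are returned as stored. Multi-slice inputs
#' (3D NIfTI, DICOM series) are returned as a list of matrices in spatial
#' order.
#'
#' @param path File (PNG/NIfTI) or directory (DICOM series).
#' @param format `"auto"` (by extension / file type) or one of `"png"`,
#'   `"nifti"`, `"dicom"`.
#' @return Numeric matrix, or list of matrices for a stack.
#' @export
read_image <- function(path, format = c("auto", "png", "nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("no such file or directory: %s", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom"
    else if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop_format(sprintf("cannot infer image format of: %s", path))
  }
  switch(format,
    png = read_png_gray(path),
    nifti = {
      a <- tryCatch(as.array(RNifti::readNifti(path)),
                    error = function(e) stop_format(sprintf("cannot parse NIfTI: %s", path)))
      d <- dim(a)
      d <- d[d > 1L]
      a <- array(a, dim = if (length(d)) d else c(1L, 1L))
      if (length(dim(a)) == 2L) a
      else if (length(dim(a)) == 3L)
        lapply(seq_len(dim(a)[3]), function(k) a[, , k])
      else stop_format(sprintf("NIfTI with >3 non-singleton dimensions: %s", path))
    },
    dicom = read_dicom_series(path)
  )
}

# --- minimal DICOM reading ---------------------------------------------

dcm_u16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
dcm_u32 <- function(raw, at) {
  as.numeric(as.integer(raw[at])) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}
dcm_str <- function(val) trimws(rawToChar(val[val != as.raw(0)]))

read_dicom_file <- function(path) {
  n_bytes <- file.size(path)
  raw <- readBin(path, "raw", n_bytes)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop_format(sprintf("not a DICOM part-10 file: %s", path))
  pos <- 133L
  explicit_body <- TRUE
  tags <- new.env(parent = emptyenv())
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    g <- dcm_u16(raw, pos); e <- dcm_u16(raw, pos + 2L)
    expl <- if (g == 2L) TRUE else explicit_body
    if (expl) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) { len <- dcm_u32(raw, pos + 8L); vstart <- pos + 12L }
      else { len <- dcm_u16(raw, pos + 6L); vstart <- pos + 8L }
    } else { vr <- ""; len <- dcm_u32(raw, pos + 4L); vstart <- pos + 8L }
    if (len >= 4294967295) stop_format(sprintf("undefined-length element in: %s", path))
    if (vstart + len - 1L > length(raw)) stop_format(sprintf("truncated DICOM: %s", path))
    val <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", g, e)
    assign(key, list(vr = vr, value = val), envir = tags)
    if (key == "0002,0010") {
      ts <- dcm_str(val)
      if (ts == "1.2.840.10008.1.2") explicit_body <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop_format(sprintf("unsupported transfer syntax %s in: %s", ts, path))
    }
    pos <- vstart + as.integer(len)
  }
  get_tag <- function(key) if (exists(key, envir = tags)) get(key, envir = tags) else NULL
  need <- function(key, what) {
    t <- get_tag(key)
    if (is.null(t)) stop_format(sprintf("DICOM misses %s (%s): %s", key, what, path))
    t
  }
  rows <- dcm_u16(need("0028,0010", "Rows")$value, 1L)
  cols <- dcm_u16(need("0028,0011", "Columns")$value, 1L)
  bits <- dcm_u16(need("0028,0100", "BitsAllocated")$value, 1L)
  if (!bits %in% c(8L, 16L)) stop_format(sprintf("unsupported BitsAllocated %d: %s", bits, path))
  signed <- !is.null(get_tag("0028,0103")) && dcm_u16(get_tag("0028,0103")$value, 1L) == 1L
  slope <- if (!is.null(get_tag("0028,1053"))) as.numeric(dcm_str(get_tag("0028,1053")$value)) else 1
  intercept <- if (!is.null(get_tag("0028,1052"))) as.numeric(dcm_str(get_tag("0028,1052")$value)) else 0
  px <- need("7fe0,0010", "PixelData")$value
  v <- readBin(px, "integer", n = rows * cols, size = bits %/% 8L,
               signed = if (bits == 8L) FALSE else signed, endian = "little")
  if (bits == 16L && !signed) v <- v + (v < 0) * 65536  # readBin size-2 unsigned workaround
  img <- matrix(v, nrow = rows, byrow = TRUE) * slope + intercept
  zpos <- if (!is.null(get_tag("0020,0032"))) {
    parts <- strsplit(dcm_str(get_tag("0020,0032")$value), "\\\\")[[1]]
    if (length(parts) >= 3) as.numeric(parts[3]) else NA_real_
  } else NA_real_
  inst <- if (!is.null(get_tag("0020,0013"))) as.numeric(dcm_str(get_tag("0020,0013")$value)) else NA_real_
  list(image = img, z = zpos, instance = inst)
}

#' Read a DICOM series directory as an ordered slice stack
#'
#' Parses every regular file in `path` as an uncompressed little-endian
#' DICOM image, applies the rescale slope/intercept, and orders slices by
#' the z component of Image Position (Patient), falling back to Instance
#' Number.
#'
#' @param path Directory containing the series.
#' @return List of numeric matrices (a single matrix for a one-file
#'   series).
#' @export
read_dicom_series <- function(path) {
  if (!dir.exists(path)) stop_format(sprintf("not a directory: %s", path))
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop_format(sprintf("empty DICOM directory: %s", path))
  parsed <- lapply(sort(files), read_dicom_file)
  z <- vapply(parsed, `[[`, numeric(1), "z")
  inst <- vapply(parsed, `[[`, numeric(1), "instance")
  ord <- if (!anyNA(z)) order(z) else if (!anyNA(inst)) order(inst) else seq_along(parsed)
  slices <- lapply(parsed[ord], `[[`, "image")
  if (length(slices) == 1L) slices[[1L]] else slices
}

# --- writing results ----------------------------------------------------

#' Write an image to PNG (integer scale) or NIfTI
#'
#' @param image Numeric matrix.
#' @param path Destination; format chosen by extension (`.png`, `.nii`,
#'   `.nii.gz`).
#' @param bit_depth PNG bit depth (8 or 16); ignored for NIfTI.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  if (grepl("\\.png$", path, ignore.case = TRUE))
    write_png_gray(image, path, bit_depth)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    RNifti::writeNifti(RNifti::asNifti(image), path)
  else stop_format(sprintf("cannot infer output format of: %s", path))
  invisible(path)
}

#' Write a binary mask
#'
#' PNG masks are written as 0/255 (8-bit) for viewer compatibility, NIfTI
#' masks as 0/1.
#'
#' @param mask Binary (0/1) matrix.
#' @param path Destination (`.png`, `.nii`, `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_binary(mask)
  if (grepl("\\.png$", path, ignore.case = TRUE))
    write_png_gray(mask * 255, path, 8L)
  else write_image(mask + 0, path)
  invisible(path)
}

json_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Write segmentation or evaluation outputs with a provenance manifest
#'
#' For a segmentation result, writes the mask (`mask.png` or
#' `mask.nii.gz`) and a `manifest.json` echoing the thresholds, the seed,
#' the configuration and its hash. For a metrics table
#' ([batch_evaluate()]), writes `metrics.csv` or `metrics.json`. Outputs
#' are deterministic: re-running with identical inputs reproduces
#' byte-identical files.
#'
#' @param x An `mwdh_segmentation` or a metrics `data.frame`.
#' @param out_dir Output directory (created if missing).
#' @param format `"png"` or `"nifti"` for masks; `"csv"` or `"json"` for
#'   metrics tables.
#' @return The manifest (a list), invisibly.
#' @export
write_outputs <- function(x, out_dir, format = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_format(sprintf("cannot create directory: %s", out_dir))
  if (inherits(x, "mwdh_segmentation")) {
    format <- if (is.null(format)) "png" else match.arg(format, c("png", "nifti"))
    mask_file <- file.path(out_dir, if (format == "png") "mask.png" else "mask.nii.gz")
    write_mask(x$mask, mask_file)
    manifest <- list(
      kind = "segmentation",
      mask = basename(mask_file),
      t_low = x$thresholds$t_low,
      t_high = x$thresholds$t_high,
      object_level = x$object_level,
      noise_sigma = x$noise_sigma,
      seed = list(row = x$seed$row, col = x$seed$col),
      config = unclass(x$config),
      config_hash = json_hash(unclass(x$config))
    )
  } else if (is.data.frame(x)) {
    format <- if (is.null(format)) "csv" else match.arg(format, c("csv", "json"))
    report <- file.path(out_dir, paste0("metrics.", format))
    if (format == "csv") write_metrics_csv(x, report) else write_metrics_json(x, report)
    manifest <- list(kind = "evaluation", report = basename(report),
                     n_cases = nrow(x))
  } else stop_validation("`x` must be an mwdh_segmentation or a metrics data.frame")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
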
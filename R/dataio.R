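# Image and annotation I/O, plus the fixed preprocessing applied to every
# frame before analysis: conversion to single-channel and resize to 256x256.

#' Validate an ultrasound image matrix
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in `[0, 255]`, row = y (downward), column = x (rightward), 0-based
#' coordinates in the API (pixel (x, y) at `pixels[y + 1, x + 1]`).
#'
#' @param pixels numeric matrix of intensities.
#' @return the validated matrix (invisibly unchanged).
#' @export
us_image <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    stop("image must be a nonempty numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("image intensities must lie in [0, 255]")
  pixels
}

#' Bilinear resize of an intensity image
#'
#' Pixel-centre aligned bilinear interpolation (the conventional default for
#' intensity imagery). Resizing to the input size returns the input exactly.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return numeric matrix `out_h` x `out_w`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  in_h <- nrow(img); in_w <- ncol(img)
  stopifnot(in_h >= 1, in_w >= 1, out_h >= 1, out_w >= 1)
  yc <- (seq_len(out_h) - 0.5) * (in_h / out_h) - 0.5
  xc <- (seq_len(out_w) - 0.5) * (in_w / out_w) - 0.5
  y0 <- pmin(pmax(floor(yc), 0), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(pmax(floor(xc), 0), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- pmin(pmax(yc - y0, 0), 1); wx <- pmin(pmax(xc - x0, 0), 1)
  A <- img[y0 + 1, x0 + 1, drop = FALSE]; B <- img[y0 + 1, x1 + 1, drop = FALSE]
  C <- img[y1 + 1, x0 + 1, drop = FALSE]; D <- img[y1 + 1, x1 + 1, drop = FALSE]
  Wy <- matrix(wy, out_h, out_w)
  Wx <- matrix(wx, out_h, out_w, byrow = TRUE)
  (1 - Wy) * ((1 - Wx) * A + Wx * B) + Wy * ((1 - Wx) * C + Wx * D)
}

#' Preprocess a raw frame to the 256x256 analysis format
#'
#' Three-channel input is converted to luminance (0.299 R + 0.587 G +
#' 0.114 B) first, then the frame is stretched (not letterboxed) to
#' 256 x 256 by bilinear interpolation. Anisotropic inputs therefore use
#' per-axis scale factors `256/W` and `256/H`, and any annotation given in
#' the raw frame is rescaled by the same factors.
#'
#' @param raw numeric matrix (grayscale) or H x W x 3 array (RGB),
#'   intensities in `[0, 255]`.
#' @param apex optional `(x, y)` annotation in raw-frame 0-based pixels.
#' @param size output side length in pixels (default 256).
#' @return list with `image` (size x size matrix), `apex` (rescaled, or
#'   NULL) and `scale` (`c(sx, sy)`).
#' @export
preprocess_image <- function(raw, apex = NULL, size = 256L) {
  if (is.array(raw) && length(dim(raw)) == 3L) {
    if (dim(raw)[3] == 1L) {
      raw <- raw[, , 1]
    } else if (dim(raw)[3] >= 3L) {
      raw <- 0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else stop("expected 1 or 3 channels")
  }
  raw <- us_image(raw)
  sx <- size / ncol(raw); sy <- size / nrow(raw)
  out <- resize_bilinear(raw, size, size)
  out <- pmin(pmax(out, 0), 255)
  if (!is.null(apex)) {
    apex <- rescale_annotation(apex, from = dim(raw)[c(2, 1)], to = c(size, size))
  }
  list(image = out, apex = apex, scale = c(sx, sy))
}

#' Rescale an (x, y) annotation between image sizes
#'
#' @param apex `(x, y)` 0-based coordinates.
#' @param from,to `(width, height)` of source and destination frames.
#' @return rescaled `(x, y)`.
#' @export
rescale_annotation <- function(apex, from, to) {
  c(apex[1] * to[1] / from[1], apex[2] * to[2] / from[2])
}

#' Read / write 8-bit grayscale PNG images
#'
#' Intensities are mapped between `[0, 255]` (package convention) and the
#' `[0, 1]` scale used on disk. Multi-channel PNGs are returned as arrays
#' scaled to `[0, 255]` and can be collapsed by [preprocess_image()].
#'
#' @param path file path.
#' @param img numeric matrix in `[0, 255]`.
#' @return `read_image_png`: matrix or array in `[0, 255]`;
#'   `write_image_png`: `path`, invisibly.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  px <- png::readPNG(path)
  px * 255
}

#' @rdname read_image_png
#' @export
write_image_png <- function(img, path) {
  img <- us_image(round(img))
  png::writePNG(img / 255, path)
  invisible(path)
}

manifest_columns <- c("path", "apex_x", "apex_y", "iliac_angle_deg",
                      "alpha_deg", "ddh_label", "qualified_label", "seed")

#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per frame and columns `path, apex_x,
#' apex_y, iliac_angle_deg, alpha_deg, ddh_label, qualified_label, seed`
#' (extra columns are preserved). An empty file yields an empty dataset.
#'
#' @param path CSV path.
#' @return data.frame of frames.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  if (file.size(path) == 0L)
    return(empty_manifest())
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  df$ddh_label <- as.logical(df$ddh_label)
  df$qualified_label <- as.logical(df$qualified_label)
  df
}

empty_manifest <- function() {
  df <- data.frame(path = character(), apex_x = double(), apex_y = double(),
                   iliac_angle_deg = double(), alpha_deg = double(),
                   ddh_label = logical(), qualified_label = logical(),
                   seed = integer(), stringsAsFactors = FALSE)
  df
}

#' Write a cohort manifest or a results table
#'
#' `write_manifest` checks the manifest schema; `write_results` writes any
#' record table as CSV (or JSON lines when the path ends in `.jsonl`).
#'
#' @param df data.frame of records.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
write_results <- function(df, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
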
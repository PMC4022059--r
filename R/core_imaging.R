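#' Calibrated grayscale image
#'
#' The basic data container of the package: a 2-D grid of real-valued
#' grayscale intensities (nominally on the 0--255 scale) together with the
#' physical length of one pixel edge.  All downstream measurements that carry
#' physical units (areas, perimeters, wall thicknesses) are derived from
#' `pixel_length`.
#'
#' Intensities are held as doubles and never re-quantized to 8-bit: rescaling
#' and standard deviations are therefore exact, avoiding quantization bias in
#' the roughness statistic.
#'
#' @param pixels numeric matrix of intensities; rows are image rows (y),
#'   columns are image columns (x).  All values must be finite.
#' @param pixel_length physical length of one pixel edge, `> 0`.
#' @param units unit tag for `pixel_length` (e.g. `"um"`, `"mm"`).
#' @param source_id free-text provenance label.
#' @return an object of class `calibrated_image` with fields `pixels`,
#'   `pixel_length`, `units`, `source_id`.
#' @examples
#' img <- calibrated_image(matrix(0:99, 10, 10), pixel_length = 0.1, units = "um")
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, pixel_length, units = "um", source_id = "") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("all pixel intensities must be finite")
  if (!is.numeric(pixel_length) || length(pixel_length) != 1L ||
      !is.finite(pixel_length) || pixel_length <= 0)
    stop("pixel_length must be a single positive finite number")
  structure(
    list(pixels = pixels, pixel_length = as.numeric(pixel_length),
         units = as.character(units), source_id = as.character(source_id)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, pixel_length = %g %s/px",
              nrow(x$pixels), ncol(x$pixels), x$pixel_length, x$units))
  if (nzchar(x$source_id)) cat(sprintf(", source = %s", x$source_id))
  cat(sprintf("\n  intensity range [%g, %g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Rectangular region of interest
#'
#' ROIs use 1-based inclusive row/column ranges, matching R matrix indexing:
#' `roi(2, 1, 4, 10)` selects `pixels[2:4, 1:10]`.
#'
#' @param row_start,col_start first row/column of the region (1-based).
#' @param row_stop,col_stop last row/column of the region (inclusive).
#' @return an object of class `roi`.
#' @examples
#' r <- roi(1, 1, 50, 50)   # a 50 x 50 square in the top-left corner
#' @export
roi <- function(row_start, col_start, row_stop, col_stop) {
  v <- c(row_start, col_start, row_stop, col_stop)
  if (!all(is.finite(v)) || any(v != round(v)))
    stop("roi bounds must be integers")
  if (row_start < 1L || col_start < 1L || row_stop < row_start || col_stop < col_start)
    stop("roi requires 1 <= start <= stop on both axes")
  structure(list(row_start = as.integer(row_start), col_start = as.integer(col_start),
                 row_stop = as.integer(row_stop), col_stop = as.integer(col_stop)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> rows %d..%d, cols %d..%d (%d x %d px)\n",
              x$row_start, x$row_stop, x$col_start, x$col_stop,
              x$row_stop - x$row_start + 1L, x$col_stop - x$col_start + 1L))
  invisible(x)
}

roi_dims <- function(r) {
  c(r$row_stop - r$row_start + 1L, r$col_stop - r$col_start + 1L)
}

check_roi_bounds <- function(r, dims) {
  if (r$row_stop > dims[1] || r$col_stop > dims[2])
    stop(sprintf("roi (rows %d..%d, cols %d..%d) exceeds image extent %d x %d",
                 r$row_start, r$row_stop, r$col_start, r$col_stop, dims[1], dims[2]))
  invisible(TRUE)
}

#' Binary mask
#'
#' A logical pixel grid sharing the calibration of the image it was derived
#' from.  Used for thresholded particle/wall/void maps and for skeletons.
#'
#' @param pixels logical matrix.
#' @param pixel_length,units calibration, as in [calibrated_image()].
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_length, units = "um") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1))) stop("mask pixels must be logical or 0/1")
    pixels <- pixels > 0
  }
  if (any(is.na(pixels))) stop("mask pixels must not be NA")
  if (!is.numeric(pixel_length) || pixel_length <= 0)
    stop("pixel_length must be positive")
  structure(list(pixels = pixels, pixel_length = as.numeric(pixel_length),
                 units = as.character(units)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground (%.1f%%), pixel_length = %g %s/px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              100 * mean(x$pixels), x$pixel_length, x$units))
  invisible(x)
}

#' Read a TIFF or PNG micrograph as a calibrated image
#'
#' Multi-channel (RGB/RGBA) input is collapsed to single-channel luminance by
#' an equal-weight channel mean (alpha is dropped); micrographs in this
#' domain are effectively grayscale.  8-/16-bit TIFFs are read at their
#' stored integer values; PNG values are mapped back to the 0--255 scale.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_length,units physical pixel size, as in [calibrated_image()].
#' @return a [calibrated_image()].
#' @export
load_image <- function(path, pixel_length, units = "um") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tryCatch(tiff::readTIFF(path, as.is = TRUE),
                            error = function(e) stop(sprintf("cannot read '%s' as TIFF: %s",
                                                             path, conditionMessage(e)))),
    png = tryCatch(png::readPNG(path) * 255,
                   error = function(e) stop(sprintf("cannot read '%s' as PNG: %s",
                                                    path, conditionMessage(e)))),
    stop(sprintf("unsupported image format '.%s' (TIFF or PNG expected)", ext))
  )
  if (length(dim(arr)) == 3L) {
    nch <- min(dim(arr)[3], 3L)  # drop alpha
    arr <- apply(arr[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  calibrated_image(arr, pixel_length = pixel_length, units = units,
                   source_id = basename(path))
}

#' Write a calibrated image or binary mask as PNG
#'
#' Intensities are clamped to \[0, 255\] and written as 8-bit grayscale; masks
#' are written as 0/255.
#'
#' @param x a [calibrated_image()] or [binary_mask()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  px <- if (inherits(x, "binary_mask")) x$pixels * 255 else x$pixels
  px <- pmin(pmax(px, 0), 255) / 255
  png::writePNG(px, target = path)
  invisible(path)
}

#' Extract a rectangular region from a calibrated image
#'
#' @param img a [calibrated_image()].
#' @param r an [roi()] lying within the image.
#' @return a [calibrated_image()] with the ROI's dimensions and the parent
#'   calibration.
#' @export
extract_roi <- function(img, r) {
  stopifnot(inherits(img, "calibrated_image"), inherits(r, "roi"))
  check_roi_bounds(r, dim(img$pixels))
  calibrated_image(img$pixels[r$row_start:r$row_stop, r$col_start:r$col_stop, drop = FALSE],
                   pixel_length = img$pixel_length, units = img$units,
                   source_id = img$source_id)
}

#' Rescale intensities to the full 0--255 dynamic range
#'
#' Applies the linear map sending the minimum intensity to 0 and the maximum
#' to 255.  Intensity ordering is preserved and the map is invariant under
#' positive affine transforms of the input (`a*I + b`, `a > 0`).  This is the
#' normalization applied to SEM regions of interest before the roughness
#' statistic.
#'
#' @param img a [calibrated_image()] with at least two distinct intensities.
#' @return a rescaled [calibrated_image()].
#' @export
rescale_dynamic_range <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  lo <- min(img$pixels); hi <- max(img$pixels)
  if (hi <= lo)
    stop("constant image: dynamic range cannot be maximized")
  calibrated_image((img$pixels - lo) * (255 / (hi - lo)),
                   pixel_length = img$pixel_length, units = img$units,
                   source_id = img$source_id)
}

#' Threshold an image into a binary mask
#'
#' A pixel is foreground iff its intensity is strictly above (`polarity =
#' "above"`) or strictly below (`polarity = "below"`) the threshold; pixels
#' exactly at the threshold are always background (a fixed, documented
#' tie-break).
#'
#' @param img a [calibrated_image()].
#' @param threshold finite intensity threshold.
#' @param polarity `"above"` or `"below"`.
#' @return a [binary_mask()].
#' @export
threshold_mask <- function(img, threshold, polarity = c("above", "below")) {
  stopifnot(inherits(img, "calibrated_image"))
  polarity <- match.arg(polarity)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a single finite number")
  px <- if (polarity == "above") img$pixels > threshold else img$pixels < threshold
  binary_mask(px, pixel_length = img$pixel_length, units = img$units)
}

#' Otsu threshold of a calibrated image
#'
#' Convenience wrapper computing Otsu's threshold on the 0--255 scale.
#'
#' @param img a non-constant [calibrated_image()].
#' @return threshold intensity (scalar).
#' @export
otsu_threshold <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  lo <- min(img$pixels); hi <- max(img$pixels)
  if (hi <= lo) stop("constant image: Otsu threshold undefined")
  # EBImage::otsu expects intensities in [0, 1]
  EBImage::otsu(EBImage::Image(img$pixels / 255), range = c(0, 1)) * 255
}
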
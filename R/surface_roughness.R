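# SEM surface-roughness factor: the standard deviation of pixel intensity in
# dynamic-range-normalized regions of interest.  Secondary-electron contrast
# tracks local surface slope, so intensity dispersion is a relative proxy for
# exposed surface area -- not a physical height roughness.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Roughness of one region of interest
#'
#' The ROI's pixels are independently rescaled to the full 0--255 range
#' (see [rescale_dynamic_range()]; per-ROI normalization makes ROIs from
#' different micrographs comparable) and the population standard deviation of
#' the rescaled values is returned.  The statistic is invariant under
#' positive affine transforms of the ROI and bounded by 127.5 (attained by a
#' half-and-half two-point \{0, 255\} intensity distribution).
#'
#' @param img a [calibrated_image()].
#' @param r optional [roi()]; the whole image when omitted.
#' @return roughness SD (grayscale units, 0--255 scale).
#' @export
roughness_of_roi <- function(img, r = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  sub <- if (is.null(r)) img else extract_roi(img, r)
  if (length(sub$pixels) < 2L)
    stop("ROI must contain at least 2 pixels")
  pop_sd(rescale_dynamic_range(sub)$pixels)  # errors on constant ROI
}

select_rois <- function(img, k, side_px, selection) {
  dims <- dim(img$pixels)
  if (side_px > min(dims))
    stop(sprintf("ROI side (%d px) exceeds image extent %d x %d",
                 side_px, dims[1], dims[2]))
  border <- pmax(1L, floor(0.05 * dims))
  max_r <- dims[1] - side_px + 1L - border[1]
  max_c <- dims[2] - side_px + 1L - border[2]
  lo_r <- min(border[1] + 1L, max_r); lo_c <- min(border[2] + 1L, max_c)
  if (max_r < lo_r || max_c < lo_c) { lo_r <- 1L; max_r <- dims[1] - side_px + 1L
                                      lo_c <- 1L; max_c <- dims[2] - side_px + 1L }
  if (selection == "grid") {
    gr <- floor(sqrt(k)); gc <- ceiling(k / gr)
    rs <- round(seq(lo_r, max_r, length.out = gr))
    cs <- round(seq(lo_c, max_c, length.out = gc))
    pos <- expand.grid(row = rs, col = cs)[seq_len(k), , drop = FALSE]
  } else {  # random
    pos <- data.frame(row = round(stats::runif(k, lo_r, max_r)),
                      col = round(stats::runif(k, lo_c, max_c)))
  }
  lapply(seq_len(k), function(i)
    roi(pos$row[i], pos$col[i],
        pos$row[i] + side_px - 1L, pos$col[i] + side_px - 1L))
}

#' Roughness factor over micrographs
#'
#' Computes [roughness_of_roi()] for a set of square ROIs on each micrograph
#' (the reference protocol analyzes six 0.5 um square ROIs on each of three
#' micrographs per sample, 18 ROIs in all) and reports the mean of the
#' per-ROI SDs and the SD among them.
#'
#' @param images a [calibrated_image()] or list of them (one per micrograph).
#' @param rois_per_image square ROIs analyzed per micrograph.
#' @param roi_side ROI side in physical units (converted per image to
#'   `max(2, round(roi_side / pixel_length))` pixels).
#' @param selection `"grid"` (deterministic border-avoiding grid, the
#'   default) or `"random"` (uniform placement; supply `seed`).  ROIs chosen
#'   by hand can be passed via `roi_list` instead, mirroring manual ROI
#'   selection on real micrographs.
#' @param seed RNG seed for `selection = "random"`.
#' @param roi_list optional list of lists of [roi()]s, one inner list per
#'   image; overrides `selection`.
#' @return a `roughness_result`: list with `per_roi` (data frame: image id,
#'   ROI bounds, `sd`), `mean_sd`, `sd_of_sd` (sample SD among ROIs),
#'   `n_rois`.
#' @export
roughness_summary <- function(images, rois_per_image = 6L, roi_side = 0.5,
                              selection = c("grid", "random"), seed = NULL,
                              roi_list = NULL) {
  if (inherits(images, "calibrated_image")) images <- list(images)
  selection <- match.arg(selection)
  stopifnot(length(images) >= 1L, rois_per_image >= 1L)
  rows <- with_rng_seed(seed, {
    out <- list()
    for (i in seq_along(images)) {
      img <- images[[i]]
      stopifnot(inherits(img, "calibrated_image"))
      rois <- if (!is.null(roi_list)) roi_list[[i]]
      else {
        side_px <- max(2L, as.integer(round(roi_side / img$pixel_length)))
        select_rois(img, as.integer(rois_per_image), side_px, selection)
      }
      for (r in rois) {
        check_roi_bounds(r, dim(img$pixels))
        out[[length(out) + 1L]] <- data.frame(
          image_id = if (nzchar(img$source_id)) img$source_id else sprintf("image%d", i),
          row_start = r$row_start, col_start = r$col_start,
          row_stop = r$row_stop, col_stop = r$col_stop,
          sd = roughness_of_roi(img, r))
      }
    }
    do.call(rbind, out)
  })
  structure(list(per_roi = rows,
                 mean_sd = mean(rows$sd),
                 sd_of_sd = if (nrow(rows) > 1L) stats::sd(rows$sd) else 0,
                 n_rois = nrow(rows)),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("<roughness_result> %d ROIs: mean SD = %.2f, SD among ROIs = %.2f\n",
              x$n_rois, x$mean_sd, x$sd_of_sd))
  invisible(x)
}
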
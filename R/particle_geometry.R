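# Particle segmentation and size/shape descriptors for flatbed scans of
# biomass particle fields.

as_eb <- function(px) EBImage::Image(px * 1)

#' 8-connected component labeling
#'
#' Labels connected foreground regions of a binary mask using 8-connectivity
#' (diagonal neighbours connect).  Components are built from the pixel
#' adjacency graph; labels are consecutive `1..K` in order of first
#' (column-major) pixel occurrence.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param pixel_length,units calibration, taken from `mask` when it is a
#'   [binary_mask()].
#' @return a `label_map`: list with integer matrix `labels` (0 = background)
#'   plus calibration.
#' @export
label_components <- function(mask, pixel_length = NULL, units = NULL) {
  if (inherits(mask, "binary_mask")) {
    px <- mask$pixels
    if (is.null(pixel_length)) pixel_length <- mask$pixel_length
    if (is.null(units)) units <- mask$units
  } else {
    px <- as.matrix(mask) > 0
    if (is.null(pixel_length)) pixel_length <- 1
    if (is.null(units)) units <- "px"
  }
  nr <- nrow(px); nc <- ncol(px)
  nfg <- sum(px)
  lab <- matrix(0L, nr, nc)
  if (nfg > 0L) {
    id <- matrix(0L, nr, nc)
    id[px] <- seq_len(nfg)
    el <- NULL
    for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
      ra <- seq.int(max(1L, 1L - o[1]), min(nr, nr - o[1]))
      ca <- seq.int(max(1L, 1L - o[2]), min(nc, nc - o[2]))
      A <- id[ra, ca, drop = FALSE]
      B <- id[ra + o[1], ca + o[2], drop = FALSE]
      keep <- A > 0L & B > 0L
      if (any(keep)) el <- rbind(el, cbind(A[keep], B[keep]))
    }
    g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
    if (!is.null(el)) g <- igraph::add_edges(g, t(el))
    memb <- igraph::components(g)$membership
    # relabel in order of first column-major occurrence
    remap <- integer(max(memb))
    first <- memb[!duplicated(memb)]
    remap[first] <- seq_along(first)
    lab[px] <- remap[memb]
  }
  structure(list(labels = lab, pixel_length = as.numeric(pixel_length),
                 units = as.character(units)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d objects, pixel_length = %g %s/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$pixel_length, x$units))
  invisible(x)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (length(u) == 0L) return(lab)
  remap <- integer(max(u)); remap[u] <- seq_along(u)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Segment biomass particles from a scan image
#'
#' Thresholds the image (Otsu by default; scans have strong bimodal
#' particle/background contrast) and labels the particle-side pixels.  When
#' `split_touching = TRUE`, merged blobs are separated by a watershed seeded
#' from local maxima of the foreground Euclidean distance transform, the
#' standard recipe for disconnecting overlapping convex particles; otherwise
#' plain 8-connected labeling is used.  Components smaller than `min_area_px`
#' (default 4 px, a dust/noise filter) are removed and the remaining labels
#' are renumbered consecutively.
#'
#' @param img a [calibrated_image()].
#' @param threshold_method `"otsu"`, or a single number used as a fixed
#'   threshold.
#' @param foreground `"dark"` (particles darker than background, as in
#'   transmitted-light scans) or `"bright"`.
#' @param min_area_px minimum component size kept, in pixels.
#' @param split_touching split merged blobs with a distance-transform-seeded
#'   watershed.
#' @param ws_tolerance,ws_ext watershed seed parameters (minimum depth
#'   between distinct seeds, and the local-maximum detection radius in px).
#' @return a `label_map` (see [label_components()]).
#' @export
segment_particles <- function(img, threshold_method = "otsu",
                              foreground = c("dark", "bright"),
                              min_area_px = 4L, split_touching = TRUE,
                              ws_tolerance = 1, ws_ext = 2) {
  stopifnot(inherits(img, "calibrated_image"))
  foreground <- match.arg(foreground)
  thr <- if (is.numeric(threshold_method)) {
    threshold_method
  } else if (identical(threshold_method, "otsu")) {
    otsu_threshold(img)
  } else stop("threshold_method must be \"otsu\" or a numeric threshold")
  mask <- if (foreground == "dark") img$pixels < thr else img$pixels > thr

  if (split_touching && any(mask)) {
    d <- EBImage::distmap(as_eb(mask))
    lab <- EBImage::imageData(EBImage::watershed(d, tolerance = ws_tolerance,
                                                 ext = ws_ext))
    storage.mode(lab) <- "integer"
  } else {
    lab <- label_components(mask)$labels
  }
  if (max(lab) > 0L && min_area_px > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    small <- which(sizes < min_area_px)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  structure(list(labels = relabel_consecutive(lab),
                 pixel_length = img$pixel_length, units = img$units),
            class = "label_map")
}

#' Size and shape descriptors of labeled particles
#'
#' Computes, per labeled region: physical area (pixel count times
#' `pixel_length^2`), perimeter (boundary-contour length times
#' `pixel_length`), the moment-matched ellipse's aspect ratio
#' (major/minor axis), and roundness `4*area_px / (pi * major_px^2)` --
#' the descriptor conventions of the standard particle-analysis tools.
#' The coordinate covariance includes the 1/12 px^2 within-pixel variance
#' term, so single-pixel and square regions behave like their continuous
#' counterparts (roundness stays in (0, 1] up to rasterization tolerance).
#'
#' @param labels a `label_map` from [segment_particles()] or
#'   [label_components()].
#' @return a data frame with one row per particle: `label`, `area_px`,
#'   `area`, `perimeter`, `aspect_ratio`, `roundness`, `centroid_row`,
#'   `centroid_col`.  Empty label map gives an empty data frame.
#' @export
compute_descriptors <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  lm <- labels$labels; l <- labels$pixel_length
  K <- max(lm)
  empty <- data.frame(label = integer(0), area_px = integer(0), area = numeric(0),
                      perimeter = numeric(0), aspect_ratio = numeric(0),
                      roundness = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
  if (K == 0L) return(empty)
  idx <- which(lm > 0L)
  lab <- lm[idx]
  rr <- ((idx - 1L) %% nrow(lm)) + 1L
  cc <- ((idx - 1L) %/% nrow(lm)) + 1L
  n_k <- tabulate(lab, nbins = K)
  mr <- rowsum(rr, lab)[, 1] / n_k
  mc <- rowsum(cc, lab)[, 1] / n_k
  vr <- rowsum(rr^2, lab)[, 1] / n_k - mr^2 + 1 / 12
  vc <- rowsum(cc^2, lab)[, 1] / n_k - mc^2 + 1 / 12
  vrc <- rowsum(rr * cc, lab)[, 1] / n_k - mr * mc
  tr <- vr + vc
  det_root <- sqrt(pmax((vr - vc)^2 + 4 * vrc^2, 0))
  lam1 <- (tr + det_root) / 2
  lam2 <- pmax((tr - det_root) / 2, 1e-12)
  major <- 4 * sqrt(lam1)
  minor <- 4 * sqrt(lam2)
  perim_px <- EBImage::computeFeatures.shape(lm)[, "s.perimeter"]
  data.frame(label = seq_len(K), area_px = n_k, area = n_k * l^2,
             perimeter = perim_px * l,
             aspect_ratio = major / minor,
             roundness = 4 * n_k / (pi * major^2),
             centroid_row = mr, centroid_col = mc)
}

hist_table <- function(x, edges) {
  k <- findInterval(x, edges)           # left-closed bins [e_i, e_{i+1})
  in_range <- k >= 1L & k < length(edges)
  counts <- tabulate(k[in_range], nbins = length(edges) - 1L)
  list(table = data.frame(lower = edges[-length(edges)], upper = edges[-1],
                          count = counts),
       below = sum(k < 1L), above = sum(k >= length(edges)))
}

#' Histograms of particle area and aspect ratio
#'
#' Bins are left-closed: a value equal to an edge falls in the bin to its
#' right.  Values outside the bin range are counted separately, not dropped
#' silently.  Default bins are powers of 2 up to 4 (area, physical units^2)
#' and unit-width bins 1--20 (aspect ratio).
#'
#' @param records descriptor data frame from [compute_descriptors()].
#' @param area_bins,ar_bins strictly increasing bin edge vectors.
#' @return a list with data frames `area` and `aspect_ratio`
#'   (`lower`, `upper`, `count`) and `out_of_range` (counts below/above the
#'   edges for each metric).
#' @export
particle_histograms <- function(records, area_bins = 2^seq(-10, 2),
                                ar_bins = 1:20) {
  if (any(diff(area_bins) <= 0) || any(diff(ar_bins) <= 0))
    stop("bin edges must be strictly increasing")
  ha <- hist_table(records$area, area_bins)
  hr <- hist_table(records$aspect_ratio, ar_bins)
  list(area = ha$table, aspect_ratio = hr$table,
       out_of_range = data.frame(metric = c("area", "aspect_ratio"),
                                 below = c(ha$below, hr$below),
                                 above = c(ha$above, hr$above)))
}

#' Mean particle size and shape of a field
#'
#' Arithmetic means in physical units, the per-sample particle descriptors
#' used in structure--digestibility correlation tables.
#'
#' @param records descriptor data frame from [compute_descriptors()].
#' @return list with `mean_area`, `mean_aspect_ratio`, `n`.
#' @export
particle_summary <- function(records) {
  if (is.null(records) || nrow(records) < 1L)
    stop("no particle records to summarize")
  list(mean_area = mean(records$area),
       mean_aspect_ratio = mean(records$aspect_ratio),
       n = nrow(records))
}
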
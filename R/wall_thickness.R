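# Cell-wall thickness from binarized confocal sections.
#
# Two operations performed in tandem yield the thickness distribution: the
# Euclidean boundary-distance map D_B assigns every wall pixel its distance
# (in physical units) to the nearest background pixel, and the medial axis
# transform gives the wall mid-line; evaluating D_B at the medial-axis pixels
# gives one cell-wall-thickness (CWT) sample per mid-line pixel.  For two
# cells adjoined across a shared wall, the mid-line value equals each
# individual cell's wall thickness; for disjoined (dislocated) cells it is
# half the actual wall thickness, which the "disjoined-doubled" sampling
# convention compensates.

#' Euclidean boundary-distance map
#'
#' For each foreground pixel, the exact Euclidean distance (in pixels, scaled
#' by `pixel_length`) to the nearest background pixel; 0 on background.
#' "Nearest boundary" follows standard distance-transform semantics (nearest
#' background pixel; the alternative, nearest background-adjacent foreground
#' pixel, differs by at most one pixel).
#'
#' @param mask a [binary_mask()] with at least one foreground and one
#'   background pixel.
#' @return a `distance_map`: list with matrix `values` (physical units),
#'   `pixel_length`, `units`.
#' @export
distance_map <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  nfg <- sum(mask$pixels)
  if (nfg == 0L || nfg == length(mask$pixels))
    stop("mask must contain both foreground and background pixels")
  d <- EBImage::imageData(EBImage::distmap(as_eb(mask$pixels),
                                           metric = "euclidean"))
  structure(list(values = d * mask$pixel_length,
                 pixel_length = mask$pixel_length, units = mask$units),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d x %d px, max %g %s, pixel_length = %g %s/px\n",
              nrow(x$values), ncol(x$values), max(x$values), x$units,
              x$pixel_length, x$units))
  invisible(x)
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq.int(max(1L, 1L + dr), min(nr, nr + dr))
  cs <- seq.int(max(1L, 1L + dc), min(nc, nc + dc))
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# neighbours in the Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# image outside treated as background
zs_neighbours <- function(m) {
  list(shift_mat(m, 1L, 0L),   # P2: north neighbour's value at (r,c) = m[r-1,c]
       shift_mat(m, 1L, -1L),  # P3: NE
       shift_mat(m, 0L, -1L),  # P4: E
       shift_mat(m, -1L, -1L), # P5: SE
       shift_mat(m, -1L, 0L),  # P6: S
       shift_mat(m, -1L, 1L),  # P7: SW
       shift_mat(m, 0L, 1L),   # P8: W
       shift_mat(m, 1L, 1L))   # P9: NW
}

zhang_suen_thin <- function(px) {
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- zs_neighbours(px)
      B <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1])
      A <- matrix(0L, nrow(px), ncol(px))
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1]])
      if (step == 1L) {
        cnd <- !(nb[[1]] & nb[[3]] & nb[[5]]) & !(nb[[3]] & nb[[5]] & nb[[7]])
      } else {
        cnd <- !(nb[[1]] & nb[[3]] & nb[[7]]) & !(nb[[1]] & nb[[5]] & nb[[7]])
      }
      del <- px & B >= 2 & B <= 6 & A == 1 & cnd
      if (any(del)) { px[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  px
}

neighbour_count <- function(px) {
  Reduce(`+`, zs_neighbours(px))
}

prune_spurs <- function(px, min_len = 3L) {
  nb <- neighbour_count(px)
  ends <- which(px & nb == 1L, arr.ind = TRUE)
  if (nrow(ends) == 0L) return(px)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  nr <- nrow(px); nc <- ncol(px)
  for (e in seq_len(nrow(ends))) {
    cur <- ends[e, ]; prev <- c(NA_integer_, NA_integer_)
    path <- matrix(cur, 1L)
    hit_junction <- FALSE
    while (nrow(path) < min_len) {
      cand <- sweep(offs, 2L, cur, `+`)
      ok <- cand[, 1] >= 1L & cand[, 1] <= nr & cand[, 2] >= 1L & cand[, 2] <= nc
      cand <- cand[ok, , drop = FALSE]
      cand <- cand[px[cand], , drop = FALSE]
      if (!is.na(prev[1]))
        cand <- cand[!(cand[, 1] == prev[1] & cand[, 2] == prev[2]), , drop = FALSE]
      if (nrow(cand) == 0L) break              # open curve end: keep
      nxt <- cand[1L, ]
      if (nb[nxt[1], nxt[2]] >= 3L) { hit_junction <- TRUE; break }
      prev <- cur; cur <- nxt
      path <- rbind(path, cur)
    }
    if (hit_junction) px[path] <- FALSE        # short branch into a junction
  }
  px
}

#' Medial axis transform (skeletonization)
#'
#' Topology-preserving thinning of the wall mask to its one-pixel-wide
#' mid-line, so the skeleton has the same number of connected components as
#' the mask and is a subset of its foreground.  By default, spur branches
#' shorter than `min_branch_px` that terminate at a junction are pruned:
#' rasterization of wall boundaries otherwise seeds short spurious branches
#' whose distance-map values spike the thickness distribution.
#'
#' @param mask a [binary_mask()] with both foreground and background.
#' @param prune_spurs prune short junction-terminated branches.
#' @param min_branch_px branches strictly shorter than this are removed.
#' @return skeleton as a [binary_mask()].
#' @export
medial_axis <- function(mask, prune_spurs = TRUE, min_branch_px = 3L) {
  stopifnot(inherits(mask, "binary_mask"))
  nfg <- sum(mask$pixels)
  if (nfg == 0L || nfg == length(mask$pixels))
    stop("mask must contain both foreground and background pixels")
  sk <- zhang_suen_thin(mask$pixels)
  if (prune_spurs) sk <- prune_spurs(sk, as.integer(min_branch_px))
  binary_mask(sk, pixel_length = mask$pixel_length, units = mask$units)
}

#' Sample wall thickness at medial-axis pixels
#'
#' Evaluates the boundary-distance map at every skeleton pixel, one CWT
#' sample per pixel.  With `convention = "raw"` the distance-map value is
#' reported as-is (the correct thickness for cells adjoined across a shared
#' wall); `"disjoined-doubled"` doubles it (for dislocated cells, where the
#' mid-line value is half the actual wall thickness).
#'
#' @param dmap a `distance_map` from [distance_map()].
#' @param skeleton a [binary_mask()] of the same dimensions, normally from
#'   [medial_axis()].
#' @param convention `"raw"` or `"disjoined-doubled"`.
#' @return a `thickness_samples` object: list with `values` (physical
#'   units), `coords` (pixel row/col matrix), `convention`, `units`,
#'   `pixel_length`.
#' @export
sample_thickness <- function(dmap, skeleton,
                             convention = c("raw", "disjoined-doubled")) {
  stopifnot(inherits(dmap, "distance_map"), inherits(skeleton, "binary_mask"))
  convention <- match.arg(convention)
  if (!identical(dim(dmap$values), dim(skeleton$pixels)))
    stop("distance map and skeleton dimensions differ")
  idx <- which(skeleton$pixels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty skeleton: no thickness samples")
  vals <- dmap$values[skeleton$pixels]
  if (convention == "disjoined-doubled") vals <- 2 * vals
  structure(list(values = vals, coords = idx, convention = convention,
                 units = dmap$units, pixel_length = dmap$pixel_length),
            class = "thickness_samples")
}

#' @export
print.thickness_samples <- function(x, ...) {
  cat(sprintf("<thickness_samples> n = %d, mean = %.3g %s (convention: %s)\n",
              length(x$values), mean(x$values), x$units, x$convention))
  invisible(x)
}

#' Summarize wall-thickness samples
#'
#' Arithmetic mean, standard deviation (sample SD, n-1 denominator) and
#' count, overall and optionally per group (e.g. per-cell labels assigned to
#' skeleton pixels, so means can be taken per cell before pooling).
#'
#' @param samples a `thickness_samples` object.
#' @param groups optional vector of group labels, one per sample.
#' @return list with `overall` (one-row data frame `mean`, `sd`, `n`) and
#'   `per_group` (data frame, or `NULL` when no groups were supplied).
#' @export
summarize_thickness <- function(samples, groups = NULL) {
  stopifnot(inherits(samples, "thickness_samples"))
  v <- samples$values
  if (length(v) < 1L) stop("no thickness samples")
  overall <- data.frame(mean = mean(v),
                        sd = if (length(v) > 1L) stats::sd(v) else 0,
                        n = length(v))
  per_group <- NULL
  if (!is.null(groups)) {
    if (length(groups) != length(v))
      stop("groups must have one label per thickness sample")
    g <- factor(groups)
    per_group <- data.frame(
      group = levels(g),
      mean = as.numeric(tapply(v, g, mean)),
      sd = as.numeric(tapply(v, g, function(z) if (length(z) > 1L) stats::sd(z) else 0)),
      n = as.integer(table(g)))
  }
  list(overall = overall, per_group = per_group)
}

#' Pseudo-colored rendering of a distance map
#'
#' Writes the distance map as a pseudo-colored PNG (dark-to-bright heat
#' palette over the distance range), the standard display for wall-thickness
#' maps.
#'
#' @param dmap a `distance_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_distance_map_png <- function(dmap, path) {
  v <- dmap$values
  mx <- max(v)
  z <- if (mx > 0) v / mx else v
  pal <- grDevices::colorRamp(c("black", "blue", "cyan", "yellow", "red"))
  rgbv <- pal(as.vector(z)) / 255
  arr <- array(rgbv, dim = c(nrow(v), ncol(v), 3L))
  png::writePNG(arr, target = path)
  invisible(path)
}
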
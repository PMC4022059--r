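# Independent brute-force oracles, deliberately naive implementations.

# exact nearest-background Euclidean distance by exhaustive search
brute_force_distance <- function(mask_px) {
  bg <- which(!mask_px, arr.ind = TRUE)
  out <- matrix(0, nrow(mask_px), ncol(mask_px))
  fg <- which(mask_px, arr.ind = TRUE)
  if (nrow(fg) > 0L)
    for (i in seq_len(nrow(fg)))
      out[fg[i, 1], fg[i, 2]] <-
        sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  out
}

# 8-connected component labeling by queue-based flood fill
flood_fill_label <- function(mask_px) {
  nr <- nrow(mask_px); nc <- ncol(mask_px)
  lab <- matrix(0L, nr, nc)
  k <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask_px)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (j in seq_len(nrow(offs))) {
        rr <- r + offs$dr[j]; cc <- c + offs$dc[j]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            mask_px[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  lab
}

# random binary mask guaranteed to contain both phases
random_mask <- function(nr, nc, p_fg) {
  m <- matrix(stats::runif(nr * nc) < p_fg, nr, nc)
  if (!any(m)) m[sample(length(m), 1L)] <- TRUE
  if (all(m)) m[sample(length(m), 1L)] <- FALSE
  m
}

# image with two overlapping disks of radius 20 px, centers 30 px apart
two_disk_image <- function(fg = 60, bg = 200) {
  sz <- 101L
  xy <- expand.grid(r = 1:sz, c = 1:sz)
  d1 <- (xy$r - 40)^2 + (xy$c - 51)^2 <= 400
  d2 <- (xy$r - 70)^2 + (xy$c - 51)^2 <= 400
  calibrated_image(matrix(ifelse(d1 | d2, fg, bg), sz, sz), pixel_length = 1)
}

# place full-range rescale anchors (one 0 px, one 255 px) inside a ROI so
# per-ROI dynamic-range normalization becomes the identity map
anchor_roi <- function(img, r) {
  img$pixels[r$row_start, r$col_start] <- 0
  img$pixels[r$row_start, r$col_start + 1L] <- 255
  img
}
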
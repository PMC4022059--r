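# Ground-truthed synthetic micrograph generators.
#
# Each generator is a pure function of its arguments including `seed` (the
# caller's RNG state is saved and restored), emulates one of the four imaging
# modalities the pipeline consumes, and returns machine-readable ground truth
# sufficient to compute expected downstream measurements without re-deriving
# geometry.  Generated intensities always lie in [0, 255].

with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

rasterize_ellipse <- function(center_row, center_col, a, b, theta, dims) {
  # pixel-center rasterization of a solid ellipse with semi-axes a >= b
  ext <- ceiling(a) + 1L
  rr <- max(1L, floor(center_row - ext)):min(dims[1], ceiling(center_row + ext))
  cc <- max(1L, floor(center_col - ext)):min(dims[2], ceiling(center_col + ext))
  dr <- outer(rr - center_row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center_col)
  u <- dc * cos(theta) + dr * sin(theta)
  v <- -dc * sin(theta) + dr * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
}

#' Simulate a flatbed scan of a biomass particle field
#'
#' Places `n` dark elliptical particles on a bright background, emulating a
#' high-resolution scan of dried pretreated biomass spread on a flatbed.
#' Particle areas are log-normal (optionally a two-component log-normal
#' mixture, emulating the bimodal size distribution of unmilled feedstock);
#' aspect ratios are normal truncated at 1.  A chosen fraction of particles
#' is deliberately placed overlapping a previously placed neighbour so that
#' watershed splitting can be exercised; all other particles are separated by
#' at least 3 px so segmentation recovers them exactly.
#'
#' @param n number of particles (`>= 1`).
#' @param area_dist `c(meanlog, sdlog)` of the log-normal particle area, in
#'   pixel^2.
#' @param aspect_dist `c(mean, sd)` of the aspect ratio (truncated at 1).
#' @param touching_fraction fraction of particles placed overlapping a
#'   neighbour, in `[0, 1]` (the first particle is always free, so at most
#'   `n - 1` can touch).
#' @param image_size `c(rows, cols)` in pixels.
#' @param seed integer RNG seed; the same seed reproduces the field exactly.
#' @param pixel_length,units calibration (defaults emulate a 2,400 dpi scan,
#'   0.010583 mm/px).
#' @param area_dist2,mix_prop optional second log-normal component and its
#'   mixing proportion, for bimodal size distributions.
#' @param background,foreground background/particle intensities.
#' @return a list with elements
#'   \describe{
#'     \item{image}{the [calibrated_image()];}
#'     \item{truth}{a list with `particles` (data frame: `id`, `center_row`,
#'       `center_col`, `major_px`, `minor_px` (full axis lengths),
#'       `orientation`, `area_px` (rasterized pixel count of the particle's
#'       own stencil), `aspect_ratio`, `touching`), `n`, `n_touching_pairs`,
#'       `background`, `foreground`.}
#'   }
#' @export
make_particle_field <- function(n, area_dist = c(meanlog = 5.5, sdlog = 0.6),
                                aspect_dist = c(mean = 1.8, sd = 0.4),
                                touching_fraction = 0,
                                image_size = c(600, 600), seed = 1,
                                pixel_length = 0.010583, units = "mm",
                                area_dist2 = NULL, mix_prop = 0,
                                background = 200, foreground = 60) {
  stopifnot(n >= 1, touching_fraction >= 0, touching_fraction <= 1,
            area_dist[2] >= 0, aspect_dist[2] >= 0, mix_prop >= 0, mix_prop <= 1)
  dims <- as.integer(image_size)
  with_rng_seed(seed, {
    areas <- stats::rlnorm(n, area_dist[1], area_dist[2])
    component <- rep(1L, n)
    if (!is.null(area_dist2) && mix_prop > 0) {
      pick2 <- stats::runif(n) < mix_prop
      areas[pick2] <- stats::rlnorm(sum(pick2), area_dist2[1], area_dist2[2])
      component[pick2] <- 2L
    }
    ar <- stats::rnorm(n, aspect_dist[1], aspect_dist[2])
    while (any(ar < 1)) ar[ar < 1] <- stats::rnorm(sum(ar < 1), aspect_dist[1], aspect_dist[2])
    a <- sqrt(areas * ar / pi)   # semi-major
    b <- a / ar                  # semi-minor
    theta <- stats::runif(n, 0, pi)

    n_touch <- min(round(touching_fraction * n), n - 1L)
    touch <- rep(FALSE, n)
    if (n_touch > 0) touch[(n - n_touch + 1L):n] <- TRUE

    cr <- numeric(n); cc <- numeric(n)
    pairs <- 0L
    for (i in seq_len(n)) {
      margin <- ceiling(a[i]) + 2
      if (2 * margin >= min(dims))
        stop(sprintf("particle %d (semi-major %.1f px) cannot be placed inside a %d x %d image",
                     i, a[i], dims[1], dims[2]))
      placed <- FALSE
      for (try in seq_len(400L)) {
        if (touch[i]) {
          j <- sample.int(i - 1L, 1L)
          phi <- stats::runif(1, 0, 2 * pi)
          d <- 0.75 * (b[i] + b[j])   # < b_i + b_j guarantees overlap
          r0 <- cr[j] + d * sin(phi); c0 <- cc[j] + d * cos(phi)
          ok_pos <- r0 > margin && r0 < dims[1] - margin &&
                    c0 > margin && c0 < dims[2] - margin
          if (ok_pos) { cr[i] <- r0; cc[i] <- c0; pairs <- pairs + 1L; placed <- TRUE; break }
        } else {
          r0 <- stats::runif(1, margin, dims[1] - margin)
          c0 <- stats::runif(1, margin, dims[2] - margin)
          sep <- TRUE
          if (i > 1L) {
            dd <- sqrt((cr[seq_len(i - 1L)] - r0)^2 + (cc[seq_len(i - 1L)] - c0)^2)
            sep <- all(dd > a[i] + a[seq_len(i - 1L)] + 3)
          }
          if (sep) { cr[i] <- r0; cc[i] <- c0; placed <- TRUE; break }
        }
      }
      if (!placed)
        stop(sprintf("could not place particle %d of %d without exceeding the image; enlarge image_size or reduce n", i, n))
    }

    fg <- matrix(FALSE, dims[1], dims[2])
    area_px <- integer(n)
    for (i in seq_len(n)) {
      px <- rasterize_ellipse(cr[i], cc[i], a[i], b[i], theta[i], dims)
      area_px[i] <- nrow(px)
      fg[px] <- TRUE
    }
    img <- matrix(background, dims[1], dims[2])
    img[fg] <- foreground

    list(
      image = calibrated_image(img, pixel_length = pixel_length, units = units,
                               source_id = sprintf("synthetic-particle-field-seed%d", seed)),
      truth = list(
        particles = data.frame(id = seq_len(n), center_row = cr, center_col = cc,
                               major_px = 2 * a, minor_px = 2 * b,
                               orientation = theta, area_px = area_px,
                               aspect_ratio = ar, touching = touch,
                               component = component),
        n = n, n_touching_pairs = pairs,
        background = background, foreground = foreground))
  })
}

#' Simulate a confocal section through a lattice of cells
#'
#' Builds a rectangular lattice of cells with bright walls of uniform
#' thickness on a dark lumen/background, emulating the contrast of
#' acriflavin-stained secondary walls in confocal sections.  A chosen
#' fraction of the interior (shared) wall segments is "dislocated": split
#' into two parallel walls separated by a background gap, emulating the
#' separation of whole cells from one another at the middle lamella seen
#' after explosive-discharge pretreatment.  The returned mask is the exact
#' wall ground truth.
#'
#' @param wall_thickness_px wall thickness in pixels (`>= 1`; `>= 3` if any
#'   dislocation is requested, so a split leaves two walls and a gap).
#' @param cell_diameter_px lumen width in pixels (must exceed the wall
#'   thickness).
#' @param n_cells requested cell count; realized as a near-square
#'   `rows x cols` grid with `rows*cols >= n_cells` (realized count returned).
#' @param dislocation_fraction fraction of interior wall segments split,
#'   in `[0, 1]`.
#' @param image_size `c(rows, cols)` in pixels; the lattice must fit with a
#'   2 px background margin.
#' @param seed integer RNG seed (selects which segments are split).
#' @param pixel_length,units calibration.
#' @return a list with `image` ([calibrated_image()]), `mask` (ground-truth
#'   wall [binary_mask()]), and `truth` (realized lattice geometry, including
#'   a `segments` data frame flagging each interior wall segment as split or
#'   adjoined).
#' @export
make_cell_lattice <- function(wall_thickness_px, cell_diameter_px, n_cells = 9,
                              dislocation_fraction = 0,
                              image_size = c(256, 256), seed = 1,
                              pixel_length = 0.5, units = "um") {
  w <- as.integer(wall_thickness_px); d <- as.integer(cell_diameter_px)
  stopifnot(w >= 1, n_cells >= 1,
            dislocation_fraction >= 0, dislocation_fraction <= 1)
  if (w >= d)
    stop("wall thickness must be smaller than the cell diameter")
  if (dislocation_fraction > 0 && w < 3)
    stop("walls thinner than 3 px cannot be split into two walls and a gap")
  dims <- as.integer(image_size)
  rows <- max(1L, round(sqrt(n_cells)))
  cols <- as.integer(ceiling(n_cells / rows))
  pitch <- d + w
  ext_r <- rows * pitch + w; ext_c <- cols * pitch + w
  if (ext_r + 4 > dims[1] || ext_c + 4 > dims[2])
    stop(sprintf("a %d x %d cell lattice (%d x %d px) does not fit in a %d x %d image",
                 rows, cols, ext_r, ext_c, dims[1], dims[2]))
  r0 <- as.integer(floor((dims[1] - ext_r) / 2))
  c0 <- as.integer(floor((dims[2] - ext_c) / 2))

  mask <- matrix(FALSE, dims[1], dims[2])
  for (i in 0:rows)
    mask[(r0 + i * pitch + 1):(r0 + i * pitch + w), (c0 + 1):(c0 + ext_c)] <- TRUE
  for (j in 0:cols)
    mask[(r0 + 1):(r0 + ext_r), (c0 + j * pitch + 1):(c0 + j * pitch + w)] <- TRUE

  # interior shared-wall segments (spanning the lumen extent only, so lattice
  # nodes stay intact and topology is preserved)
  seg <- list()
  for (i in seq_len(rows)) for (j in seq_len(cols - 1L))
    seg[[length(seg) + 1L]] <- list(
      orientation = "vertical", cell_row = i, cell_col = j,
      rr = (r0 + (i - 1L) * pitch + w + 1L):(r0 + (i - 1L) * pitch + w + d),
      cc = (c0 + j * pitch + 1L):(c0 + j * pitch + w))
  for (i in seq_len(rows - 1L)) for (j in seq_len(cols))
    seg[[length(seg) + 1L]] <- list(
      orientation = "horizontal", cell_row = i, cell_col = j,
      rr = (r0 + i * pitch + 1L):(r0 + i * pitch + w),
      cc = (c0 + (j - 1L) * pitch + w + 1L):(c0 + (j - 1L) * pitch + w + d))

  n_seg <- length(seg)
  n_split <- round(dislocation_fraction * n_seg)
  split_idx <- integer(0)
  if (n_seg > 0 && n_split > 0)
    split_idx <- with_rng_seed(seed, sort(sample.int(n_seg, n_split)))
  gap <- if (w %% 2L == 1L) 1L else 2L
  sub <- (w - gap) / 2L
  for (k in split_idx) {
    s <- seg[[k]]
    if (s$orientation == "vertical") {
      gap_cc <- s$cc[(sub + 1L):(sub + gap)]
      mask[s$rr, gap_cc] <- FALSE
    } else {
      gap_rr <- s$rr[(sub + 1L):(sub + gap)]
      mask[gap_rr, s$cc] <- FALSE
    }
  }

  img <- matrix(30, dims[1], dims[2])
  img[mask] <- 200
  segments <- if (n_seg > 0)
    data.frame(segment = seq_len(n_seg),
               orientation = vapply(seg, `[[`, "", "orientation"),
               cell_row = vapply(seg, `[[`, 0L, "cell_row"),
               cell_col = vapply(seg, `[[`, 0L, "cell_col"),
               split = seq_len(n_seg) %in% split_idx)
  else data.frame(segment = integer(0), orientation = character(0),
                  cell_row = integer(0), cell_col = integer(0), split = logical(0))

  list(
    image = calibrated_image(img, pixel_length = pixel_length, units = units,
                             source_id = sprintf("synthetic-cell-lattice-seed%d", seed)),
    mask = binary_mask(mask, pixel_length = pixel_length, units = units),
    truth = list(wall_thickness_px = w, cell_diameter_px = d,
                 n_cells = rows * cols, rows = rows, cols = cols,
                 dislocation_fraction = dislocation_fraction,
                 n_segments = n_seg, n_split = n_split,
                 gap_px = if (n_split > 0) gap else 0L,
                 sub_wall_px = if (n_split > 0) sub else w,
                 segments = segments,
                 origin = c(row = r0, col = c0), pitch = pitch))
}

#' Simulate a textured SEM surface with known intensity dispersion
#'
#' Pixels are drawn i.i.d. from a normal law with the given mean and standard
#' deviation, then clipped to \[0, 255\].  Clipping biases the realized SD
#' slightly; keep `base` at least four `sigma` away from 0 and 255 when the
#' truth SD is to be recovered.
#'
#' @param base mean intensity.
#' @param sigma intensity standard deviation (`>= 0`).
#' @param image_size `c(rows, cols)` in pixels.
#' @param seed integer RNG seed.
#' @param pixel_length,units calibration.
#' @return a list with `image` and `truth = list(base, sigma)`.
#' @export
make_textured_surface <- function(base = 128, sigma = 10,
                                  image_size = c(256, 256), seed = 1,
                                  pixel_length = 0.01, units = "um") {
  stopifnot(sigma >= 0)
  dims <- as.integer(image_size)
  with_rng_seed(seed, {
    px <- matrix(stats::rnorm(prod(dims), base, sigma), dims[1], dims[2])
    px <- pmin(pmax(px, 0), 255)
    list(image = calibrated_image(px, pixel_length = pixel_length, units = units,
                                  source_id = sprintf("synthetic-surface-seed%d", seed)),
         truth = list(base = base, sigma = sigma))
  })
}

runif_moment <- function(n, mean, sd) {
  # bounded-support noise law with the requested mean and SD
  stats::runif(n, mean - sqrt(3) * sd, mean + sqrt(3) * sd)
}

#' Simulate a TEM section of a delaminated cell wall
#'
#' Produces a wall-intensity image containing (i) a designated void-reference
#' region (emulating a cell lumen) filled purely from the void intensity law,
#' and (ii) an intra-wall region in which elongated void lamellae -- stripes
#' parallel to the wall axis, emulating intramural delamination banding --
#' occupy a known percentage of the area.  Stripe pixels are drawn from the
#' void law and the remaining intra-wall pixels from the wall law.
#'
#' Both laws are uniform with the requested mean and SD (support
#' `mean +/- sqrt(3)*sd`).  Bounded support means a reference-derived
#' threshold two reference-SDs inside the wall-ward flank of the void law
#' classifies *every* void pixel correctly, so recovery error measures
#' geometry, not tail mass; Gaussian tails would leak ~2.3% of void pixels
#' across such a threshold and bias recovered fractions down by up to
#' 2.3% of the void fraction.
#'
#' @param void_fraction target void percentage of the intra-wall region,
#'   in `[0, 100]`.
#' @param void_reference_roi,intra_wall_roi non-overlapping [roi()]s inside
#'   the image.
#' @param image_size `c(rows, cols)` in pixels.
#' @param seed integer RNG seed.
#' @param void_intensity_mean,void_intensity_sd void (electron-lucent,
#'   bright) intensity law.
#' @param wall_intensity_mean,wall_intensity_sd wall-material intensity law.
#'   The two means must be separated by at least four combined SDs so that
#'   recovery is well-posed.
#' @param pixel_length,units calibration.
#' @return a list with `image` and `truth`; `truth` carries the nominal and
#'   realized void fraction, the realized void pixel count, both intensity
#'   laws, both ROIs, and the exact void stencil (logical matrix in
#'   intra-wall-ROI-local coordinates).
#' @export
make_tem_wall <- function(void_fraction,
                          void_reference_roi = roi(1, 1, 40, 40),
                          intra_wall_roi = roi(61, 1, 180, 160),
                          image_size = c(200, 200), seed = 1,
                          void_intensity_mean = 220, void_intensity_sd = 8,
                          wall_intensity_mean = 120, wall_intensity_sd = 12,
                          pixel_length = 0.002, units = "um") {
  stopifnot(void_fraction >= 0, void_fraction <= 100,
            void_intensity_sd >= 0, wall_intensity_sd >= 0)
  dims <- as.integer(image_size)
  check_roi_bounds(void_reference_roi, dims)
  check_roi_bounds(intra_wall_roi, dims)
  a <- void_reference_roi; b <- intra_wall_roi
  overlap <- a$row_start <= b$row_stop && b$row_start <= a$row_stop &&
             a$col_start <= b$col_stop && b$col_start <= a$col_stop
  if (overlap) stop("void_reference_roi and intra_wall_roi must not overlap")
  if (abs(void_intensity_mean - wall_intensity_mean) <
      4 * (void_intensity_sd + wall_intensity_sd))
    stop("void and wall intensity laws must be separated by at least 4 combined SDs")

  hd <- roi_dims(intra_wall_roi)
  h <- hd[1]; wd <- hd[2]; area <- h * wd
  target <- round(void_fraction / 100 * area)

  with_rng_seed(seed, {
    stencil <- matrix(FALSE, h, wd)
    if (target >= area) {
      stencil[] <- TRUE
    } else if (target > 0) {
      done <- FALSE
      for (attempt in seq_len(10000L)) {
        tt <- min(sample(2:4, 1L), h)
        r1 <- sample.int(h - tt + 1L, 1L)
        len <- sample(seq.int(max(2L, ceiling(0.3 * wd)), wd), 1L)
        c1 <- sample.int(wd - len + 1L, 1L)
        block <- stencil[r1:(r1 + tt - 1L), c1:(c1 + len - 1L), drop = FALSE]
        new_local <- which(!block, arr.ind = TRUE)
        if (nrow(new_local) == 0L) next
        need <- target - sum(stencil)
        if (nrow(new_local) > need) {
          # trim the final stripe column-by-column from its far end
          ord <- order(-new_local[, 2], new_local[, 1])
          new_local <- new_local[ord, , drop = FALSE][seq_len(need), , drop = FALSE]
        }
        stencil[cbind(r1 + new_local[, 1] - 1L, c1 + new_local[, 2] - 1L)] <- TRUE
        if (sum(stencil) >= target) { done <- TRUE; break }
      }
      if (!done)
        stop("requested void_fraction unreachable at the given intra-wall geometry")
    }

    px <- matrix(runif_moment(prod(dims), wall_intensity_mean, wall_intensity_sd),
                 dims[1], dims[2])
    px[a$row_start:a$row_stop, a$col_start:a$col_stop] <-
      runif_moment(prod(roi_dims(a)), void_intensity_mean, void_intensity_sd)
    sub <- px[b$row_start:b$row_stop, b$col_start:b$col_stop]
    sub[stencil] <- runif_moment(sum(stencil), void_intensity_mean, void_intensity_sd)
    px[b$row_start:b$row_stop, b$col_start:b$col_stop] <- sub
    px <- pmin(pmax(px, 0), 255)

    list(
      image = calibrated_image(px, pixel_length = pixel_length, units = units,
                               source_id = sprintf("synthetic-tem-wall-seed%d", seed)),
      truth = list(void_fraction = void_fraction,
                   realized_void_px = sum(stencil),
                   realized_void_fraction = 100 * sum(stencil) / area,
                   void_intensity_mean = void_intensity_mean,
                   void_intensity_sd = void_intensity_sd,
                   wall_intensity_mean = wall_intensity_mean,
                   wall_intensity_sd = wall_intensity_sd,
                   void_reference_roi = a, intra_wall_roi = b,
                   stencil = stencil))
  })
}
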
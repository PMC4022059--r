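test_that("segmentation finds single and merged particles as constructed", {
  img <- two_disk_image()
  one_disk <- calibrated_image(
    ifelse((row(matrix(0, 60, 60)) - 30)^2 + (col(matrix(0, 60, 60)) - 30)^2 <= 225,
           60, 200), pixel_length = 1)
  expect_equal(max(segment_particles(one_disk)$labels), 1L)
  expect_equal(max(segment_particles(img, split_touching = TRUE)$labels), 2L)
  expect_equal(max(segment_particles(img, split_touching = FALSE)$labels), 1L)
  expect_error(segment_particles(calibrated_image(matrix(7, 5, 5), 1)),
               "constant")
})

test_that("watershed splitting conserves foreground area", {
  img <- two_disk_image()
  thr <- otsu_threshold(img)
  fg <- sum(img$pixels < thr)
  lab <- segment_particles(img, split_touching = TRUE, min_area_px = 1)
  expect_equal(sum(lab$labels > 0), fg)
})

test_that("8-connected labeling matches the flood-fill oracle on small masks", {
  set.seed(11)
  for (k in 1:40) {
    m <- random_mask(sample(5:32, 1), sample(5:32, 1), runif(1, 0.2, 0.7))
    lab <- label_components(binary_mask(m, 1))$labels
    oracle <- flood_fill_label(m)
    expect_equal(max(lab), max(oracle))
    # identical partition: each label maps 1-1 onto an oracle label
    if (max(lab) > 0) {
      pairs <- unique(cbind(lab[m], oracle[m]))
      expect_equal(nrow(pairs), max(lab))
    }
  }
})

test_that("descriptors reproduce known geometry", {
  # 10 x 10 solid square at l = 0.1 mm -> 1.00 mm^2
  m <- matrix(0L, 20, 20); m[5:14, 5:14] <- 1L
  lm <- structure(list(labels = m, pixel_length = 0.1, units = "mm"),
                  class = "label_map")
  rec <- compute_descriptors(lm)
  expect_equal(rec$area, 1.00)
  expect_equal(rec$centroid_row, 9.5)

  # rasterized ellipse, full axes 60 x 20 px -> aspect ratio 3
  pf <- make_particle_field(n = 1, area_dist = c(log(pi * 30 * 10), 1e-9),
                            aspect_dist = c(3, 1e-9), seed = 5,
                            image_size = c(150, 150))
  lab <- segment_particles(pf$image, split_touching = FALSE)
  rec <- compute_descriptors(lab)
  expect_equal(rec$aspect_ratio, 3, tolerance = 0.1 / 3)

  # disk -> roundness ~ 1
  disk <- matrix(0L, 41, 41)
  disk[(row(disk) - 21)^2 + (col(disk) - 21)^2 <= 15^2] <- 1L
  lmd <- structure(list(labels = disk, pixel_length = 1, units = "px"),
                   class = "label_map")
  expect_gte(compute_descriptors(lmd)$roundness, 0.95)

  expect_equal(nrow(compute_descriptors(structure(
    list(labels = matrix(0L, 5, 5), pixel_length = 1, units = "px"),
    class = "label_map"))), 0L)
})

test_that("descriptors scale correctly with pixel_length", {
  pf <- make_particle_field(n = 8, seed = 13, image_size = c(400, 400))
  lab1 <- segment_particles(pf$image, split_touching = FALSE)
  lab2 <- lab1; lab2$pixel_length <- 2 * lab1$pixel_length
  r1 <- compute_descriptors(lab1); r2 <- compute_descriptors(lab2)
  expect_equal(r2$area, 4 * r1$area)
  expect_equal(r2$perimeter, 2 * r1$perimeter)
  expect_equal(r2$aspect_ratio, r1$aspect_ratio)
  expect_equal(r2$roundness, r1$roundness)
})

test_that("non-touching synthetic fields are recovered particle-for-particle", {
  pf <- make_particle_field(n = 25, touching_fraction = 0, seed = 17,
                            image_size = c(600, 600))
  lab <- segment_particles(pf$image)
  rec <- compute_descriptors(lab)
  expect_equal(nrow(rec), pf$truth$n)
  tr <- pf$truth$particles
  match_idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((tr$center_row - rec$centroid_row[i])^2 +
              (tr$center_col - rec$centroid_col[i])^2), integer(1))
  expect_equal(sort(match_idx), seq_len(nrow(tr)))   # bijection
  expect_true(all(abs(rec$area_px - tr$area_px[match_idx]) /
                    tr$area_px[match_idx] <= 0.02))
  # summary recovers the truth mean aspect ratio within 5%
  s <- particle_summary(rec)
  expect_equal(s$mean_aspect_ratio, mean(tr$aspect_ratio), tolerance = 0.05)
  expect_equal(s$n, 25L)
})

test_that("histograms use left-closed bins and report out-of-range counts", {
  rec <- data.frame(area = c(0.5, 0.5, 0.5), aspect_ratio = c(2, 2, 2))
  h <- particle_histograms(rec, area_bins = c(0.25, 1), ar_bins = 1:4)
  expect_equal(h$area$count, 3L)
  expect_equal(h$aspect_ratio$count, c(0L, 1L * 3L, 0L))

  # value equal to an edge goes to the right bin
  rec2 <- data.frame(area = 1, aspect_ratio = 2)
  h2 <- particle_histograms(rec2, area_bins = c(0, 1, 2), ar_bins = c(1, 2, 3))
  expect_equal(h2$area$count, c(0L, 1L))
  expect_equal(h2$aspect_ratio$count, c(0L, 1L))

  # out-of-range reported, not dropped
  rec3 <- data.frame(area = c(0.1, 5), aspect_ratio = c(0.5, 30))
  h3 <- particle_histograms(rec3, area_bins = c(0.5, 1, 2), ar_bins = 1:20)
  expect_equal(sum(h3$area$count), 0L)
  expect_equal(h3$out_of_range$below, c(1L, 1L))
  expect_equal(h3$out_of_range$above, c(1L, 1L))

  expect_error(particle_histograms(rec, area_bins = c(1, 1, 2)),
               "strictly increasing")
})

test_that("bimodal fields put the right histogram mass above 1 mm^2", {
  pf <- make_particle_field(
    n = 250, area_dist = c(log(80), 0.5),
    area_dist2 = c(log(900), 0.3), mix_prop = 0.3,
    aspect_dist = c(1.8, 0.3), seed = 23,
    image_size = c(800, 800), pixel_length = 0.05, units = "mm")
  tr <- pf$truth$particles
  rec <- data.frame(area = tr$area_px * 0.05^2, aspect_ratio = tr$aspect_ratio)
  h <- particle_histograms(rec, area_bins = 2^seq(-10, 3))
  mass_above <- sum(h$area$count[h$area$lower >= 1]) + h$out_of_range$above[1]
  frac <- mass_above / nrow(rec)
  # matches the realized component-2 draw up to boundary crossers
  expect_equal(frac, mean(tr$component == 2L), tolerance = 0.15)
  # and the nominal 30% mixing mass up to sampling error (3 binomial SDs)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 250) + 0.02)
})

test_that("particle_summary computes plain means and rejects empty input", {
  rec <- data.frame(area = c(0.1, 0.3), aspect_ratio = c(1.5, 2.5))
  s <- particle_summary(rec)
  expect_equal(s$mean_area, 0.2)
  expect_equal(s$mean_aspect_ratio, 2)
  expect_error(particle_summary(rec[0, ]), "no particle")
})
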
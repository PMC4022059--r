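test_that("distance map matches hand geometry and the brute-force oracle", {
  # 1-px-wide line: every foreground pixel is adjacent to background
  m <- matrix(FALSE, 10, 20); m[5, 3:17] <- TRUE
  d <- distance_map(binary_mask(m, 1, "um"))
  expect_equal(unique(d$values[m]), 1.0)
  expect_true(all(d$values[!m] == 0))

  # 4-px strip: interior rows sit 2 px from background
  m2 <- matrix(FALSE, 12, 30); m2[5:8, 3:28] <- TRUE
  d2 <- distance_map(binary_mask(m2, 1, "um"))
  expect_equal(max(d2$values), 2.0)
  expect_equal(unique(d2$values[6, 10:20]), 2.0)

  set.seed(29)
  for (k in 1:30) {
    m <- random_mask(sample(5:32, 1), sample(5:32, 1), runif(1, 0.2, 0.8))
    d <- distance_map(binary_mask(m, 1, "um"))
    expect_equal(d$values, brute_force_distance(m), tolerance = 1e-12)
  }

  expect_error(distance_map(binary_mask(matrix(TRUE, 4, 4), 1)), "foreground and background")
  expect_error(distance_map(binary_mask(matrix(FALSE, 4, 4), 1)), "foreground and background")
})

test_that("distance values are Lipschitz across neighboring pixels", {
  set.seed(31)
  m <- random_mask(40, 40, 0.6)
  d <- distance_map(binary_mask(m, 2, "um"))$values  # l = 2 um
  for (o in list(c(0, 1), c(1, 0), c(1, 1))) {
    a <- d[1:(40 - o[1]), 1:(40 - o[2])]
    b <- d[(1 + o[1]):40, (1 + o[2]):40]
    expect_true(all(abs(a - b) <= 2 * sqrt(sum(o^2)) + 1e-9))
  }
})

test_that("medial axis of a strip is its center row; skeletons stay inside masks", {
  m <- matrix(FALSE, 20, 60); m[8:12, 6:55] <- TRUE   # width 5, center row 10
  sk <- medial_axis(binary_mask(m, 1))
  pts <- which(sk$pixels, arr.ind = TRUE)
  expect_true(all(pts[, 1] == 10))
  expect_gt(nrow(pts), 30)                   # spans most of the strip length
  expect_true(all(m[sk$pixels]))             # subset of foreground
  expect_lte(sum(sk$pixels), sum(m))

  # disk collapses to within 2 px of its center
  disk <- matrix(FALSE, 41, 41)
  disk[(row(disk) - 21)^2 + (col(disk) - 21)^2 <= 100] <- TRUE
  skd <- medial_axis(binary_mask(disk, 1))
  p <- which(skd$pixels, arr.ind = TRUE)
  expect_true(all(sqrt((p[, 1] - 21)^2 + (p[, 2] - 21)^2) <= 2))
})

test_that("medial axis preserves the component count of the mask", {
  lat <- make_cell_lattice(5, 22, n_cells = 4, dislocation_fraction = 0.5,
                           image_size = c(120, 120), seed = 2)
  sk <- medial_axis(lat$mask)
  expect_equal(max(label_components(sk)$labels),
               max(label_components(lat$mask)$labels))
})

test_that("thickness sampling applies the convention and scales with l", {
  m <- matrix(FALSE, 12, 40); m[5:8, 3:38] <- TRUE   # strip width 4
  bm <- binary_mask(m, 1, "um")
  dm <- distance_map(bm); sk <- medial_axis(bm)
  raw <- sample_thickness(dm, sk, "raw")
  expect_equal(unique(raw$values), 2.0)
  dbl <- sample_thickness(dm, sk, "disjoined-doubled")
  expect_equal(dbl$values, 2 * raw$values)

  # scale equivariance: l -> 3 l triples every sample
  bm3 <- binary_mask(m, 3, "um")
  raw3 <- sample_thickness(distance_map(bm3), medial_axis(bm3), "raw")
  expect_equal(raw3$values, 3 * raw$values)

  # disk of radius r: max sample ~ r * l
  disk <- matrix(FALSE, 41, 41)
  disk[(row(disk) - 21)^2 + (col(disk) - 21)^2 <= 100] <- TRUE
  bd <- binary_mask(disk, 0.5, "um")
  sd_ <- sample_thickness(distance_map(bd), medial_axis(bd))
  expect_equal(max(sd_$values), 10 * 0.5, tolerance = 0.1)

  empty <- binary_mask(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), 1)
  sk0 <- binary_mask(matrix(FALSE, 5, 5), 1)
  expect_error(sample_thickness(distance_map(empty), sk0), "empty skeleton")
})

test_that("strip identity holds across widths 3..15", {
  for (w in 3:15) {
    m <- matrix(FALSE, w + 14, 70); m[8:(7 + w), 6:65] <- TRUE
    bm <- binary_mask(m, 1, "um")
    v <- sample_thickness(distance_map(bm), medial_axis(bm))$values
    expect_lte(abs(mean(v) - w / 2), 0.5 + 1e-9)
  }
})

test_that("lattice walls are recovered at half-width under the raw convention", {
  lat <- make_cell_lattice(6, 30, n_cells = 9, image_size = c(160, 160),
                           seed = 3, pixel_length = 0.5, units = "um")
  s <- summarize_thickness(sample_thickness(distance_map(lat$mask),
                                            medial_axis(lat$mask), "raw"))
  expect_lte(abs(s$overall$mean - 1.5), 0.5 * 0.5)   # within 0.5 * l of w/2 * l
  expect_gt(s$overall$n, 100)
})

test_that("summaries pool overall and per group", {
  smp <- structure(list(values = c(2, 2, 2, 1, 3), coords = cbind(1:5, 1:5),
                        convention = "raw", units = "um", pixel_length = 1),
                   class = "thickness_samples")
  s <- summarize_thickness(smp)
  expect_equal(s$overall$mean, 2)
  expect_equal(s$overall$n, 5L)
  g <- summarize_thickness(smp, groups = c("a", "a", "a", "b", "b"))
  expect_equal(g$per_group$mean, c(2, 2))
  expect_equal(g$per_group$sd, c(0, sd(c(1, 3))))
  expect_equal(g$per_group$n, c(3L, 2L))
  expect_error(summarize_thickness(smp, groups = 1:3), "one label per")
})
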
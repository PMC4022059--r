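test_that("generators are deterministic in their seed and bounded in [0,255]", {
  a <- make_particle_field(n = 20, seed = 7, image_size = c(400, 400))
  b <- make_particle_field(n = 20, seed = 7, image_size = c(400, 400))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$particles, b$truth$particles)
  c2 <- make_particle_field(n = 20, seed = 8, image_size = c(400, 400))
  expect_false(identical(a$image$pixels, c2$image$pixels))

  l1 <- make_cell_lattice(5, 24, n_cells = 9, dislocation_fraction = 0.5,
                          image_size = c(140, 140), seed = 4)
  l2 <- make_cell_lattice(5, 24, n_cells = 9, dislocation_fraction = 0.5,
                          image_size = c(140, 140), seed = 4)
  expect_identical(l1$mask$pixels, l2$mask$pixels)

  s1 <- make_textured_surface(128, 10, c(64, 64), seed = 5)
  s2 <- make_textured_surface(128, 10, c(64, 64), seed = 5)
  expect_identical(s1$image$pixels, s2$image$pixels)

  t1 <- make_tem_wall(25, seed = 6)
  t2 <- make_tem_wall(25, seed = 6)
  expect_identical(t1$image$pixels, t2$image$pixels)

  for (img in list(a$image, l1$image, s1$image, t1$image)) {
    expect_true(min(img$pixels) >= 0)
    expect_true(max(img$pixels) <= 255)
  }
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  r1 <- runif(1)
  set.seed(99)
  invisible(make_textured_surface(128, 5, c(16, 16), seed = 3))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("a single circular particle has the rasterized disk area", {
  # area pi*10^2, aspect ratio 1 -> nearly a circle of radius 10
  pf <- make_particle_field(n = 1, area_dist = c(log(pi * 100), 1e-9),
                            aspect_dist = c(1, 1e-9), seed = 2,
                            image_size = c(100, 100))
  expect_equal(pf$truth$particles$area_px, 317, tolerance = 0.03)  # ~ pi*100
  expect_equal(sum(pf$image$pixels == 60), pf$truth$particles$area_px)
})

test_that("touching placement records pairs and capacity errors are raised", {
  pf <- make_particle_field(n = 2, touching_fraction = 1, seed = 3,
                            area_dist = c(log(200), 0.1),
                            image_size = c(200, 200))
  expect_equal(pf$truth$n_touching_pairs, 1L)
  expect_true(sum(pf$truth$particles$touching) == 1L)
  expect_error(make_particle_field(n = 1, area_dist = c(log(5e4), 1e-9),
                                   image_size = c(60, 60), seed = 1),
               "cannot be placed")
  expect_error(make_particle_field(n = 400, area_dist = c(log(900), 0.1),
                                   image_size = c(150, 150), seed = 1),
               "could not place")
})

test_that("lattice walls have the constructed thickness and dislocations split them", {
  lat <- make_cell_lattice(5, 24, n_cells = 9, image_size = c(140, 140), seed = 1)
  expect_equal(lat$truth$n_cells, 9L)
  # wall runs measure 5 px across: column profile through a cell-row midline
  mid_cell_rows <- lat$truth$origin["row"] + lat$truth$wall_thickness_px +
    12 + (0:2) * lat$truth$pitch
  for (r in mid_cell_rows) {
    runs <- rle(lat$mask$pixels[r, ])
    expect_true(all(runs$lengths[runs$values] == 5))
  }

  none <- make_cell_lattice(5, 24, 9, dislocation_fraction = 0,
                            image_size = c(140, 140), seed = 1)
  expect_true(all(!none$truth$segments$split))

  all_split <- make_cell_lattice(5, 24, 9, dislocation_fraction = 1,
                                 image_size = c(140, 140), seed = 1)
  expect_true(all(all_split$truth$segments$split))
  # each split wall now reads sub-gap-sub across: 2,1,2 for w=5
  r <- all_split$truth$origin["row"] + all_split$truth$wall_thickness_px + 12
  prof <- rle(all_split$mask$pixels[r, ])
  inner <- prof$lengths[prof$values]
  expect_true(all(inner %in% c(2, 5)))  # split sub-walls 2 px, outer border walls 5 px
  expect_true(any(inner == 2))
  # gap pixels are background in the rendered image
  expect_true(all(all_split$image$pixels[!all_split$mask$pixels] == 30))

  expect_error(make_cell_lattice(10, 8, 4, image_size = c(100, 100)),
               "smaller than the cell diameter")
  expect_error(make_cell_lattice(5, 24, 100, image_size = c(100, 100)),
               "does not fit")
})

test_that("textured surfaces realize the requested intensity dispersion", {
  flat <- make_textured_surface(100, 0, c(32, 32), seed = 1)
  expect_true(all(flat$image$pixels == 100))
  ts <- make_textured_surface(128, 10, c(512, 512), seed = 9)
  expect_equal(sd(as.vector(ts$image$pixels)), 10, tolerance = 0.02)
})

test_that("TEM wall stencils hit the requested void fraction", {
  t0 <- make_tem_wall(0, seed = 1)
  expect_equal(sum(t0$truth$stencil), 0L)
  t100 <- make_tem_wall(100, seed = 1)
  expect_true(all(t100$truth$stencil))

  t25 <- make_tem_wall(25, seed = 2)
  expect_equal(t25$truth$realized_void_fraction, 25, tolerance = 0.04)
  expect_true(abs(t25$truth$realized_void_fraction - 25) <= 1)

  # stencil pixels carry the void law, rest the wall law (well separated)
  r <- t25$truth$intra_wall_roi
  sub <- t25$image$pixels[r$row_start:r$row_stop, r$col_start:r$col_stop]
  expect_true(min(sub[t25$truth$stencil]) > max(sub[!t25$truth$stencil]))

  expect_error(make_tem_wall(25, void_intensity_mean = 150,
                             wall_intensity_mean = 120, seed = 1),
               "separated")
  expect_error(make_tem_wall(25, void_reference_roi = roi(1, 1, 80, 80),
                             intra_wall_roi = roi(61, 1, 180, 160), seed = 1),
               "overlap")
})
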
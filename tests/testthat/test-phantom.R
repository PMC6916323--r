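test_that("written series reads back to the exact analytic pattern", {
  cases <- list(
    list(intensity = intensity_constant(0),
         spec = list(grid_shape = c(8L, 16L, 16L), spacing = c(2, 1, 1))),
    list(intensity = intensity_constant(7),
         spec = list(grid_shape = c(4L, 8L, 8L), spacing = c(1, 0.5, 0.5))),
    list(intensity = intensity_axis_gradient(5L, c(10L, 2L, 1L)),
         spec = list(grid_shape = c(5L, 10L, 12L), spacing = c(2, 1, 1))),
    list(intensity = intensity_uniform_levels(6L, 25L),
         spec = list(grid_shape = c(4L, 8L, 8L), spacing = c(2, 1, 1))))
  for (cs in cases) {
    spec <- do.call(phantom_spec, c(cs$spec, list(intensity = cs$intensity)))
    dir <- withr::local_tempdir()
    write_phantom_series(spec, dir)
    vol <- read_series(dir)
    expect_identical(dim(vol$voxels), as.integer(spec$grid_shape))
    expect_equal(vol$voxels, array(as.numeric(phantom_volume(spec)),
                                   dim = spec$grid_shape))
    expect_equal(vol$spacing, spec$spacing, tolerance = 1e-9)
    expect_equal(vol$origin, spec$origin, tolerance = 1e-9)
  }
})

test_that("sphere lesion voxels match the analytic sphere equation", {
  spec <- phantom_spec(
    grid_shape = c(10L, 20L, 20L), spacing = c(2, 1, 1),
    intensity = intensity_sphere_lesion(center = c(9.5, 9.5, 9), radius = 6,
                                        fg = 100L, bg = -50L))
  vox <- phantom_volume(spec)
  # direct evaluation of ||x - center|| <= r at every voxel center
  for (trial in seq_len(50)) {
    k <- sample(spec$grid_shape[1], 1); r <- sample(spec$grid_shape[2], 1)
    cc <- sample(spec$grid_shape[3], 1)
    x <- c((cc - 1) * 1, (r - 1) * 1, (k - 1) * 2)  # patient (x,y,z), LPS
    inside <- sum((x - c(9.5, 9.5, 9))^2) <= 36
    expect_identical(vox[k, r, cc], if (inside) 100L else -50L)
  }
})

test_that("write -> read -> write produces byte-equivalent pixel data", {
  spec <- phantom_spec(grid_shape = c(3L, 8L, 8L), spacing = c(2, 1, 1),
                       intensity = intensity_axis_gradient(0L, c(7L, 3L, 1L)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_phantom_series(spec, d1)
  # reading back and re-writing the same spec must reproduce the bytes
  write_phantom_series(spec, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, function(f) readBin(f, raw(), file.size(f))),
                   lapply(f2, function(f) readBin(f, raw(), file.size(f))))
})

test_that("voxel-center geometry round-trips through the written tags", {
  for (orient in c("identity", "rotated")) {
    spec <- phantom_spec(grid_shape = c(4L, 6L, 6L), spacing = c(2.5, 1.5, 1),
                         origin = c(-10, 5, 2), orientation = orient)
    dir <- withr::local_tempdir()
    write_phantom_series(spec, dir)
    vol <- read_series(dir)
    D <- vol$direction
    for (idx in list(c(0, 0, 0), c(3, 5, 5), c(2, 1, 4))) {
      expected <- spec$origin +
        radsem:::phantom_direction(spec) %*% (spec$spacing * idx)
      got <- vol$origin + D %*% (vol$spacing * idx)
      expect_lt(max(abs(got - expected)), 1e-6)
    }
  }
})

test_that("rtstruct encodes the requested contour geometry", {
  rois <- list(
    roi_spec("circle", shape_circle(c(8, 8), 10, 64L), 0:4),
    roi_spec("ring", shape_ring(shape_circle(c(8, 8), 6, 32L),
                                shape_circle(c(8, 8), 3, 32L)), 1:2),
    roi_spec("rect", shape_rectangle(c(8, 8), c(4, 6)), 0L))
  spec <- phantom_spec(grid_shape = c(6L, 24L, 24L), spacing = c(2, 1, 1),
                       rois = rois)
  dir <- withr::local_tempdir()
  write_phantom_series(spec, file.path(dir, "series"))
  rt <- file.path(dir, "rtstruct.dcm")
  write_phantom_rtstruct(spec, rt)
  ss <- read_structset(rt)
  expect_named(ss$rois, c("circle", "ring", "rect"))

  circ <- ss$rois[["circle"]]$contours
  expect_length(circ, 5L)
  for (ct in circ) {
    expect_equal(nrow(ct), 64L)
    radii <- sqrt((ct[, 1] - 8)^2 + (ct[, 2] - 8)^2)
    expect_lt(max(abs(radii - 10)), 1e-6)
  }
  # ring: two contours per slice, inner strictly inside outer
  ring <- ss$rois[["ring"]]$contours
  expect_length(ring, 4L)
  r1 <- sqrt((ring[[1]][, 1] - 8)^2 + (ring[[1]][, 2] - 8)^2)
  r2 <- sqrt((ring[[2]][, 1] - 8)^2 + (ring[[2]][, 2] - 8)^2)
  expect_true(max(r2) < min(r1))
})

test_that("an rtstruct with zero ROIs is written and read without error", {
  spec <- phantom_spec(grid_shape = c(2L, 4L, 4L))
  dir <- withr::local_tempdir()
  write_phantom_series(spec, file.path(dir, "series"))
  rt <- write_phantom_rtstruct(spec, file.path(dir, "rtstruct.dcm"))
  ss <- read_structset(rt)
  expect_length(ss$rois, 0L)
})

test_that("spec invariants reject impossible phantoms", {
  expect_error(phantom_spec(spacing = c(0, 1, 1)), "spacing")
  expect_error(phantom_spec(
    grid_shape = c(4L, 8L, 8L), spacing = c(1, 1, 1),
    intensity = intensity_sphere_lesion(c(4, 4, 2), radius = 50)),
    "outside")
  expect_error(shape_circle(c(0, 0), 5, n_vertices = 2L))
})
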
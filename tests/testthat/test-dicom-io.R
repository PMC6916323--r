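test_that("series reading is invariant to on-disk file order", {
  spec <- phantom_spec(grid_shape = c(6L, 8L, 8L), spacing = c(2, 1, 1),
                       intensity = intensity_axis_gradient(0L, c(10L, 2L, 1L)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  paths <- write_phantom_series(spec, d1)
  # copy with shuffled, misleading names
  set.seed(42)
  shuffled <- sample(paths)
  for (i in seq_along(shuffled))
    file.copy(shuffled[i], file.path(d2, sprintf("x-%03d.dcm", i)))
  v1 <- read_series(d1); v2 <- read_series(d2)
  expect_identical(v2$voxels, v1$voxels)
  expect_identical(v2$origin, v1$origin)
})

test_that("mixed series in one directory raise an informative error", {
  d <- withr::local_tempdir()
  s1 <- file.path(d, "s1"); write_phantom_series(
    phantom_spec(grid_shape = c(2L, 4L, 4L), patient_id = "A"), s1)
  s2 <- file.path(d, "s2"); write_phantom_series(
    phantom_spec(grid_shape = c(2L, 4L, 4L), patient_id = "B"), s2)
  mixed <- file.path(d, "mixed"); dir.create(mixed)
  file.copy(list.files(s1, full.names = TRUE), mixed)
  file.copy(list.files(s2, full.names = TRUE)[1],
            file.path(mixed, "b-001.dcm"))
  expect_error(read_series(mixed), "multiple series")
})

test_that("degenerate contours are dropped, valid ROIs kept", {
  # hand-build an RTSTRUCT-like structure via the phantom writer, then damage
  # one contour by truncating its points through the low-level codec
  spec <- phantom_spec(
    grid_shape = c(4L, 12L, 12L), spacing = c(2, 1, 1),
    rois = list(roi_spec("good", shape_circle(c(6, 6), 4, 16L), 0:1),
                roi_spec("bad", shape_circle(c(6, 6), 3, 16L), 0L)))
  d <- withr::local_tempdir()
  case <- make_case(spec, d)
  raw <- radsem:::dcm_read(case$rtstruct_path)
  rcs <- raw$data[["30060039"]]$val
  # truncate the bad ROI's only contour to 2 points (6 coordinates)
  ct <- rcs[[2]][["30060040"]]$val[[1]]
  ct[["30060050"]]$val <- ct[["30060050"]]$val[1:6]
  ct[["30060046"]]$val <- 2
  rcs[[2]][["30060040"]]$val[[1]] <- ct
  raw$data[["30060039"]]$val <- rcs
  out <- file.path(d, "damaged.dcm")
  ds <- radsem:::rebuild_elements(raw$data)
  radsem:::dcm_write(out, radsem:::SOP_CLASS[["RTSTRUCT"]],
                     "1.2.3.4", ds)
  ss <- suppressMessages(read_structset(out))
  expect_length(ss$rois[["good"]]$contours, 2L)
  expect_length(ss$rois[["bad"]]$contours, 0L)
})

test_that("match_cases pairs series with structure sets by precedence", {
  root <- withr::local_tempdir()
  for (i in 1:3)
    sphere_case(file.path(root, sprintf("case-%d", i)),
                patient_id = sprintf("PH-%03d", i), seed = 100L + i)
  pairings <- match_cases(root)
  expect_length(pairings, 3L)
  expect_true(all(vapply(pairings, `[[`, character(1), "matched_by") ==
                    "frame_of_reference"))
  dirs <- sort(vapply(pairings, `[[`, character(1), "series_dir"))
  expect_identical(basename(dirname(dirs)), paste0("case-", 1:3))
})

test_that("a foreign RTSTRUCT falls back to directory co-location", {
  root <- withr::local_tempdir()
  case_dir <- file.path(root, "case-1")
  sphere_case(case_dir, patient_id = "PH-001", seed = 1L)
  # rtstruct from an unrelated phantom dropped into the same case directory
  other <- phantom_spec(grid_shape = c(2L, 4L, 4L), patient_id = "ALIEN",
                        rois = list(roi_spec("x", shape_circle(c(2, 2), 1, 8L), 0L)))
  file.remove(file.path(case_dir, "rtstruct.dcm"))
  write_phantom_rtstruct(other, file.path(case_dir, "rtstruct.dcm"))
  pairings <- suppressMessages(match_cases(root))
  expect_length(pairings, 1L)
  expect_identical(pairings[[1]]$matched_by, "directory_fallback")
})

test_that("select_rois applies case-insensitive globs, exclude wins", {
  ss <- structure(list(rois = stats::setNames(
    lapply(c("GTV-1", "Lung_L", "ring"), function(n) list(name = n)),
    c("GTV-1", "Lung_L", "ring"))), class = "structure_set")
  expect_named(select_rois(ss, include = "gtv*")$rois, "GTV-1")
  expect_named(select_rois(ss, exclude = "*ring*")$rois, c("GTV-1", "Lung_L"))
  expect_length(select_rois(ss, include = "*", exclude = "*")$rois, 0L)
  expect_length(select_rois(ss)$rois, 3L)
})

test_that("nrrd volume and mask files round-trip with geometry intact", {
  arr <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  vol <- make_volume(arr, spacing = c(2.5, 1.5, 0.5), origin = c(10, -4, 3))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume_nrrd(vol, p)
  v2 <- read_volume_nrrd(p)
  expect_equal(v2$voxels, vol$voxels)
  expect_equal(v2$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(v2$origin, vol$origin, tolerance = 1e-9)

  m <- make_mask(array(arr > 0, dim(arr)), vol)
  pm <- withr::local_tempfile(fileext = ".nrrd")
  write_mask_nrrd(m, pm)
  m2 <- read_mask_nrrd(pm)
  expect_identical(m2$bits, m$bits)
  expect_equal(m2$spacing, m$spacing, tolerance = 1e-9)
  # empty mask round-trips too
  m$bits[] <- FALSE
  write_mask_nrrd(m, pm)
  expect_identical(read_mask_nrrd(pm)$bits, m$bits)
})
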